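# Shared fixtures: small pedigrees, genotype tables and oracle helpers.
# Everything is built in code; no binary data.

ped_trio <- function() {
  pedigree("t", c("f", "m", "c1"), c(NA, NA, "f"), c(NA, NA, "m"),
           sex = c("male", "female", "unknown"),
           affection = c("unaffected", "unaffected", "CD"))
}

ped_sibs <- function() {
  pedigree("s", c("f", "m", "c1", "c2"), c(NA, NA, "f", "f"),
           c(NA, NA, "m", "m"), sex = c("male", "female", rep("unknown", 2)))
}

ped_avuncular <- function() {
  pedigree("a", c("f", "m", "c1", "c2", "sp", "n1"),
           c(NA, NA, "f", "f", NA, "c2"),
           c(NA, NA, "m", "m", NA, "sp"))
}

ped_cousins <- function() {
  pedigree("c", c("gf", "gm", "p1", "p2", "s1", "s2", "c1", "c2"),
           c(NA, NA, "gf", "gf", NA, NA, "p1", "p2"),
           c(NA, NA, "gm", "gm", NA, NA, "s1", "s2"))
}

# two collateral 3-meiosis branches: 6 meioses between targets a2 and b2
ped_chain6 <- function() {
  pedigree("h",
           c("f", "m", "a", "b", "sa", "sb", "a1", "b1", "saa", "sbb",
             "a2", "b2"),
           c(NA, NA, "f", "f", NA, NA, "a", "b", NA, NA, "a1", "b1"),
           c(NA, NA, "m", "m", NA, NA, "sa", "sb", NA, NA, "saa", "sbb"))
}

# lineal chain: target pair = top father and his depth-d descendant
ped_lineal <- function(d) {
  ids <- c("f0", "m0", paste0("x", seq_len(d)), paste0("s", seq_len(d - 1)))
  father <- c(NA, NA, "f0", if (d > 1) paste0("x", seq_len(d - 1)),
              rep(NA, d - 1))
  mother <- c(NA, NA, "m0", if (d > 1) paste0("s", seq_len(d - 1)),
              rep(NA, d - 1))
  pedigree("l", ids, father, mother)
}

# variant_table builder: geno is a matrix with sample columns
toy_vt <- function(geno, chrom = "chr1", pos = NULL, quality = 50,
                   pop_af = 0, consequence = "missense", gene = "GENE1") {
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  variant_table(
    data.frame(chrom = rep_len(chrom, n), pos = pos,
               ref = "A", alt = "T",
               quality = rep_len(quality, n),
               pop_af = rep_len(pop_af, n),
               consequence = rep_len(consequence, n),
               gene = rep_len(gene, n), stringsAsFactors = FALSE),
    geno)
}

panel1 <- function() data.frame(gene = c("GENE1", "GENE2", "GENE3"),
                                distance = c(0L, 1L, 2L),
                                stringsAsFactors = FALSE)

# Mendelian reachability of a child allele count from parental counts
mendel_ok <- function(gf, gm, gc) {
  from <- function(g) switch(g + 1L, 0L, c(0L, 1L), 1L)
  gc %in% outer(from(gf), from(gm), "+")
}

# fraction of the genome over which two individuals share founder
# haplotypes (0, 1/2 or 1 per point), length-weighted
ibd_fraction <- function(drop, a, b) {
  total <- 0; shared <- 0
  for (ci in seq_len(nrow(drop$map$chrom))) {
    ga <- drop$genomes[[a]][[ci]]; gb <- drop$genomes[[b]][[ci]]
    ends <- sort(unique(c(ga$h1[, 1], ga$h2[, 1], gb$h1[, 1], gb$h2[, 1])))
    starts <- c(0, ends[-length(ends)])
    mids <- (starts + ends) / 2
    lab <- function(h) h[findInterval(mids, h[, 1]) + 1L, 2L]
    a1 <- lab(ga$h1); a2 <- lab(ga$h2); b1 <- lab(gb$h1); b2 <- lab(gb$h2)
    n_sh <- (a1 == b1 | a1 == b2) + (a2 == b1 | a2 == b2)
    shared <- shared + sum((ends - starts) * n_sh / 2)
    total <- total + sum(ends - starts)
  }
  shared / total
}

# independent logistic maximum-likelihood fit (no glm): Nelder-Mead on the
# exact log-likelihood, used as oracle for nagelkerke_r2
oracle_nagelkerke <- function(scores, labels) {
  y <- as.numeric(labels)
  nll <- function(b) {
    eta <- b[1] + b[2] * scores
    -sum(y * eta - log1p(exp(eta)))
  }
  fit1 <- stats::optim(c(0, 0), nll, control = list(reltol = 1e-12,
                                                    maxit = 5000))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  ll1 <- -fit1$value
  n <- length(y)
  r2_cs <- 1 - exp(2 / n * (ll0 - ll1))
  r2_cs / (1 - exp(2 / n * ll0))
}
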