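# Gene-drop simulation: founder haplotypes are dropped through a pedigree,
# recombining at each meiosis.  Haplotypes are segment tracks labelled with
# founder-haplotype ids, so identity by descent is known exactly in every
# simulation -- this makes the simulator usable as an oracle for the
# analytic segment-sharing model.
#
# A haplotype on one chromosome is a two-column matrix (end, hap): segment i
# spans the 0-based half-open interval [end[i-1], end[i]) and carries founder
# haplotype `hap`.  The last end equals the chromosome length.

hap_track <- function(len, hap) cbind(end = len, hap = hap)

# one gamete: recombine parent's two haplotype tracks
# bp: sorted crossover positions; start: starting strand (1 or 2)
recombine_track <- function(h1, h2, bp, start) {
  if (length(bp) == 0L) return(if (start == 1L) h1 else h2)
  ends <- sort(unique(c(bp, h1[, 1L], h2[, 1L])))
  mids <- (c(0, ends[-length(ends)]) + ends) / 2
  strand <- (start - 1L + findInterval(mids, bp)) %% 2L + 1L
  hap <- ifelse(strand == 1L,
                h1[findInterval(mids, h1[, 1L]) + 1L, 2L],
                h2[findInterval(mids, h2[, 1L]) + 1L, 2L])
  n <- length(ends)
  keep <- c(hap[-n] != hap[-1L], TRUE)
  cbind(end = ends[keep], hap = hap[keep])
}

# one meiosis over all chromosomes of a parental genome
# genome: list per chromosome of list(h1, h2)
meiosis <- function(genome, map) {
  lapply(seq_along(genome), function(ci) {
    lam <- map$chrom$exp_xo[ci]
    len <- map$chrom$length[ci]
    k <- rpois(1L, lam)
    bp <- if (k > 0L) sort(runif(k, 0, len)) else numeric(0)
    start <- sample.int(2L, 1L)
    recombine_track(genome[[ci]]$h1, genome[[ci]]$h2, bp, start)
  })
}

#' Drop founder haplotypes through a pedigree
#'
#' Simulates inheritance in `ped` on the genetic map `map`.  Every meiosis
#' draws a Poisson number of crossovers per chromosome (expectation from the
#' map, positions uniform on physical length, no interference) and a fair
#' starting strand.  Founders receive uniquely labelled haplotypes, so the
#' returned tracks record the founder origin of every genomic interval of
#' every member.
#'
#' @param ped a `fam_pedigree`; every non-founder must have both parents.
#' @param map a `genetic_map`.
#' @param seed optional integer seed for reproducibility.
#' @return object of class `gene_drop`: list with `ped`, `map`,
#'   `founder_haps` (data frame `id`, `hap1`, `hap2` giving each founder's
#'   haplotype labels) and `genomes`, a named list per individual of
#'   per-chromosome `list(h1, h2)` segment tracks (`h1` paternal).
#' @export
gene_drop <- function(ped, map, seed = NULL) {
  validate_pedigree(ped)
  half <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(half))
    stop("missing parent: every non-founder needs both parents (",
         paste(ped$id[half], collapse = ", "), ")")
  if (!is.null(seed)) set.seed(seed)
  ord <- ped_topological_order(ped)
  fnd <- founders(ped)
  founder_haps <- data.frame(id = fnd,
                             hap1 = 2L * seq_along(fnd) - 1L,
                             hap2 = 2L * seq_along(fnd),
                             stringsAsFactors = FALSE)
  lens <- map$chrom$length
  genomes <- vector("list", nrow(ped))
  names(genomes) <- ped$id
  for (who in ord) {
    row <- ped[ped$id == who, ]
    if (is.na(row$father)) {
      k <- match(who, founder_haps$id)
      genomes[[who]] <- lapply(lens, function(L)
        list(h1 = hap_track(L, founder_haps$hap1[k]),
             h2 = hap_track(L, founder_haps$hap2[k])))
    } else {
      pat <- meiosis(genomes[[row$father]], map)
      mat <- meiosis(genomes[[row$mother]], map)
      genomes[[who]] <- lapply(seq_along(lens), function(ci)
        list(h1 = pat[[ci]], h2 = mat[[ci]]))
    }
  }
  structure(list(ped = ped, map = map, founder_haps = founder_haps,
                 genomes = genomes),
            class = "gene_drop")
}

# founder haplotype label carried by a track at 0-based position pos0
hap_at <- function(track, pos0) track[findInterval(pos0, track[, 1L]) + 1L, 2L]

#' Genotypes of gene-drop individuals at marker loci
#'
#' Looks up the founder haplotype carried at each locus and translates it to
#' an allele count via `founder_alleles`.
#'
#' @param drop a `gene_drop` object.
#' @param loci data frame with columns `chrom` and `pos` (1-based).
#' @param founder_alleles integer matrix (n_loci x n_founder_haplotypes) of
#'   alternate-allele indicators (0/1); column j corresponds to founder
#'   haplotype label j.
#' @return integer matrix (n_loci x n_individuals) of alternate-allele
#'   counts in 0..2.
#' @export
drop_genotypes <- function(drop, loci, founder_alleles) {
  ci <- match(loci$chrom, drop$map$chrom$chrom)
  if (anyNA(ci)) stop("locus chromosome absent from map: ",
                      paste(unique(loci$chrom[is.na(ci)]), collapse = ", "))
  pos0 <- loci$pos - 1
  ids <- names(drop$genomes)
  out <- matrix(0L, nrow(loci), length(ids),
                dimnames = list(loci$locus_id %||% NULL, ids))
  by_chr <- split(seq_len(nrow(loci)), ci)
  for (j in seq_along(ids)) {
    g <- drop$genomes[[j]]
    for (cc in names(by_chr)) {
      k <- by_chr[[cc]]
      cn <- as.integer(cc)
      h1 <- g[[cn]]$h1; h2 <- g[[cn]]$h2
      lab1 <- h1[findInterval(pos0[k], h1[, 1L]) + 1L, 2L]
      lab2 <- h2[findInterval(pos0[k], h2[, 1L]) + 1L, 2L]
      out[k, j] <- founder_alleles[cbind(k, lab1)] +
        founder_alleles[cbind(k, lab2)]
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Founder haplotype model
#'
#' Describes the population the founders are drawn from: marker loci with
#' population alternate-allele frequencies, plus an optional list of rare
#' variants injected into named founder carriers (one heterozygous copy),
#' used to plant family-private variants.
#'
#' @param loci data frame with columns `locus_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `freq` (frequency in `[0, 1)`).
#' @param rare optional data frame with columns `locus_id`, `carrier`.
#' @return object of class `founder_model`.
#' @export
founder_model <- function(loci, rare = NULL) {
  stopifnot(all(c("locus_id", "chrom", "pos", "freq") %in% names(loci)))
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus ids")
  if (any(loci$freq < 0 | loci$freq >= 1))
    stop("locus frequencies must lie in [0, 1)")
  if (!is.null(rare)) {
    bad <- setdiff(rare$locus_id, loci$locus_id)
    if (length(bad)) stop("rare injection for unknown locus: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(loci = loci, rare = rare), class = "founder_model")
}

#' Draw founder haplotype alleles from a founder model
#'
#' Each founder haplotype carries the alternate allele at a locus with the
#' locus's population frequency (independent loci: no linkage disequilibrium
#' among founders).  Rare injections then place one alternate copy on the
#' first haplotype of the named carrier founder.
#'
#' @param model a `founder_model`.
#' @param founder_haps the `founder_haps` table of a [gene_drop()] result.
#' @return 0/1 integer matrix (n_loci x n_founder_haplotypes).
#' @export
draw_founder_alleles <- function(model, founder_haps) {
  n_hap <- max(founder_haps$hap2)
  loci <- model$loci
  m <- matrix(rbinom(nrow(loci) * n_hap, 1L, rep(loci$freq, n_hap)),
              nrow = nrow(loci), ncol = n_hap)
  if (!is.null(model$rare)) {
    for (k in seq_len(nrow(model$rare))) {
      i <- match(model$rare$locus_id[k], loci$locus_id)
      f <- match(model$rare$carrier[k], founder_haps$id)
      if (!is.na(f)) m[i, founder_haps$hap1[f]] <- 1L
    }
  }
  m
}

#' Simulate an unrelated control genotype panel
#'
#' Controls are unrelated genomes drawn at the population allele
#' frequencies, i.e. Hardy-Weinberg genotype counts `Binomial(2, p)` per
#' locus.
#'
#' @param n number of controls (>= 1).
#' @param model a `founder_model` (its `rare` injections are ignored:
#'   family-private variants do not occur in the unrelated panel).
#' @param seed optional integer seed.
#' @return integer matrix (n_loci x n) of alternate-allele counts, rows
#'   named by locus id, columns `control_1` ... `control_n`.
#' @export
simulate_controls <- function(n, model, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  loci <- model$loci
  g <- matrix(rbinom(nrow(loci) * n, 2L, rep(loci$freq, n)),
              nrow = nrow(loci), ncol = n,
              dimnames = list(loci$locus_id, paste0("control_", seq_len(n))))
  g
}

#' Liability model linking risk score to affection
#'
#' Affection is Bernoulli with probability `plogis(beta0 + beta1 * score)`.
#' This logistic liability is a generative stand-in (the true architecture
#' of the disease is unknown); it exists so that case/control statistics
#' have a known truth in simulations.  Affected individuals are labelled
#' with the subtype whose score is larger, flipped with probability `mix`.
#'
#' @param beta0 intercept (log-odds of affection at score 0).
#' @param beta1 score coefficient.
#' @param mix probability of assigning the subtype with the smaller score.
#' @return object of class `disease_model`.
#' @export
disease_model <- function(beta0 = -3, beta1 = 1, mix = 0.1) {
  stopifnot(is.finite(beta0), is.finite(beta1), mix >= 0, mix <= 0.5)
  structure(list(beta0 = beta0, beta1 = beta1, mix = mix),
            class = "disease_model")
}

#' Draw affection statuses from risk scores
#'
#' @param scores numeric vector of risk scores used as the liability, or a
#'   data frame / matrix with columns `s_cd` and `s_uc` (the liability is
#'   then the per-individual maximum of the two subtype scores).
#' @param model a [disease_model()].
#' @param seed optional integer seed.
#' @return character vector over `"CD"`, `"UC"`, `"unaffected"`.
#' @export
assign_phenotypes <- function(scores, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(scores) || is.matrix(scores)) {
    s_cd <- scores[, "s_cd"]
    s_uc <- scores[, "s_uc"]
    liab <- pmax(s_cd, s_uc)
  } else {
    s_cd <- scores
    s_uc <- rep(0, length(scores))
    liab <- scores
  }
  if (any(!is.finite(liab))) stop("scores must be finite")
  p <- stats::plogis(model$beta0 + model$beta1 * liab)
  affected <- rbinom(length(p), 1L, p) == 1L
  flip <- runif(length(p)) < model$mix
  cd_like <- xor(s_cd >= s_uc, flip)
  ifelse(affected, ifelse(cd_like, "CD", "UC"), "unaffected")
}
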