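# Probability that a set of relatives shares a chromosomal segment identical
# by descent, following the classical shared-genomic-segment argument: with
# each meiosis the probability of sharing a segment not linked to the
# ascertained phenotype is approximately halved, so in deep pedigrees any
# observed all-affected sharing is unlikely to be chance.
#
# The point-sharing probability is computed by exact enumeration of
# inheritance vectors on the minimal transmission subgraph connecting the
# targets to their most recent common ancestral couple.  The genome-wide
# probability then treats the genome as N = C + m * rho segments (C
# chromosomes, m meioses, rho expected crossovers per meiosis) sharing
# independently.

ancestor_closure <- function(ped, ids) {
  out <- character(0)
  queue <- ids
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur %in% out) next
    out <- c(out, cur)
    row <- ped[ped$id == cur, ]
    for (p in c(row$father, row$mother))
      if (!is.na(p) && !(p %in% out)) queue <- c(queue, p)
  }
  out
}

descendant_closure <- function(ped, ids) {
  out <- character(0)
  queue <- ids
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur %in% out) next
    out <- c(out, cur)
    kids <- ped$id[(!is.na(ped$father) & ped$father == cur) |
                     (!is.na(ped$mother) & ped$mother == cur)]
    queue <- c(queue, setdiff(kids, out))
  }
  out
}

# Minimal transmission subgraph connecting `targets` to a common ancestral
# couple.  The couple is contracted to a single node for the meiosis count
# (parent-child: 1, full sibs: 2, first cousins: 4).  Among all candidate
# couples the one giving the smallest meiosis count is chosen.
minimal_subgraph <- function(ped, targets) {
  stopifnot(length(targets) >= 1)
  missing_t <- setdiff(targets, ped$id)
  if (length(missing_t))
    stop("targets absent from pedigree: ", paste(missing_t, collapse = ", "))
  kids <- ped[!is.na(ped$father), ]
  couples <- unique(kids[, c("father", "mother")])
  anc <- lapply(setNames(targets, targets),
                function(t) ancestor_closure(ped, t))
  best <- NULL
  for (k in seq_len(nrow(couples))) {
    f <- couples$father[k]; m <- couples$mother[k]
    desc <- unique(c(f, m, descendant_closure(ped, c(f, m))))
    if (!all(targets %in% desc)) next
    # nodes lying on a descent path couple -> target
    on_path <- vapply(ped$id, function(x)
      x %in% desc && any(vapply(anc, function(a) x %in% a, logical(1))),
      logical(1))
    nodes <- ped$id[on_path]
    inner <- setdiff(nodes, c(f, m))
    m_total <- 0L
    for (x in inner) {
      row <- ped[ped$id == x, ]
      pf <- row$father; pm <- row$mother
      pf_in <- !is.na(pf) && pf %in% nodes
      pm_in <- !is.na(pm) && pm %in% nodes
      if (pf_in && pm_in && pf == f && pm == m) {
        m_total <- m_total + 1L  # couple contracted to one node
      } else {
        m_total <- m_total + pf_in + pm_in
      }
    }
    cand <- list(couple = c(f, m), nodes = nodes, m_total = m_total)
    if (is.null(best) || cand$m_total < best$m_total) best <- cand
  }
  if (is.null(best))
    stop("no common ancestral couple connects the targets")
  best
}

#' Count meioses connecting a target set
#'
#' Number of parent-to-child transmissions in the minimal subgraph joining
#' `targets` to their most recent common ancestral couple (the couple being
#' one node: 1 for parent-child, 2 for full sibs, 4 for first cousins).
#'
#' @param ped a `fam_pedigree`.
#' @param targets character vector of member ids.
#' @return integer meiosis count.
#' @export
count_meioses <- function(ped, targets) minimal_subgraph(ped, targets)$m_total

#' Probability that all targets share a haplotype at a genomic point
#'
#' Exact enumeration over the inheritance vectors of the minimal subgraph:
#' every meiosis independently transmits the grandpaternal or grandmaternal
#' haplotype with probability 1/2 (meioses out of the ancestral couple
#' resolve both founder strands).  The returned value is the fraction of
#' vectors in which every target carries a copy of one common haplotype of
#' the ancestral couple -- any of the couple's four strands counts, since
#' identity by descent does not prescribe which ancestral chromosome is
#' shared.  Full sibs give 0.75, first cousins 0.25, a parent-child pair 1.
#'
#' @param ped a `fam_pedigree`.
#' @param targets character vector of >= 1 member ids.
#' @param max_meioses exact-enumeration bound (default 26); above it the
#'   caller is directed to [gene_drop_sharing_mc()].
#' @param chunk_bits enumeration chunk size (2^chunk_bits vectors at a time).
#' @return probability in (0, 1]; attributes `m_total` and `n_vectors`.
#' @export
point_sharing_probability <- function(ped, targets, max_meioses = 26L,
                                      chunk_bits = 18L) {
  sg <- minimal_subgraph(ped, targets)
  if (sg$m_total > max_meioses)
    stop("meiosis count ", sg$m_total, " exceeds the exact enumeration ",
         "bound (", max_meioses, "); use gene_drop_sharing_mc()")
  f <- sg$couple[1]; m <- sg$couple[2]
  inner <- setdiff(sg$nodes[order(match(sg$nodes,
                                        ped_topological_order(ped)))],
                   c(f, m))
  # assign one enumeration bit per transmitted strand choice
  bit_of <- list(); n_bits <- 0L
  parents_in <- list()
  for (x in inner) {
    row <- ped[ped$id == x, ]
    pf <- row$father; pm <- row$mother
    use_f <- !is.na(pf) && pf %in% sg$nodes
    use_m <- !is.na(pm) && pm %in% sg$nodes
    b <- c(father = NA_integer_, mother = NA_integer_)
    if (use_f) { b["father"] <- n_bits; n_bits <- n_bits + 1L }
    if (use_m) { b["mother"] <- n_bits; n_bits <- n_bits + 1L }
    bit_of[[x]] <- b
    parents_in[[x]] <- c(father = use_f, mother = use_m)
  }
  total <- 2^n_bits
  chunk <- min(total, 2^chunk_bits)
  n_share <- 0
  done <- 0
  while (done < total) {
    v <- done + seq_len(min(chunk, total - done)) - 1
    # haplotype labels: couple strands are 1,2 (father) and 3,4 (mother);
    # 0 denotes any non-couple haplotype
    haps <- list()
    haps[[f]] <- list(a = rep(1, length(v)), b = rep(2, length(v)))
    haps[[m]] <- list(a = rep(3, length(v)), b = rep(4, length(v)))
    for (x in inner) {
      row <- ped[ped$id == x, ]
      hx <- list(a = rep(0, length(v)), b = rep(0, length(v)))
      if (parents_in[[x]]["father"]) {
        bit <- bitwAnd(v, 2^bit_of[[x]]["father"]) > 0
        ph <- haps[[row$father]]
        hx$a <- ifelse(bit, ph$a, ph$b)
      }
      if (parents_in[[x]]["mother"]) {
        bit <- bitwAnd(v, 2^bit_of[[x]]["mother"]) > 0
        ph <- haps[[row$mother]]
        hx$b <- ifelse(bit, ph$a, ph$b)
      }
      haps[[x]] <- hx
    }
    shared <- rep(FALSE, length(v))
    for (lab in 1:4) {
      carry <- rep(TRUE, length(v))
      for (t in targets)
        carry <- carry & (haps[[t]]$a == lab | haps[[t]]$b == lab)
      shared <- shared | carry
    }
    n_share <- n_share + sum(shared)
    done <- done + length(v)
  }
  structure(n_share / total, m_total = sg$m_total, n_vectors = total)
}

#' Genome-wide probability of an all-target shared segment
#'
#' Models the genome as `N = C + m * rho` segments (one starting segment per
#' chromosome plus one per expected crossover across the `m` connecting
#' meioses) that share independently with the point probability from
#' [point_sharing_probability()].  The default returns the binomial form
#' `1 - (1 - p)^N`; `model = "poisson"` gives `1 - exp(-p * N)`.
#'
#' @param ped a `fam_pedigree`.
#' @param targets character vector of member ids.
#' @param map a `genetic_map` (supplies `C` and `rho`).
#' @param model `"binomial"` (default) or `"poisson"` tail.
#' @param ... passed to [point_sharing_probability()].
#' @return probability; attributes `p_point`, `m_total`, `n_segments`.
#' @examples
#' fams <- cohort_pedigrees()
#' gmap <- build_genetic_map(grch37_autosomes(), 35.3)
#' genome_sharing_probability(fams$fam1, affected_members(fams$fam1), gmap)
#' @export
genome_sharing_probability <- function(ped, targets, map,
                                       model = c("binomial", "poisson"),
                                       ...) {
  model <- match.arg(model)
  p <- point_sharing_probability(ped, targets, ...)
  m <- attr(p, "m_total")
  n_seg <- nrow(map$chrom) + m * map$rho_total
  p <- as.numeric(p)
  out <- if (model == "binomial") 1 - (1 - p)^n_seg else 1 - exp(-p * n_seg)
  structure(out, p_point = p, m_total = m, n_segments = n_seg)
}

#' Monte-Carlo estimate of the genome-wide sharing probability
#'
#' Runs [gene_drop()] with founder-haplotype tracking and reports the
#' fraction of simulations in which at least one genomic interval is carried
#' identically by descent by every target, with its binomial standard error.
#' Serves as the independent oracle for [genome_sharing_probability()].
#'
#' @param ped a `fam_pedigree`.
#' @param targets character vector of >= 2 member ids.
#' @param map a `genetic_map`.
#' @param n_sims number of gene-drop replicates (>= 100).
#' @param seed optional integer seed.
#' @return list with `estimate`, `se` and `n_sims`.
#' @export
gene_drop_sharing_mc <- function(ped, targets, map, n_sims = 2000,
                                 seed = NULL) {
  if (n_sims < 100) stop("n_sims must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (s in seq_len(n_sims)) {
    drop <- gene_drop(ped, map)
    if (any_shared_interval(drop, targets)) hits <- hits + 1L
  }
  est <- hits / n_sims
  list(estimate = est, se = sqrt(est * (1 - est) / n_sims), n_sims = n_sims)
}

# TRUE when some interval exists on which all targets carry a common founder
# haplotype
any_shared_interval <- function(drop, targets) {
  for (ci in seq_len(nrow(drop$map$chrom))) {
    tracks <- lapply(targets, function(t) drop$genomes[[t]][[ci]])
    ends <- sort(unique(unlist(lapply(tracks, function(tr)
      c(tr$h1[, 1L], tr$h2[, 1L])))))
    mids <- (c(0, ends[-length(ends)]) + ends) / 2
    lab <- lapply(tracks, function(tr)
      cbind(tr$h1[findInterval(mids, tr$h1[, 1L]) + 1L, 2L],
            tr$h2[findInterval(mids, tr$h2[, 1L]) + 1L, 2L]))
    cand <- lab[[1L]]
    ok1 <- rep(TRUE, length(mids)); ok2 <- ok1
    for (j in seq_along(lab)[-1L]) {
      ok1 <- ok1 & (lab[[j]][, 1L] == cand[, 1L] | lab[[j]][, 2L] == cand[, 1L])
      ok2 <- ok2 & (lab[[j]][, 1L] == cand[, 2L] | lab[[j]][, 2L] == cand[, 2L])
    }
    if (any(ok1 | ok2)) return(TRUE)
  }
  FALSE
}
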