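# Polygenic risk scores.  The score of a genome is the natural log of the
# product of the odds ratios of the risk alleles it carries: a homozygous
# risk variant contributes its odds ratio twice, a heterozygous one once,
# an absent one not at all.  Equivalently s = sum_i g_i * ln(OR_i) with g_i
# the risk-allele count.  CD and UC scores use the subtype-specific odds
# ratio lists.

#' Compute polygenic risk scores
#'
#' @param geno either a numeric matrix of risk-allele counts (rows named by
#'   `locus_id`, columns by sample) or a [variant_table()], in which case
#'   loci are matched by chromosome and position and the risk allele is
#'   oriented against ref/alt (risk allele equal to ref counts `2 - alt
#'   count`).  Missing genotypes contribute 0 risk alleles.
#' @param locus_table validated locus-weight table.
#' @param subtype `"CD"` or `"UC"`; loci without an odds ratio for the
#'   requested subtype are skipped.
#' @return named numeric vector of scores (natural-log scale, >= 0 when all
#'   odds ratios are >= 1); a genome with no risk alleles scores exactly 0.
#' @examples
#' lw <- nod2_loci()
#' g <- matrix(c(1, 0, 0), 3, 1, dimnames = list(lw$locus_id, "ind1"))
#' compute_prs(g, lw, "CD")  # ln(2.023)
#' @export
compute_prs <- function(geno, locus_table, subtype = c("CD", "UC")) {
  subtype <- match.arg(subtype)
  validate_locus_weights(locus_table)
  or_col <- if (subtype == "CD") locus_table$or_cd else locus_table$or_uc
  use <- !is.na(or_col)
  lw <- locus_table[use, , drop = FALSE]
  w <- log(or_col[use])
  counts <- risk_allele_counts(geno, lw)
  counts[is.na(counts)] <- 0L
  setNames(as.numeric(crossprod(counts, w)), colnames(counts))
}

# risk-allele count matrix (loci x samples) for the rows of `lw`
risk_allele_counts <- function(geno, lw) {
  if (inherits(geno, "variant_table")) {
    key <- paste(geno$variants$chrom, geno$variants$pos)
    idx <- match(paste(lw$chrom, lw$pos), key)
    counts <- matrix(0L, nrow(lw), ncol(geno$geno),
                     dimnames = list(lw$locus_id, colnames(geno$geno)))
    for (k in seq_len(nrow(lw))) {
      i <- idx[k]
      if (is.na(i)) next  # locus not genotyped: contributes 0
      if (lw$risk_allele[k] == geno$variants$alt[i]) {
        counts[k, ] <- geno$geno[i, ]
      } else if (lw$risk_allele[k] == geno$variants$ref[i]) {
        counts[k, ] <- 2L - geno$geno[i, ]
      } else {
        stop("risk allele of locus ", lw$locus_id[k],
             " matches neither ref nor alt")
      }
    }
    counts
  } else {
    idx <- match(lw$locus_id, rownames(geno))
    if (anyNA(idx))
      stop("loci absent from genotype matrix: ",
           paste(lw$locus_id[is.na(idx)], collapse = ", "))
    geno[idx, , drop = FALSE]
  }
}

#' Per-individual CD and UC risk score table
#'
#' @inheritParams compute_prs
#' @return data frame with columns `id`, `s_cd`, `s_uc`.
#' @export
risk_score_table <- function(geno, locus_table) {
  s_cd <- compute_prs(geno, locus_table, "CD")
  s_uc <- compute_prs(geno, locus_table, "UC")
  data.frame(id = names(s_cd), s_cd = as.numeric(s_cd),
             s_uc = as.numeric(s_uc), stringsAsFactors = FALSE)
}

#' Update a baseline risk through an odds ratio
#'
#' Converts a baseline disease risk to odds, multiplies by the odds ratio,
#' and converts back.  Carrying one NOD2 p.L1007fs allele (OR 3.99) lifts a
#' 0.25% background prevalence to about 1%.
#'
#' @param baseline_risk probability in (0, 1).
#' @param or odds ratio (> 0).
#' @return updated risk (probability).
#' @export
odds_update <- function(baseline_risk, or) {
  stopifnot(baseline_risk > 0, baseline_risk < 1, or > 0)
  o <- baseline_risk / (1 - baseline_risk) * or
  o / (1 + o)
}

#' One-sided Wilcoxon rank-sum test (cases stochastically greater)
#'
#' Mid-ranks for ties; exact permutation enumeration when
#' `n1 + n2 <= exact_limit` (default 12), otherwise a normal approximation
#' with tie correction and continuity correction.  When every value in both
#' groups is identical the test is degenerate and returns p = 1 with a
#' warning.
#'
#' @param cases,controls numeric vectors (both non-empty).
#' @param exact_limit sample-size bound for exhaustive enumeration.
#' @return list with `p_value`, `statistic` (case rank sum) and `method`.
#' @export
wilcoxon_one_sided <- function(cases, controls, exact_limit = 12L) {
  stopifnot(length(cases) > 0, length(controls) > 0)
  x <- c(cases, controls)
  n1 <- length(cases); n2 <- length(controls); n <- n1 + n2
  if (length(unique(x)) == 1L) {
    warning("degenerate data: all values identical; p = 1")
    return(list(p_value = 1, statistic = sum(rank(x)[seq_len(n1)]),
                method = "degenerate"))
  }
  r <- rank(x)  # mid-ranks
  w_obs <- sum(r[seq_len(n1)])
  if (n <= exact_limit) {
    sets <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[sets], nrow = n1))
    p <- mean(w_all >= w_obs - 1e-9)
    return(list(p_value = p, statistic = w_obs, method = "exact"))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(x)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (w_obs - mu - 0.5) / sqrt(sigma2)
  list(p_value = stats::pnorm(z, lower.tail = FALSE), statistic = w_obs,
       method = "normal")
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random case outscores a
#' random control, ties counting one half; identical to the trapezoidal
#' area under the empirical ROC curve.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector, `TRUE` = case; both classes must
#'   be present.
#' @return AUC in \eqn{[0, 1]}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both label classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Points of the empirical ROC curve
#'
#' @inheritParams roc_auc
#' @return data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Nagelkerke pseudo R-squared of a score for a binary outcome
#'
#' Fits intercept-only and intercept-plus-score logistic regressions by
#' iteratively reweighted least squares (convergence tolerance 1e-8) and
#' rescales the Cox-Snell likelihood-ratio R-squared,
#' \eqn{R^2_{CS} = 1 - (L_0/L_1)^{2/n}}, by its maximum
#' \eqn{1 - L_0^{2/n}} so the measure reaches 1.
#'
#' @inheritParams roc_auc
#' @return pseudo R-squared in \eqn{[0, 1]}.
#' @export
nagelkerke_r2 <- function(scores, labels) {
  labels <- as.logical(labels)
  n <- length(labels)
  if (n < 4) stop("need n >= 4")
  if (!any(labels) || all(labels)) stop("both label classes must be present")
  ctl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  f1 <- suppressWarnings(stats::glm(labels ~ scores, family = stats::binomial(),
                                    control = ctl))
  f0 <- stats::glm(labels ~ 1, family = stats::binomial(), control = ctl)
  if (!f1$converged || any(f1$fitted.values > 1 - 1e-10) ||
      any(f1$fitted.values < 1e-10))
    warning("possible separation: logistic fit at or near the boundary")
  ll1 <- as.numeric(stats::logLik(f1))
  ll0 <- as.numeric(stats::logLik(f0))
  r2_cs <- 1 - exp(2 / n * (ll0 - ll1))
  r2_max <- 1 - exp(2 / n * ll0)
  max(0, min(1, r2_cs / r2_max))
}
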