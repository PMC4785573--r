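# Parent-to-offspring transmission of polygenic risk, and per-family /
# case-control summaries.  Under random Mendelian transmission each
# parental risk allele passes with probability 1/2, so the expected
# offspring score is the mean of the two parental scores and the expected
# transmission ratio is 1; enrichment of ratios above 1 in affected
# offspring indicates over-transmission of risk alleles.

#' Transmission-ratio analysis of risk scores
#'
#' For every offspring with both parents scored, the expected score is the
#' parental mean and the transmission ratio is observed/expected.
#' Offspring with an expected score of 0 (ratio undefined) are excluded and
#' counted.  Affected (CD or UC) and unaffected offspring ratios are
#' compared with a Welch two-sided t-test.
#'
#' @param ped a `fam_pedigree` or list of them.
#' @param score_table data frame with columns `id` and the score column.
#' @param subtype `"CD"` or `"UC"`: selects score column `s_cd` or `s_uc`.
#' @return list with `records` (data frame: `id`, `family_id`, `affected`,
#'   `observed`, `expected`, `ratio`), `n_excluded`, `mean_ratio_affected`,
#'   `mean_ratio_unaffected` and `p_value` (`NA` when a group is empty or
#'   degenerate).
#' @export
transmission_analysis <- function(ped, score_table, subtype = c("CD", "UC")) {
  subtype <- match.arg(subtype)
  col <- if (subtype == "CD") "s_cd" else "s_uc"
  peds <- if (inherits(ped, "fam_pedigree")) list(ped) else ped
  s <- setNames(score_table[[col]], score_table$id)
  recs <- list()
  for (p in peds) {
    ok <- !is.na(p$father) & !is.na(p$mother) &
      p$id %in% score_table$id & p$father %in% score_table$id &
      p$mother %in% score_table$id
    for (i in which(ok)) {
      expected <- (s[[p$father[i]]] + s[[p$mother[i]]]) / 2
      recs[[length(recs) + 1L]] <- data.frame(
        id = p$id[i], family_id = p$family_id[i],
        affected = p$affection[i] %in% c("CD", "UC"),
        observed = s[[p$id[i]]], expected = expected,
        ratio = if (expected > 0) s[[p$id[i]]] / expected else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) stop("no offspring with both parents scored")
  records <- do.call(rbind, recs)
  n_excluded <- sum(is.na(records$ratio))
  kept <- records[!is.na(records$ratio), , drop = FALSE]
  ra <- kept$ratio[kept$affected]
  ru <- kept$ratio[!kept$affected]
  p_value <- if (length(ra) >= 2 && length(ru) >= 2 &&
                 (stats::sd(ra) > 0 || stats::sd(ru) > 0)) {
    stats::t.test(ra, ru, var.equal = FALSE)$p.value
  } else NA_real_
  list(records = records, n_excluded = n_excluded,
       mean_ratio_affected = if (length(ra)) mean(ra) else NA_real_,
       mean_ratio_unaffected = if (length(ru)) mean(ru) else NA_real_,
       p_value = p_value)
}

#' Per-family mean risk scores versus controls
#'
#' Means are taken over affected members only.  A family is flagged `low`
#' when both its subtype means fall below the respective control means
#' (the pattern of a family whose disease burden the known common variants
#' do not explain).
#'
#' @param families list of `fam_pedigree` objects.
#' @param score_table data frame with columns `id`, `s_cd`, `s_uc`.
#' @param control_scores data frame with columns `s_cd`, `s_uc` for the
#'   unrelated control panel.
#' @return data frame: `family_id`, `n_affected`, `mean_cd`, `mean_uc`,
#'   `control_mean_cd`, `control_mean_uc`, `low`.
#' @export
family_summary <- function(families, score_table, control_scores) {
  if (inherits(families, "fam_pedigree")) families <- list(families)
  cm_cd <- mean(control_scores$s_cd)
  cm_uc <- mean(control_scores$s_uc)
  rows <- lapply(families, function(p) {
    aff <- intersect(affected_members(p), score_table$id)
    if (!length(aff))
      stop("family ", p$family_id[1], " has no scored affected member")
    idx <- match(aff, score_table$id)
    m_cd <- mean(score_table$s_cd[idx])
    m_uc <- mean(score_table$s_uc[idx])
    data.frame(family_id = p$family_id[1], n_affected = length(aff),
               mean_cd = m_cd, mean_uc = m_uc,
               control_mean_cd = cm_cd, control_mean_uc = cm_uc,
               low = m_cd < cm_cd && m_uc < cm_uc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Case/control comparison report for one subtype
#'
#' Bundles the statistics of the published score comparison: group means,
#' one-sided Wilcoxon rank-sum p-value (cases greater), ROC AUC and the
#' Nagelkerke pseudo R-squared of a logistic regression of status on score.
#'
#' @param case_scores,control_scores numeric score vectors.
#' @return list with `mean_cases`, `mean_controls`, `p_wilcoxon`, `auc`,
#'   `r2_nagelkerke`, `n_cases`, `n_controls`.
#' @export
comparison_report <- function(case_scores, control_scores) {
  scores <- c(case_scores, control_scores)
  labels <- rep(c(TRUE, FALSE), c(length(case_scores),
                                  length(control_scores)))
  list(
    n_cases = length(case_scores),
    n_controls = length(control_scores),
    mean_cases = mean(case_scores),
    mean_controls = mean(control_scores),
    p_wilcoxon = wilcoxon_one_sided(case_scores, control_scores)$p_value,
    auc = roc_auc(scores, labels),
    r2_nagelkerke = nagelkerke_r2(scores, labels)
  )
}
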