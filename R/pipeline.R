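# End-to-end orchestration: simulate -> ibd -> filter -> prs -> report,
# driven by one JSON config.  Each stage reads and writes only standard
# formats (PED, VCF, BED, TSV, JSON), so stages are independently
# re-runnable from their on-disk inputs.

#' Default run configuration
#'
#' @param seed integer seed (required for any simulation step).
#' @param out_dir output directory.
#' @return nested list config with blocks `simulate`, `ibd`, `filter`,
#'   `prs`.
#' @export
default_run_config <- function(seed, out_dir = "famibd_out") {
  list(
    seed = seed,
    out_dir = out_dir,
    simulate = list(n_controls = 1096, n_cd = 140, n_uc = 133,
                    n_shared = 110, include_nod2 = TRUE, rho_total = 35.3,
                    n_rare_per_family = 2),
    ibd = list(min_support = 3, max_conflicts = 0, max_af = 0.03,
               families = c("fam1", "fam2")),
    filter = list(min_quality = 35, max_af = 0.03, max_gene_distance = 2),
    prs = list()
  )
}

read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  for (field in c("seed", "out_dir"))
    if (is.null(cfg[[field]]))
      stop("config schema error: missing required field '", field, "'")
  base <- default_run_config(cfg$seed, cfg$out_dir)
  for (block in c("simulate", "ibd", "filter", "prs")) {
    user <- cfg[[block]]
    merged <- base[[block]]
    for (k in names(user)) merged[[k]] <- user[[k]]
    cfg[[block]] <- merged
  }
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline
#'
#' Simulates the cohort, computes segment-sharing probabilities and shared
#' segments for the two deep families, filters candidate variants per
#' family, scores everyone, and writes a report bundle (score TSV, segment
#' BED, candidate TSV, ROC points TSV, report JSON) plus a reproducibility
#' manifest (config hash, package version, per-stage record counts).
#' Deterministic under a fixed seed.
#'
#' @param config config list (see [default_run_config()]) or path to a
#'   JSON file.
#' @return invisibly, the report list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  sim <- stage("simulate", {
    s <- config$simulate
    cohort <- simulate_cohort(seed = config$seed,
                              n_controls = s$n_controls, n_cd = s$n_cd,
                              n_uc = s$n_uc, n_shared = s$n_shared,
                              include_nod2 = s$include_nod2,
                              rho_total = s$rho_total,
                              n_rare_per_family = s$n_rare_per_family)
    write_pedigree(cohort$families, file.path(out, "cohort.ped"))
    write_vcf(cohort$family_vt, file.path(out, "families.vcf"))
    write_locus_weights(cohort$locus_table, file.path(out, "loci.tsv"))
    write.table(cohort$gene_panel, file.path(out, "gene_panel.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$variants <- nrow(cohort$family_vt$variants)
    counts$samples <- ncol(cohort$family_vt$geno)
    counts$controls <- ncol(cohort$control_geno)
    cohort
  })

  ibd_res <- stage("ibd", {
    cfg <- config$ibd
    sharing <- list()
    segs <- empty_segments()
    for (fam in intersect(cfg$families, names(sim$families))) {
      ped <- sim$families[[fam]]
      targets <- affected_members(ped)
      if (fam == "fam2") targets <- setdiff(targets, "2-V-1")
      gp <- genome_sharing_probability(ped, targets, sim$map)
      sharing[[fam]] <- list(targets = targets,
                             m_total = attr(gp, "m_total"),
                             p_point = attr(gp, "p_point"),
                             p_genome = as.numeric(gp))
      targets_typed <- intersect(targets, colnames(sim$family_vt$geno))
      if (length(targets_typed) >= 2) {
        s <- shared_segments(sim$family_vt, targets_typed,
                             min_support = cfg$min_support,
                             max_conflicts = cfg$max_conflicts,
                             max_af = cfg$max_af)
        if (nrow(s)) segs <- rbind(segs, s)
      }
    }
    write_bed(segs, file.path(out, "segments.bed"))
    counts$segments <- nrow(segs)
    list(sharing = sharing, segments = segs)
  })

  candidates <- stage("filter", {
    cfg <- config$filter
    all_calls <- list()
    for (fam in names(sim$families)) {
      ped <- sim$families[[fam]]
      req <- intersect(affected_members(ped), colnames(sim$family_vt$geno))
      if (length(req) < 1) next
      fc <- filter_config(required_carriers = req,
                          min_quality = cfg$min_quality,
                          max_af = cfg$max_af,
                          max_gene_distance = cfg$max_gene_distance)
      calls <- filter_variants(sim$family_vt, sim$gene_panel, fc, ped)
      if (nrow(calls)) {
        calls$family_id <- ped$family_id[1]
        all_calls[[fam]] <- calls
      }
    }
    cand <- if (length(all_calls)) do.call(rbind, all_calls) else NULL
    if (is.null(cand)) {
      cand <- data.frame()
      writeLines(paste("chrom", "pos", "ref", "alt", "gene", "zygosity",
                       "family_id", sep = "\t"),
                 file.path(out, "candidates.tsv"))
    } else {
      write_candidate_table(cand, file.path(out, "candidates.tsv"))
    }
    counts$candidates <- nrow(cand)
    cand
  })

  prs_res <- stage("prs", {
    fam_scores <- risk_score_table(sim$family_vt, sim$locus_table)
    ctl_scores <- risk_score_table(sim$control_geno, sim$locus_table)
    write.table(fam_scores, file.path(out, "scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    aff <- unlist(lapply(sim$families, affected_members))
    cd_ids <- unlist(lapply(sim$families, affected_members, subtype = "CD"))
    cd_ids <- intersect(cd_ids, fam_scores$id)
    uc_ids <- intersect(setdiff(aff, cd_ids), fam_scores$id)
    rep_cd <- comparison_report(
      fam_scores$s_cd[match(cd_ids, fam_scores$id)], ctl_scores$s_cd)
    rep_uc <- comparison_report(
      fam_scores$s_uc[match(uc_ids, fam_scores$id)], ctl_scores$s_uc)
    roc <- roc_points(c(fam_scores$s_cd[match(cd_ids, fam_scores$id)],
                        ctl_scores$s_cd),
                      rep(c(TRUE, FALSE), c(length(cd_ids),
                                            nrow(ctl_scores))))
    write.table(roc, file.path(out, "roc_points.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    trans <- transmission_analysis(sim$families, fam_scores, "CD")
    famsum <- family_summary(sim$families, fam_scores, ctl_scores)
    counts$scored <- nrow(fam_scores)
    list(cd = rep_cd, uc = rep_uc,
         transmission = trans[c("mean_ratio_affected",
                                "mean_ratio_unaffected", "p_value",
                                "n_excluded")],
         family_summary = famsum)
  })

  report <- stage("report", {
    hashed <- config[setdiff(names(config), "out_dir")]  # path-independent
    cfg_json <- jsonlite::toJSON(hashed, auto_unbox = TRUE, digits = NA)
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    manifest <- list(
      package = "famibd",
      version = as.character(utils::packageVersion("famibd")),
      config_md5 = unname(tools::md5sum(tmp)),
      seed = config$seed,
      counts = counts
    )
    unlink(tmp)
    rep <- list(manifest = manifest,
                sharing = ibd_res$sharing,
                prs = prs_res)
    jsonlite::write_json(rep, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    rep
  })
  invisible(report)
}
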