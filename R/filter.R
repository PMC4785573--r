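# Rare candidate-variant filtering: sequencing quality >= 35, population
# allele frequency <= 3%, a putative functional consequence, a gene within
# a bounded network distance of the disease concept, and carriage by all
# required affected family members under at least one zygosity model
# (shared heterozygous, recessive homozygous, compound heterozygous).

#' Read a gene-panel table (gene, distance)
#'
#' The panel abstracts a disease knowledge base as the node distance of
#' each gene to the disease concept: 0 = directly connected ("Direct"),
#' 1 = interacting with a directly connected gene, and so on.
#'
#' @param path TSV with columns `gene` and `distance`.
#' @return data frame with character `gene` and integer `distance`.
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gp <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_gene_panel(gp)
}

validate_gene_panel <- function(gp) {
  stopifnot(all(c("gene", "distance") %in% names(gp)))
  if (any(gp$distance < 0) || any(gp$distance != floor(gp$distance)))
    stop("distances must be non-negative integers")
  if (anyDuplicated(gp$gene)) stop("duplicate genes in panel")
  gp$distance <- as.integer(gp$distance)
  gp
}

#' Candidate-filter configuration
#'
#' Defaults mirror the published cascade: quality >= 35, allele frequency
#' <= 3%, consequence in the functional whitelist, gene within 2 network
#' nodes of the disease.
#'
#' @param required_carriers ids of affected members that must all carry a
#'   candidate.
#' @param min_quality minimum variant quality score.
#' @param max_af maximum population allele frequency.
#' @param consequences consequence whitelist.
#' @param max_gene_distance maximum gene panel distance.
#' @param zygosity_models subset of `c("het_shared", "hom_recessive",
#'   "compound_het")`.
#' @param cross_gene_comphet also pair compound hets across two genes
#'   (default off).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(required_carriers,
                          min_quality = 35,
                          max_af = 0.03,
                          consequences = c("loss_of_function", "missense",
                                           "splice", "mirna_binding",
                                           "promoter", "enhancer"),
                          max_gene_distance = 2L,
                          zygosity_models = c("het_shared", "hom_recessive",
                                              "compound_het"),
                          cross_gene_comphet = FALSE) {
  stopifnot(length(required_carriers) >= 1,
            min_quality >= 0, max_af >= 0, max_af <= 1,
            max_gene_distance >= 0)
  zygosity_models <- match.arg(zygosity_models, several.ok = TRUE)
  bad <- setdiff(consequences, CONSEQUENCE_LEVELS)
  if (length(bad)) stop("unknown consequence class(es): ",
                        paste(bad, collapse = ", "))
  structure(list(required_carriers = as.character(required_carriers),
                 min_quality = min_quality, max_af = max_af,
                 consequences = consequences,
                 max_gene_distance = as.integer(max_gene_distance),
                 zygosity_models = zygosity_models,
                 cross_gene_comphet = cross_gene_comphet),
            class = "filter_config")
}

#' Drop carriers from the required set
#'
#' Restricting the analysis to a subset of the affected members (for
#' example to CD patients only) relaxes the carriage requirement, so the
#' candidate set under the restricted configuration is always a superset
#' of the original on the same input.
#'
#' @param config a [filter_config()].
#' @param exclude_ids ids to drop; must be a subset of the required
#'   carriers and must not empty the set.
#' @return the modified `filter_config`.
#' @export
restrict_targets <- function(config, exclude_ids) {
  if (!length(exclude_ids)) return(config)
  bad <- setdiff(exclude_ids, config$required_carriers)
  if (length(bad)) stop("not required carriers: ", paste(bad, collapse = ", "))
  kept <- setdiff(config$required_carriers, exclude_ids)
  if (!length(kept)) stop("cannot exclude every required carrier")
  config$required_carriers <- kept
  config
}

carries <- function(geno_row, ids) {
  g <- geno_row[ids]
  !is.na(g) & g >= 1L
}

#' Classify the zygosity of one variant in a family
#'
#' `het`: every required affected is heterozygous.  `hom_recessive`: every
#' required affected is homozygous for the alternate allele while every
#' genotyped parent of a required affected is heterozygous.  Compound
#' heterozygotes are paired separately ([pair_compound_hets()]).  A variant
#' matching neither model returns `NA` (filtered out).
#'
#' @param geno_row named vector of allele counts for one variant.
#' @param required ids of required affected carriers.
#' @param ped the family `fam_pedigree` (parental genotypes for the
#'   recessive model).
#' @return `"het"`, `"hom"` or `NA_character_`.
#' @export
classify_zygosity <- function(geno_row, required, ped) {
  g <- geno_row[required]
  if (any(is.na(g))) return(NA_character_)
  if (all(g == 1L)) return("het")
  if (all(g == 2L)) {
    parents <- unique(unlist(ped[ped$id %in% required, c("father", "mother")]))
    parents <- parents[!is.na(parents)]
    parents <- intersect(parents, names(geno_row)[!is.na(geno_row)])
    if (all(geno_row[parents] == 1L)) return("hom")
  }
  NA_character_
}

# phase of a variant pair in one individual: "trans", "cis" or "unknown"
pair_phase <- function(g1, g2, ind, ped) {
  row <- ped[ped$id == ind, ]
  f <- row$father; m <- row$mother
  if (is.na(f) || is.na(m) || !(f %in% names(g1)) || !(m %in% names(g1)))
    return("unknown")
  cf1 <- isTRUE(carries(g1, f)); cf2 <- isTRUE(carries(g2, f))
  cm1 <- isTRUE(carries(g1, m)); cm2 <- isTRUE(carries(g2, m))
  if (any(is.na(g1[c(f, m)])) || any(is.na(g2[c(f, m)]))) return("unknown")
  # trans: one variant from each parent
  if ((cf1 && !cf2 && cm2 && !cm1) || (cf2 && !cf1 && cm1 && !cm2))
    return("trans")
  # cis: both variants carried by exactly one parent and absent in the other
  if ((cf1 && cf2 && !cm1 && !cm2) || (cm1 && cm2 && !cf1 && !cf2))
    return("cis")
  "unknown"
}

#' Pair compound-heterozygous candidates within a gene
#'
#' Two heterozygous candidate variants pair in an affected individual who
#' carries both.  Parental genotypes prove trans phase when each parent
#' carries exactly one of the two variants; a pair proven trans in at least
#' one affected carrier (and cis in none) is classed `comp_het`, otherwise
#' `comp_het_unphased` (rendered "Comp-het?").  Pairing is symmetric.
#'
#' @param idx integer indices (into `vt`) of surviving het variants of one
#'   gene.
#' @param vt the [variant_table()].
#' @param required ids of required affected carriers.
#' @param ped the family pedigree.
#' @return data frame with columns `i`, `j`, `class`, `carriers`
#'   (comma-joined affected carriers of the pair); zero rows when nothing
#'   pairs.
#' @export
pair_compound_hets <- function(idx, vt, required, ped) {
  out <- list()
  if (length(idx) < 2) {
    return(data.frame(i = integer(0), j = integer(0),
                      class = character(0), carriers = character(0),
                      stringsAsFactors = FALSE))
  }
  for (a in seq_along(idx)[-length(idx)]) {
    for (b in seq(a + 1, length(idx))) {
      g1 <- vt$geno[idx[a], ]; g2 <- vt$geno[idx[b], ]
      both <- required[carries(g1, required) & carries(g2, required)]
      if (!length(both)) next
      phases <- vapply(both, function(ind) pair_phase(g1, g2, ind, ped),
                       character(1))
      if (any(phases == "cis")) next
      cls <- if (any(phases == "trans")) "comp_het" else "comp_het_unphased"
      out[[length(out) + 1L]] <- data.frame(
        i = idx[a], j = idx[b], class = cls,
        carriers = paste(both, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(0), j = integer(0),
                      class = character(0), carriers = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Filter variants to family candidate calls
#'
#' A variant survives iff (i) quality >= `min_quality`, (ii) population
#' allele frequency <= `max_af`, (iii) consequence in the whitelist,
#' (iv) its gene sits within `max_gene_distance` nodes of the disease in
#' the panel, and (v) it passes at least one enabled zygosity model with
#' every required carrier carrying.  Unaffected carriers never disqualify
#' a candidate.  Output is sorted by (chrom, pos).
#'
#' @param vt a [variant_table()] of the family's genotypes.
#' @param gene_panel data frame (`gene`, `distance`).
#' @param config a [filter_config()].
#' @param ped the family `fam_pedigree`.
#' @return data frame of candidate calls: `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`, `pop_af`, `quality`, `zygosity`, `partners`,
#'   `carriers`, `affected_carriers`, `gene_distance`.
#' @export
filter_variants <- function(vt, gene_panel, config, ped) {
  gene_panel <- validate_gene_panel(gene_panel)
  req <- config$required_carriers
  absent <- setdiff(req, colnames(vt$geno))
  if (length(absent))
    stop("required carrier(s) not genotyped: ", paste(absent, collapse = ", "))
  v <- vt$variants
  dist <- gene_panel$distance[match(v$gene, gene_panel$gene)]
  site_ok <- v$quality >= config$min_quality &
    v$pop_af <= config$max_af &
    v$consequence %in% config$consequences &
    !is.na(dist) & dist <= config$max_gene_distance
  all_carry <- apply(vt$geno[, req, drop = FALSE], 1,
                     function(g) all(!is.na(g) & g >= 1L))
  affected_ids <- intersect(affected_members(ped), colnames(vt$geno))
  calls <- list()
  add_call <- function(i, zyg, partners = "") {
    carr <- colnames(vt$geno)[!is.na(vt$geno[i, ]) & vt$geno[i, ] >= 1L]
    calls[[length(calls) + 1L]] <<- data.frame(
      chrom = v$chrom[i], pos = v$pos[i], ref = v$ref[i], alt = v$alt[i],
      gene = v$gene[i], consequence = v$consequence[i],
      pop_af = v$pop_af[i], quality = v$quality[i],
      zygosity = zyg, partners = partners,
      carriers = paste(carr, collapse = ","),
      affected_carriers = paste(intersect(carr, affected_ids),
                                collapse = ","),
      gene_distance = dist[i], stringsAsFactors = FALSE)
  }
  simple_idx <- which(site_ok & all_carry)
  for (i in simple_idx) {
    z <- classify_zygosity(vt$geno[i, ], req, ped)
    if (is.na(z)) next
    if (z == "het" && "het_shared" %in% config$zygosity_models) add_call(i, "het")
    if (z == "hom" && "hom_recessive" %in% config$zygosity_models) add_call(i, "hom")
  }
  if ("compound_het" %in% config$zygosity_models) {
    het_ok <- which(site_ok & !is.na(v$gene))
    by_gene <- split(het_ok, v$gene[het_ok])
    for (gn in names(by_gene)) {
      idx <- by_gene[[gn]]
      pairs <- pair_compound_hets(idx, vt, req, ped)
      if (!nrow(pairs)) next
      # the gene qualifies when every required affected carries >= 1 pair
      covered <- unique(unlist(strsplit(pairs$carriers, ",")))
      if (!all(req %in% covered)) next
      vid <- function(i) paste0(v$chrom[i], ":", v$pos[i], ":", v$alt[i])
      for (k in seq_len(nrow(pairs))) {
        add_call(pairs$i[k], pairs$class[k], partners = vid(pairs$j[k]))
        add_call(pairs$j[k], pairs$class[k], partners = vid(pairs$i[k]))
      }
    }
  }
  if (!length(calls)) {
    return(data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      gene = character(0), consequence = character(0),
                      pop_af = numeric(0), quality = numeric(0),
                      zygosity = character(0), partners = character(0),
                      carriers = character(0),
                      affected_carriers = character(0),
                      gene_distance = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  out <- out[!duplicated(out[, c("chrom", "pos", "alt", "zygosity",
                                 "partners")]), , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate candidate presence in other families
#'
#' Post-hoc annotation (never a filter): for each candidate, which other
#' families contain at least one carrier.
#'
#' @param candidates output of [filter_variants()].
#' @param vt a [variant_table()] covering all cohort samples.
#' @param sample_families named character vector mapping sample id to
#'   family id.
#' @param own_family the family the candidates belong to.
#' @return `candidates` with an extra `other_families` column.
#' @export
annotate_presence <- function(candidates, vt, sample_families, own_family) {
  key <- paste(vt$variants$chrom, vt$variants$pos, vt$variants$alt)
  idx <- match(paste(candidates$chrom, candidates$pos, candidates$alt), key)
  candidates$other_families <- vapply(idx, function(i) {
    if (is.na(i)) return("")
    carr <- colnames(vt$geno)[!is.na(vt$geno[i, ]) & vt$geno[i, ] >= 1L]
    fams <- setdiff(unique(sample_families[carr]), c(own_family, NA))
    paste(sort(fams), collapse = ",")
  }, character(1))
  candidates
}

#' Write candidate calls as a TSV
#'
#' @param candidates output of [filter_variants()].
#' @param path output path.
#' @param method method tag column value (`"genome-wide"` or
#'   `"identical-by-descent"`).
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path, method = "genome-wide") {
  out <- candidates
  out$method <- method
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
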