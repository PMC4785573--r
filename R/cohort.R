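# Synthetic cohort emulating the study's statistical structure: the five
# reconstructed pedigrees with genotypes dropped from founder haplotypes,
# common risk loci with published-scale odds ratios, family-private rare
# variants, and an unrelated control panel.  Everything is deterministic
# under a fixed seed.

#' Simulate the five-family cohort with controls
#'
#' Gene-drops founder haplotypes through the [cohort_pedigrees()] on a
#' genetic map (default: 22 GRCh37 autosomes recombining at 35.3 crossovers
#' per meiosis), genotypes the sequenced members at the common risk loci
#' (risk-allele frequencies uniform on 0.1--0.5, typical of genome-wide
#' association loci) and at family-private rare variants injected into one
#' founder per family, and draws an unrelated Hardy-Weinberg control panel.
#' Variant annotations (quality, population frequency, consequence class,
#' gene, with genes mapped to a synthetic disease panel) make the output
#' directly consumable by the filtering and scoring stages.
#'
#' @param seed integer seed (required: the cohort is a simulation).
#' @param n_controls size of the unrelated control panel (study: 1,096).
#' @param n_cd,n_uc,n_shared locus-list sizes (study: 140/133/110).
#' @param include_nod2 add the three NOD2 CD loci (default TRUE).
#' @param rho_total genome-wide crossovers per meiosis (default 35.3).
#' @param map genetic map; default GRCh37 autosomes.
#' @param n_rare_per_family family-private rare variants planted per family.
#' @return list with `families` (pedigrees), `map`, `locus_table`,
#'   `gene_panel`, `founder_model`, `family_vt` (a [variant_table()] over
#'   the 38 sequenced members), `control_geno` (risk-allele count matrix),
#'   `drops` (per-family `gene_drop` objects) and `sample_families`.
#' @export
simulate_cohort <- function(seed,
                            n_controls = 1096,
                            n_cd = 140, n_uc = 133, n_shared = 110,
                            include_nod2 = TRUE,
                            rho_total = 35.3,
                            map = build_genetic_map(grch37_autosomes(),
                                                    rho_total),
                            n_rare_per_family = 2L) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  set.seed(seed)
  fams <- cohort_pedigrees()
  lw <- make_locus_table(n_cd, n_uc, n_shared, include_nod2 = include_nod2,
                         map = map)
  common <- data.frame(locus_id = lw$locus_id, chrom = lw$chrom,
                       pos = lw$pos, ref = "G", alt = lw$risk_allele,
                       freq = runif(nrow(lw), 0.1, 0.5),
                       stringsAsFactors = FALSE)
  # synthetic disease gene panel + private rare variants, one founder each
  panel_genes <- sprintf("GENE%03d", 1:60)
  gene_panel <- data.frame(gene = panel_genes,
                           distance = rep(0:3, 15)[1:60],
                           stringsAsFactors = FALSE)
  rare_rows <- list(); rare_inj <- list()
  for (fi in seq_along(fams)) {
    ped <- fams[[fi]]
    # plant on a founder with affected descendants (or an affected founder
    # parent in the nuclear families) so candidates can descend
    fnd <- founders(ped)
    aff <- affected_members(ped)
    anc_of_aff <- unique(unlist(lapply(aff, function(a)
      ancestor_closure(ped, a))))
    carriers <- intersect(fnd, c(aff, anc_of_aff))
    for (k in seq_len(n_rare_per_family)) {
      ci <- sample.int(nrow(map$chrom), 1, prob = map$chrom$length)
      id <- sprintf("rare_f%d_%d", fi, k)
      rare_rows[[length(rare_rows) + 1L]] <- data.frame(
        locus_id = id, chrom = map$chrom$chrom[ci],
        pos = floor(runif(1, 1, map$chrom$length[ci])) + 1,
        ref = "C", alt = "T", freq = 0,
        stringsAsFactors = FALSE)
      rare_inj[[length(rare_inj) + 1L]] <- data.frame(
        locus_id = id, carrier = sample(carriers, 1),
        stringsAsFactors = FALSE)
    }
  }
  loci <- rbind(common, do.call(rbind, rare_rows))
  fm <- founder_model(loci, do.call(rbind, rare_inj))
  drops <- list(); geno_cols <- list(); sample_families <- character(0)
  for (fi in seq_along(fams)) {
    ped <- fams[[fi]]
    drop <- gene_drop(ped, map)
    fa <- draw_founder_alleles(fm, drop$founder_haps)
    g <- drop_genotypes(drop, loci, fa)
    keep <- ped$id[ped$sequenced]
    drops[[names(fams)[fi]]] <- drop
    geno_cols[[fi]] <- g[, keep, drop = FALSE]
    sample_families <- c(sample_families,
                         setNames(rep(ped$family_id[1], length(keep)), keep))
  }
  geno <- do.call(cbind, geno_cols)
  rownames(geno) <- loci$locus_id
  is_rare <- loci$freq == 0
  variants <- data.frame(
    chrom = loci$chrom, pos = loci$pos, ref = loci$ref, alt = loci$alt,
    quality = round(runif(nrow(loci), 30, 70), 1),
    pop_af = ifelse(is_rare, round(runif(nrow(loci), 0, 0.02), 4),
                    round(loci$freq, 4)),
    consequence = ifelse(is_rare,
                         sample(c("missense", "loss_of_function", "splice"),
                                nrow(loci), replace = TRUE),
                         sample(CONSEQUENCE_LEVELS, nrow(loci),
                                replace = TRUE)),
    gene = ifelse(is_rare, sample(panel_genes[gene_panel$distance <= 2],
                                  nrow(loci), replace = TRUE),
                  sample(c(panel_genes, sprintf("OTH%03d", 1:200)),
                         nrow(loci), replace = TRUE)),
    stringsAsFactors = FALSE)
  family_vt <- variant_table(variants, geno)
  control_geno <- simulate_controls(n_controls, fm)
  list(families = fams, map = map, locus_table = lw,
       gene_panel = gene_panel, founder_model = fm,
       family_vt = family_vt, control_geno = control_geno,
       drops = drops, sample_families = sample_families)
}

#' Simulate nuclear families for transmission analyses
#'
#' Gene-drops `n_families` families of two founder parents and
#' `n_offspring` children on `map`, genotypes everyone at the loci of
#' `locus_table` (risk-allele frequencies from `freq`), and returns the
#' per-individual risk scores with pedigree bookkeeping -- the workhorse
#' for the transmission-ratio null (expected ratio 1 under random
#' Mendelian transmission) and for parameter-recovery simulations.
#'
#' @param n_families number of families (>= 1).
#' @param locus_table locus-weight table for scoring.
#' @param freq risk-allele frequencies (recycled over loci).
#' @param map genetic map (default: 2 chromosomes, rho 2; transmission
#'   statistics do not depend on map scale).
#' @param n_offspring children per family.
#' @param seed integer seed.
#' @return list with `peds` (list of pedigrees), `scores` (data frame
#'   `id`, `s_cd`, `s_uc`) and `geno` (risk-allele counts, loci x samples).
#' @export
simulate_nuclear_families <- function(n_families, locus_table,
                                      freq = 0.3,
                                      map = uniform_map(2, 1.25e8, 2),
                                      n_offspring = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_locus_weights(locus_table)
  loci <- data.frame(locus_id = locus_table$locus_id,
                     chrom = locus_table$chrom, pos = locus_table$pos,
                     freq = rep_len(freq, nrow(locus_table)),
                     stringsAsFactors = FALSE)
  # place loci on the simulation map irrespective of their nominal genome
  # coordinates: spread uniformly over chromosomes
  ci <- rep_len(seq_len(nrow(map$chrom)), nrow(loci))
  loci$chrom <- map$chrom$chrom[ci]
  loci$pos <- floor(seq(1, min(map$chrom$length) - 1,
                        length.out = nrow(loci))) + 0
  fm <- founder_model(loci)
  peds <- list(); cols <- list()
  for (f in seq_len(n_families)) {
    ids <- sprintf("f%d_%s", f, c("p1", "p2", paste0("o", seq_len(n_offspring))))
    ped <- pedigree(sprintf("fam%d", f), ids,
                    father = c(NA, NA, rep(ids[1], n_offspring)),
                    mother = c(NA, NA, rep(ids[2], n_offspring)),
                    sex = c("male", "female", rep("unknown", n_offspring)))
    drop <- gene_drop(ped, map)
    fa <- draw_founder_alleles(fm, drop$founder_haps)
    cols[[f]] <- drop_genotypes(drop, loci, fa)
    peds[[f]] <- ped
  }
  geno <- do.call(cbind, cols)
  rownames(geno) <- loci$locus_id
  lw2 <- locus_table
  lw2$chrom <- loci$chrom; lw2$pos <- loci$pos
  scores <- risk_score_table(geno, lw2)
  list(peds = peds, scores = scores, geno = geno)
}
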