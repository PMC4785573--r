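# Locus-weight tables: the published common risk loci with their
# subtype-specific odds ratios, which are the per-locus weights of the
# polygenic risk score.

#' The three NOD2 loss-of-function CD risk loci
#'
#' Odds ratios for the well-characterized NOD2 coding variants p.R702W
#' (2.023), p.G908R (3.500) and p.L1007fs (4.255), derived from reported
#' case/control frequencies in European populations.  These CD-specific
#' loci supplement the genome-wide association lists.
#'
#' @param chrom,pos_start placement of the three loci (defaults on chr16,
#'   the NOD2 locus region).
#' @return locus-weight data frame with three rows.
#' @export
nod2_loci <- function(chrom = "chr16", pos_start = 50745926) {
  data.frame(
    locus_id = c("NOD2_R702W", "NOD2_G908R", "NOD2_L1007fs"),
    chrom = chrom,
    pos = pos_start + c(0L, 10000L, 20000L),
    risk_allele = "A",
    or_cd = c(2.023, 3.500, 4.255),
    or_uc = NA_real_,
    stringsAsFactors = FALSE
  )
}

validate_locus_weights <- function(lw) {
  req <- c("locus_id", "chrom", "pos", "risk_allele", "or_cd", "or_uc")
  missing_cols <- setdiff(req, names(lw))
  if (length(missing_cols))
    stop("locus table missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(lw$locus_id))
    stop("duplicate locus ids: ",
         paste(unique(lw$locus_id[duplicated(lw$locus_id)]), collapse = ", "))
  if (any(is.na(lw$or_cd) & is.na(lw$or_uc)))
    stop("every locus needs at least one of or_cd / or_uc")
  if (any(c(lw$or_cd, lw$or_uc) <= 0, na.rm = TRUE))
    stop("validation error: odds ratios must be strictly positive")
  invisible(lw)
}

#' Read a locus-weight TSV
#'
#' Expected columns: `locus_id`, `chrom`, `pos`, `risk_allele`, `or_cd`,
#' `or_uc`; an empty cell means the locus carries no odds ratio for that
#' subtype.  Duplicate locus ids and non-positive odds ratios are rejected.
#'
#' @param path path to the TSV.
#' @return validated locus-weight data frame.
#' @export
read_locus_weights <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lw <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = c("", "NA"))
  lw$or_cd <- suppressWarnings(as.numeric(lw$or_cd))
  lw$or_uc <- suppressWarnings(as.numeric(lw$or_uc))
  validate_locus_weights(lw)
  lw
}

#' Write a locus-weight TSV
#' @param lw locus-weight data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_weights <- function(lw, path) {
  validate_locus_weights(lw)
  out <- lw
  out$or_cd <- ifelse(is.na(lw$or_cd), "", format(lw$or_cd, trim = TRUE))
  out$or_uc <- ifelse(is.na(lw$or_uc), "", format(lw$or_uc, trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a synthetic locus-weight table
#'
#' Creates `n_cd` loci with a CD odds ratio and `n_uc` loci with a UC odds
#' ratio, of which `n_shared` carry both (subtype-specific values drawn
#' independently), mirroring the published bookkeeping of 140 CD / 133 UC /
#' 110 shared loci whose union counts 163.  Optionally appends the three
#' NOD2 CD loci.  Loci are placed uniformly over the map's chromosomes,
#' proportionally to length.
#'
#' @param n_cd,n_uc,n_shared list sizes (`n_shared <= min(n_cd, n_uc)`).
#' @param or_sampler function(n) returning n odds ratios; the default draws
#'   uniformly from 1.05--1.35, the effect-size range typical of genome-wide
#'   association loci for IBD.
#' @param include_nod2 append the [nod2_loci()] rows.
#' @param map a `genetic_map` used to place loci.
#' @param seed optional integer seed.
#' @return validated locus-weight data frame.
#' @export
make_locus_table <- function(n_cd = 140, n_uc = 133, n_shared = 110,
                             or_sampler = function(n) runif(n, 1.05, 1.35),
                             include_nod2 = FALSE,
                             map = build_genetic_map(grch37_autosomes(),
                                                     35.3),
                             seed = NULL) {
  if (n_shared > min(n_cd, n_uc))
    stop("n_shared must not exceed min(n_cd, n_uc)")
  if (!is.null(seed)) set.seed(seed)
  n <- n_cd + n_uc - n_shared
  ci <- sample.int(nrow(map$chrom), n, replace = TRUE,
                   prob = map$chrom$length)
  pos <- floor(runif(n, 1, map$chrom$length[ci])) + 1
  kind <- c(rep("both", n_shared), rep("cd", n_cd - n_shared),
            rep("uc", n_uc - n_shared))
  lw <- data.frame(
    locus_id = sprintf("locus_%03d", seq_len(n)),
    chrom = map$chrom$chrom[ci],
    pos = pos,
    risk_allele = "A",
    or_cd = ifelse(kind %in% c("both", "cd"), or_sampler(n), NA_real_),
    or_uc = ifelse(kind %in% c("both", "uc"), or_sampler(n), NA_real_),
    stringsAsFactors = FALSE
  )
  if (include_nod2) lw <- rbind(lw, nod2_loci())
  validate_locus_weights(lw)
  lw
}
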