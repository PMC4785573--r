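# VCF input/output.  Reading goes through VariantAnnotation (the reference
# parser); multi-allelic sites are split into bi-allelic records so that
# frequency and genotype filters act per alternate allele.  Writing emits
# minimal deterministic VCF 4.2 text.
#
# In-memory representation: a `variant_table`, i.e. a list of
#   variants: data.frame(chrom, pos (1-based), ref, alt, quality, pop_af,
#                        consequence, gene)
#   geno:     integer matrix (variants x samples) of alternate-allele
#             counts 0/1/2, NA = missing genotype

CONSEQUENCE_LEVELS <- c("loss_of_function", "missense", "splice",
                        "mirna_binding", "promoter", "enhancer",
                        "noncoding_other")

#' Construct a variant table
#'
#' @param variants data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `quality`, `pop_af`, `consequence`, `gene` (`NA` allowed).
#' @param geno integer matrix of per-sample alternate-allele counts
#'   (0, 1, 2 or `NA`), one row per variant.
#' @return object of class `variant_table`.
#' @export
variant_table <- function(variants, geno) {
  stopifnot(is.data.frame(variants), is.matrix(geno),
            nrow(variants) == nrow(geno))
  req <- c("chrom", "pos", "ref", "alt", "quality", "pop_af", "consequence",
           "gene")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols))
    stop("variant table missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(variants$pos < 1)) stop("positions are 1-based (pos >= 1)")
  variants$pos <- as.integer(variants$pos)
  variants$quality <- as.numeric(variants$quality)
  variants$pop_af <- as.numeric(variants$pop_af)
  if (any(variants$quality < 0, na.rm = TRUE)) stop("quality must be >= 0")
  if (any(variants$pop_af < 0 | variants$pop_af > 1, na.rm = TRUE))
    stop("pop_af must lie in [0, 1]")
  bad_csq <- setdiff(stats::na.omit(unique(variants$consequence)),
                     CONSEQUENCE_LEVELS)
  if (length(bad_csq))
    stop("unknown consequence class(es): ", paste(bad_csq, collapse = ", "))
  bad_gt <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad_gt)) stop("allele counts must be 0, 1, 2 or NA")
  structure(list(variants = variants, geno = geno), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d variant(s) x %d sample(s)\n",
              nrow(x$variants), ncol(x$geno)))
  invisible(x)
}

parse_gt_counts <- function(gt, alt_index) {
  # gt: character vector like "0/1", "1|1", "./.", "."; count of alt_index
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (all(a %in% c(".", ""))) return(NA_integer_)
    sum(a == as.character(alt_index))
  }, integer(1))
}

info_field <- function(vals, i, j) {
  # i-th row, j-th alternate allele of a possibly per-allele INFO column
  v <- if (is.list(vals) || inherits(vals, "List")) vals[[i]] else vals[i]
  if (length(v) == 0L || all(is.na(v))) return(NA)
  if (length(v) >= j) v[j] else v[1L]
}

#' Read a VCF into a variant table
#'
#' Wraps `VariantAnnotation::readVcf`.  Positions stay 1-based; missing
#' genotypes stay missing; multi-allelic rows are split into one bi-allelic
#' record per alternate allele (allele counts are recomputed against each
#' alternate).  INFO keys carrying the population allele frequency, the
#' consequence class and the gene symbol are configurable.
#'
#' @param path path to a (plain-text or bgzipped) VCF.
#' @param af_key,csq_key,gene_key INFO field names (defaults `"AF"`,
#'   `"CSQ"`, `"GENE"`).
#' @return a [variant_table()].
#' @export
read_vcf <- function(path, af_key = "AF", csq_key = "CSQ",
                     gene_key = "GENE") {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  gmat <- VariantAnnotation::geno(vcf)
  if (!"GT" %in% names(gmat))
    stop("format error: VCF has no GT FORMAT field")
  gt <- gmat$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  qual <- VariantAnnotation::qual(vcf)
  inf <- VariantAnnotation::info(vcf)
  has <- function(k) k %in% names(inf)
  rows <- list(); genos <- list(); r <- 0L
  for (i in seq_len(length(vcf))) {
    a_i <- as.character(alts[[i]])
    for (j in seq_along(a_i)) {
      r <- r + 1L
      af <- if (has(af_key)) info_field(inf[[af_key]], i, j) else NA
      af <- suppressWarnings(as.numeric(af))
      if (has(af_key) && !is.na(info_field(inf[[af_key]], i, j)) && is.na(af))
        stop("parse error: malformed ", af_key, " at record ", i)
      rows[[r]] <- data.frame(
        chrom = chrom[i], pos = pos[i], ref = refs[i], alt = a_i[j],
        quality = ifelse(is.na(qual[i]), 0, qual[i]),
        pop_af = ifelse(is.na(af), 0, af),
        consequence = as.character(
          if (has(csq_key)) info_field(inf[[csq_key]], i, j)
          else NA_character_),
        gene = as.character(
          if (has(gene_key)) info_field(inf[[gene_key]], i, j)
          else NA_character_),
        stringsAsFactors = FALSE)
      genos[[r]] <- parse_gt_counts(gt[i, ], j)
    }
  }
  variants <- do.call(rbind, rows)
  geno <- do.call(rbind, genos)
  colnames(geno) <- colnames(gt)
  rownames(geno) <- NULL
  variant_table(variants, geno)
}

#' Write a variant table as VCF 4.2
#'
#' Inverse of [read_vcf()]: bi-allelic records, INFO keys `AF`, `CSQ`,
#' `GENE`, genotypes encoded `0/0`, `0/1`, `1/1` or `./.`.  Round-trips
#' through [read_vcf()] without coordinate shift.
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  v <- vt$variants
  samples <- colnames(vt$geno)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(vt$geno)))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  ord <- order(v$chrom, v$pos, v$alt)
  body <- vapply(ord, function(i) {
    info <- sprintf("AF=%s;CSQ=%s;GENE=%s",
                    format(v$pop_af[i], scientific = FALSE, trim = TRUE),
                    ifelse(is.na(v$consequence[i]), ".", v$consequence[i]),
                    ifelse(is.na(v$gene[i]), ".", v$gene[i]))
    g <- vt$geno[i, ]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i],
            format(v$quality[i], trim = TRUE), "PASS", info, "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
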