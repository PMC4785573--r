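# Shared-segment container and BED3+ serialization.  All internal intervals
# are 0-based half-open (BED convention); user-facing VCF positions are
# 1-based, so a VCF position p lies in a segment when start <= p-1 < end.

#' Construct shared identical-by-descent segments
#'
#' @param chrom character vector of chromosome labels.
#' @param start,end 0-based half-open interval bounds (`start < end`).
#' @param carriers list (or comma-joined character vector) of carrier id
#'   sets, one per segment; non-empty.
#' @param support integer count of informative sites supporting each
#'   segment.
#' @return data frame of class `shared_segments`.
#' @export
shared_segments_table <- function(chrom, start, end, carriers,
                                  support = NA_integer_) {
  if (is.character(carriers)) carriers <- strsplit(carriers, ",")
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n, length(carriers) == n)
  if (any(start >= end)) stop("segment start must be < end")
  if (any(lengths(carriers) == 0L)) stop("carriers must be non-empty")
  seg <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), stringsAsFactors = FALSE)
  seg$carriers <- lapply(carriers, function(x) sort(unique(as.character(x))))
  seg$support <- rep_len(as.integer(support), n)
  class(seg) <- c("shared_segments", "data.frame")
  seg
}

empty_segments <- function() {
  seg <- data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), stringsAsFactors = FALSE)
  seg$carriers <- list()
  seg$support <- integer(0)
  class(seg) <- c("shared_segments", "data.frame")
  seg
}

# merge overlapping or abutting segments with identical carrier sets
merge_segments <- function(seg) {
  if (nrow(seg) == 0L) return(seg)
  key <- paste(seg$chrom, vapply(seg$carriers, paste, character(1),
                                 collapse = ","))
  out <- lapply(split(seq_len(nrow(seg)), key), function(idx) {
    s <- seg[idx, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    merged <- list(); cur <- s[1, , drop = FALSE]
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start[i] <= cur$end) {
        cur$end <- max(cur$end, s$end[i])
        cur$support <- cur$support + s$support[i]
      } else {
        merged <- c(merged, list(cur)); cur <- s[i, , drop = FALSE]
      }
    }
    do.call(rbind, c(merged, list(cur)))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("shared_segments", "data.frame")
  res
}

#' Write shared segments as BED3+
#'
#' Emits 0-based half-open BED lines with the carrier set comma-joined in
#' column 4 and the support count in column 5.  Overlapping or abutting
#' segments with identical carriers are merged, never duplicated.  An empty
#' segment list yields a file holding only the header comment.
#'
#' @param seg a `shared_segments` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(seg, path) {
  seg <- merge_segments(seg)
  lines <- "#chrom\tstart\tend\tcarriers\tsupport"
  if (nrow(seg)) {
    lines <- c(lines, sprintf(
      "%s\t%s\t%s\t%s\t%s",
      seg$chrom,
      format(seg$start, scientific = FALSE, trim = TRUE),
      format(seg$end, scientific = FALSE, trim = TRUE),
      vapply(seg$carriers, paste, character(1), collapse = ","),
      ifelse(is.na(seg$support), ".", as.character(seg$support))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3+ segment file written by [write_bed()]
#'
#' @param path path to the BED file.
#' @return a `shared_segments` table (0-based half-open coordinates).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(empty_segments())
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 3)) stop("parse error: BED needs >= 3 columns")
  chrom <- vapply(parts, `[`, character(1), 1)
  start <- as.numeric(vapply(parts, `[`, character(1), 2))
  end <- as.numeric(vapply(parts, `[`, character(1), 3))
  carriers <- vapply(parts, function(p) if (length(p) >= 4) p[4] else "",
                     character(1))
  support <- vapply(parts, function(p) if (length(p) >= 5) p[5] else ".",
                    character(1))
  shared_segments_table(chrom, start, end, carriers,
                        suppressWarnings(as.integer(
                          ifelse(support == ".", NA, support))))
}

#' Convert between VCF and BED coordinates
#'
#' VCF positions are 1-based inclusive; BED intervals are 0-based half-open.
#' `vcf_to_bed_start` and `bed_to_vcf_pos` are mutual inverses.
#'
#' @param pos 1-based VCF position(s).
#' @param start 0-based BED start(s).
#' @return converted coordinate vector.
#' @export
vcf_to_bed_start <- function(pos) pos - 1

#' @rdname vcf_to_bed_start
#' @export
bed_to_vcf_pos <- function(start) start + 1
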