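#' GRCh37 autosome lengths
#'
#' Physical lengths (bp) of the 22 human autosomes in genome build GRCh37.
#'
#' @return named integer-valued numeric vector, names `"chr1"`..`"chr22"`.
#' @export
grch37_autosomes <- function() {
  setNames(c(249250621, 243199373, 198022430, 191154276, 180915260,
             171115067, 159138663, 146364022, 141213431, 135534747,
             135006516, 133851895, 115169878, 107349540, 102531392,
             90354753, 81195210, 78077248, 59128983, 63025520,
             48129895, 51304566),
           paste0("chr", 1:22))
}

#' Build a genetic map from physical chromosome lengths
#'
#' The genome-wide recombination rate `rho_total` (expected crossovers per
#' meiosis; human autosomal default 35.3) is allocated to chromosomes in
#' proportion to their physical length.  No hotspot structure and no
#' crossover interference are modelled: each meiosis later draws a
#' Poisson-distributed crossover count per chromosome with these
#' expectations, at positions uniform on physical length.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param rho_total expected genome-wide crossovers per meiosis (>= 0).
#' @return object of class `genetic_map`: list with `chrom` (data frame of
#'   `chrom`, `length`, `exp_xo`) and `rho_total`.
#' @examples
#' gmap <- build_genetic_map(grch37_autosomes(), 35.3)
#' sum(gmap$chrom$exp_xo)  # 35.3
#' @export
build_genetic_map <- function(chrom_lengths = grch37_autosomes(),
                              rho_total = 35.3) {
  if (length(chrom_lengths) < 1) stop("need at least one chromosome")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (rho_total < 0) stop("rho_total must be >= 0")
  total <- sum(as.numeric(chrom_lengths))
  if (total <= 0) stop("zero total length")
  nm <- names(chrom_lengths)
  if (is.null(nm)) nm <- paste0("chr", seq_along(chrom_lengths))
  map <- list(
    chrom = data.frame(
      chrom = nm,
      length = as.numeric(chrom_lengths),
      exp_xo = rho_total * as.numeric(chrom_lengths) / total,
      stringsAsFactors = FALSE
    ),
    rho_total = rho_total
  )
  class(map) <- "genetic_map"
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %d chromosome(s), rho_total = %g crossovers/meiosis\n",
              nrow(x$chrom), x$rho_total))
  invisible(x)
}

# convenience: tiny map for tests/examples
uniform_map <- function(n_chrom = 1, chrom_length = 1e8, rho_total = 2) {
  build_genetic_map(setNames(rep(chrom_length, n_chrom),
                             paste0("chr", seq_len(n_chrom))), rho_total)
}
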