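# Inheritance-state analysis for a nuclear family with two genotyped
# children.  At each biallelic site the children's genotypes, given the
# parents', constrain which parental strands the two children share:
#   identical               same paternal and same maternal strand
#   haploidentical_paternal same paternal strand only
#   haploidentical_maternal same maternal strand only
#   nonidentical            neither strand shared
# Sites where both parents are homozygous constrain nothing
# (uninformative).  A windowed majority vote smooths per-site
# compatibility into contiguous state segments robust to genotyping error.

IBD_STATES <- c("identical", "haploidentical_paternal",
                "haploidentical_maternal", "nonidentical")

.state_env <- new.env(parent = emptyenv())

# compatibility[gf+1, gm+1, gc1+1, gc2+1, state]: is the genotype quadruple
# reachable under the state's strand-sharing pattern?  Built by exhaustive
# enumeration of parental strand transmissions.
state_table <- function() {
  if (!is.null(.state_env$tab)) return(.state_env$tab)
  alleles <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  tab <- array(FALSE, c(3, 3, 3, 3, 4))
  for (gf in 0:2) for (gm in 0:2) {
    fa <- alleles(gf); ma <- alleles(gm)
    for (f1 in 1:2) for (f2 in 1:2) for (m1 in 1:2) for (m2 in 1:2) {
      c1 <- fa[f1] + ma[m1]
      c2 <- fa[f2] + ma[m2]
      st <- if (f1 == f2 && m1 == m2) 1L else if (f1 == f2) 2L
            else if (m1 == m2) 3L else 4L
      tab[gf + 1, gm + 1, c1 + 1, c2 + 1, st] <- TRUE
    }
  }
  .state_env$tab <- tab
  tab
}

# n_sites x 4 logical compatibility matrix; rows of NA genotypes are
# all-TRUE (no information)
state_compatibility <- function(gf, gm, gc1, gc2) {
  tab <- state_table()
  n <- length(gf)
  out <- matrix(TRUE, n, 4, dimnames = list(NULL, IBD_STATES))
  ok <- !(is.na(gf) | is.na(gm) | is.na(gc1) | is.na(gc2))
  idx <- which(ok)
  for (s in 1:4)
    out[idx, s] <- tab[cbind(gf[idx] + 1, gm[idx] + 1, gc1[idx] + 1,
                             gc2[idx] + 1, s)]
  out
}

#' Infer inheritance states in a nuclear family
#'
#' Votes per informative site for the four canonical states and smooths
#' them with a running mean over `window` informative sites; on ties the
#' preceding state is extended (minimizing spurious breakpoints).  Sites at
#' which both parents are homozygous are uninformative and carry no vote.
#'
#' @param vt a [variant_table()] genotyping the family.
#' @param ped the nuclear `fam_pedigree`; both parents and at least two
#'   children must be genotyped.
#' @param children ids of the two children to analyse (default: the first
#'   two genotyped children).
#' @param window smoothing window, in informative sites.
#' @return data frame of class `inheritance_track`: `chrom`, `start`,
#'   `end` (0-based half-open), `state`, `support` (votes for the state
#'   inside the segment).
#' @export
infer_inheritance_states <- function(vt, ped, children = NULL, window = 10L) {
  kids <- ped$id[!is.na(ped$father)]
  kids <- intersect(kids, colnames(vt$geno))
  if (length(kids) < 2) stop("need >= 2 genotyped children")
  if (is.null(children)) children <- kids[1:2]
  stopifnot(length(children) == 2, all(children %in% kids))
  par1 <- ped[ped$id == children[1], ]
  fa <- par1$father; mo <- par1$mother
  if (!all(c(fa, mo) %in% colnames(vt$geno)))
    stop("both parents must be genotyped")
  v <- vt$variants
  out <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    idx <- idx[order(v$pos[idx])]
    comp <- state_compatibility(vt$geno[idx, fa], vt$geno[idx, mo],
                                vt$geno[idx, children[1]],
                                vt$geno[idx, children[2]])
    informative <- rowSums(comp) < 4L
    ii <- idx[informative]
    if (length(ii) < 2L) next
    sc <- comp[informative, , drop = FALSE] * 1
    # running mean over `window` informative sites
    w <- min(window, nrow(sc))
    smooth <- apply(sc, 2, function(col)
      stats::filter(col, rep(1 / w, w), sides = 2))
    smooth[is.na(smooth)] <- sc[is.na(smooth)]  # window edges: raw votes
    state_i <- integer(nrow(sc))
    prev <- 0L
    # tie preference: extend the preceding state; otherwise prefer the
    # haploidentical states over "identical" (claim only the sharing the
    # sites prove) and "nonidentical" last
    pref <- c(2L, 3L, 1L, 4L)
    for (k in seq_len(nrow(sc))) {
      best <- which(smooth[k, ] == max(smooth[k, ]))
      state_i[k] <- if (prev %in% best) prev
                    else pref[pref %in% best][1]
      prev <- state_i[k]
    }
    runs <- rle(state_i)
    stops <- cumsum(runs$lengths)
    starts <- c(1L, head(stops, -1) + 1L)
    pos <- v$pos[ii]
    for (r in seq_along(runs$values)) {
      a <- starts[r]; b <- stops[r]
      seg_start <- if (r == 1) pos[1] - 1 else (pos[a - 1] + pos[a]) / 2
      seg_end <- if (r == length(runs$values)) pos[length(pos)]
                 else (pos[b] + pos[b + 1]) / 2
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = seg_start, end = seg_end,
        state = IBD_STATES[runs$values[r]],
        support = sum(sc[a:b, runs$values[r]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(structure(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), state = character(0),
                                support = numeric(0)),
                     class = c("inheritance_track", "data.frame")))
  res <- do.call(rbind, out)
  class(res) <- c("inheritance_track", "data.frame")
  res
}

#' Write an inheritance-state track as BED4+
#' @param track an `inheritance_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_state_bed <- function(track, path) {
  lines <- c("#chrom\tstart\tend\tstate\tsupport",
             sprintf("%s\t%s\t%s\t%s\t%s", track$chrom,
                     format(track$start, scientific = FALSE, trim = TRUE),
                     format(track$end, scientific = FALSE, trim = TRUE),
                     track$state, track$support))
  writeLines(lines, path)
  invisible(path)
}

#' Recall of true crossover breakpoints by an inferred track
#'
#' Fraction of true breakpoints having an inferred segment boundary within
#' `tol_bp`.
#'
#' @param true_bp data frame (`chrom`, `pos`) of true crossover positions.
#' @param track an `inheritance_track`.
#' @param tol_bp matching tolerance in base pairs.
#' @return recall in \eqn{[0, 1]} (`NaN` when there are no true
#'   breakpoints).
#' @export
recall_breakpoints <- function(true_bp, track, tol_bp) {
  if (!nrow(true_bp)) return(NaN)
  hit <- vapply(seq_len(nrow(true_bp)), function(k) {
    b <- track$start[track$chrom == true_bp$chrom[k]]
    b <- c(b, track$end[track$chrom == true_bp$chrom[k]])
    any(abs(b - true_bp$pos[k]) <= tol_bp)
  }, logical(1))
  mean(hit)
}
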