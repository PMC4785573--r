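# Rare-allele sharing scan: identical-by-descent candidate segments are
# maximal runs of rare alleles carried by every target, tolerating a
# bounded number of rare alleles private to a strict subset (conflicts).

#' Detect segments shared by all targets
#'
#' Scans rare alleles (population frequency at most `max_af`, mirroring the
#' candidate-variant rarity bound).  Sites where every target carries the
#' allele support sharing; rare alleles carried by a strict subset of
#' targets conflict with it.  Maximal runs containing at least
#' `min_support` all-shared sites and at most `max_conflicts` conflicts are
#' reported.  When an [infer_inheritance_states()] track is supplied (for a
#' nuclear sub-family), reported segments are clipped to its
#' non-`nonidentical` regions, the state evidence overriding the
#' rare-allele heuristic.
#'
#' @param vt a [variant_table()].
#' @param targets >= 2 sample ids that must share.
#' @param min_support minimum number of all-shared rare sites per segment.
#' @param max_conflicts maximum subset-private rare sites tolerated inside
#'   a segment.
#' @param max_af rarity bound on the population allele frequency.
#' @param state_track optional `inheritance_track` override.
#' @return a `shared_segments` table (possibly empty).
#' @export
shared_segments <- function(vt, targets, min_support = 3L,
                            max_conflicts = 0L, max_af = 0.03,
                            state_track = NULL) {
  stopifnot(length(targets) >= 2)
  absent <- setdiff(targets, colnames(vt$geno))
  if (length(absent))
    stop("targets not genotyped: ", paste(absent, collapse = ", "))
  v <- vt$variants
  g <- vt$geno[, targets, drop = FALSE]
  carry <- !is.na(g) & g >= 1L
  n_carry <- rowSums(carry)
  rare <- v$pop_af <= max_af
  status <- rep("ignore", nrow(v))
  status[rare & n_carry == length(targets)] <- "shared"
  status[rare & n_carry > 0 & n_carry < length(targets)] <- "conflict"
  segs <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch & status != "ignore")
    idx <- idx[order(v$pos[idx])]
    if (!length(idx)) next
    st <- status[idx]
    pos <- v$pos[idx]
    # greedy scan: extend while the conflict budget holds
    k <- 1L
    while (k <= length(idx)) {
      if (st[k] != "shared") { k <- k + 1L; next }
      start_k <- k
      conflicts <- 0L
      last_shared <- k
      j <- k + 1L
      while (j <= length(idx)) {
        if (st[j] == "conflict") {
          if (conflicts + 1L > max_conflicts) break
          conflicts <- conflicts + 1L
        } else {
          last_shared <- j
        }
        j <- j + 1L
      }
      n_shared <- sum(st[start_k:last_shared] == "shared")
      if (n_shared >= min_support) {
        segs[[length(segs) + 1L]] <- data.frame(
          chrom = ch, start = pos[start_k] - 1, end = pos[last_shared],
          support = n_shared, stringsAsFactors = FALSE)
      }
      k <- last_shared + 1L
    }
  }
  if (!length(segs)) return(empty_segments())
  segs <- do.call(rbind, segs)
  out <- shared_segments_table(segs$chrom, segs$start, segs$end,
                               replicate(nrow(segs), targets,
                                         simplify = FALSE),
                               segs$support)
  if (!is.null(state_track)) out <- clip_to_states(out, state_track)
  out
}

# intersect segments with the non-nonidentical regions of a state track
clip_to_states <- function(seg, track) {
  keep <- track[track$state != "nonidentical", , drop = FALSE]
  if (!nrow(seg)) return(seg)
  rows <- list()
  for (i in seq_len(nrow(seg))) {
    k <- keep[keep$chrom == seg$chrom[i] & keep$start < seg$end[i] &
                keep$end > seg$start[i], , drop = FALSE]
    for (j in seq_len(nrow(k))) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = seg$chrom[i],
        start = max(seg$start[i], k$start[j]),
        end = min(seg$end[i], k$end[j]),
        support = seg$support[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_segments())
  m <- do.call(rbind, rows)
  shared_segments_table(m$chrom, m$start, m$end,
                        replicate(nrow(m), seg$carriers[[1]],
                                  simplify = FALSE),
                        m$support)
}
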