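# Quality trimming, read filtering and paired-end merging.

#' Sliding-window quality trimming
#'
#' Scans each read 5' to 3' with a window of `window` bases and cuts the read
#' at the start of the first window whose mean quality falls below
#' `q_threshold`; bases before the cut are kept. Reads shorter than the
#' window, and reads with no failing window, are returned unchanged.
#'
#' @param reads a [read_set].
#' @param window window width in bases (>= 1).
#' @param q_threshold mean Phred quality threshold.
#' @return A trimmed [read_set] (never longer than the input reads).
#' @export
sliding_window_trim <- function(reads, window, q_threshold) {
  stopifnot(inherits(reads, "read_set"), window >= 1)
  n <- length(reads)
  if (n == 0L) return(reads)
  keep_len <- vapply(reads$qual, function(q) {
    L <- length(q)
    if (L < window) return(L)
    cs <- cumsum(as.numeric(q))
    wmean <- (cs[window:L] - c(0, cs[seq_len(L - window)])) / window
    bad <- which(wmean < q_threshold)
    if (!length(bad)) L else bad[1L] - 1L
  }, numeric(1))
  reads$seq <- substr(reads$seq, 1L, keep_len)
  reads$qual <- lapply(seq_len(n), function(i) {
    reads$qual[[i]][seq_len(keep_len[i])]
  })
  reads
}

#' Length and global-quality read filtering
#'
#' Drops reads shorter than the mate-specific minimum length
#' (`min_len_r1` for R1, `min_len_r2` for R2) and reads where fewer than
#' `qual_fraction` of bases have quality >= `qual_floor` (a read with
#' exactly the required fraction is kept). Sequences are never modified.
#'
#' @param reads a [read_set] with mate labels.
#' @param cfg a [pipeline_config].
#' @return A list: `reads` (surviving [read_set]), `keep` (logical vector on
#'   the input), `drops` (named counts by reason: `short`, `low_quality`).
#' @export
filter_reads <- function(reads, cfg) {
  stopifnot(inherits(reads, "read_set"))
  min_len <- ifelse(reads$mate == "R1", cfg$min_len_r1, cfg$min_len_r2)
  len_ok <- nchar(reads$seq) >= min_len
  frac_ok <- vapply(reads$qual, function(q) {
    length(q) > 0L && mean(q >= cfg$qual_floor) >= cfg$qual_fraction
  }, logical(1))
  keep <- len_ok & frac_ok
  list(reads = reads[keep],
       keep = keep,
       drops = c(short = sum(!len_ok),
                 low_quality = sum(len_ok & !frac_ok)))
}

#' Merge one read pair by best overlap
#'
#' The R2 read is reverse-complemented (qualities reversed); among candidate
#' overlap lengths in `[min_overlap, max_overlap]` the one with the lowest
#' mismatch fraction is chosen (ties: the longer overlap). The merge succeeds
#' iff that fraction is at most `1 - merge_identity`. In the overlap,
#' disagreeing positions take the higher-quality base (tie: the R1 base);
#' every overlap position keeps the larger of the two qualities.
#'
#' @param r1,r2 single-read [read_set]s (mates R1 and R2 of one fragment).
#' @param cfg a [pipeline_config].
#' @return On success a list with `amplicon_id`, `sequence`, `qualities`,
#'   `overlap_length`, `source_pair`; on failure `NULL` (a reported outcome,
#'   not an error).
#' @export
merge_pair <- function(r1, r2, cfg) {
  stopifnot(inherits(r1, "read_set"), inherits(r2, "read_set"),
            length(r1) == 1L, length(r2) == 1L)
  rc_seq <- rev_comp(r2$seq)
  rc_qual <- rev(r2$qual[[1L]])
  hit <- cpp_best_overlap(r1$seq, rc_seq, cfg$min_overlap, cfg$max_overlap)
  if (hit[1L] < 0L || hit[2L] / hit[1L] > 1 - cfg$merge_identity + 1e-12)
    return(NULL)
  m <- cpp_merge_at(r1$seq, rc_seq, r1$qual[[1L]], rc_qual, hit[1L])
  list(amplicon_id = r1$id, sequence = m$sequence, qualities = m$qualities,
       overlap_length = as.integer(hit[1L]),
       source_pair = c(r1$id, r2$id))
}

#' Merge all pairs of two read sets
#'
#' Pairs are matched by position (`r1[i]` with `r2[i]`).
#'
#' @param r1 [read_set] of forward reads.
#' @param r2 [read_set] of reverse reads (same length and order as `r1`).
#' @param cfg a [pipeline_config].
#' @return A list: `amplicons` (list with parallel `id`, `seq`, `qual`,
#'   `overlap` fields), `merged` (logical per pair), `n_failed`.
#' @export
merge_pairs <- function(r1, r2, cfg) {
  stopifnot(length(r1) == length(r2))
  n <- length(r1)
  ids <- character(n); seqs <- character(n)
  quals <- vector("list", n); ovl <- integer(n)
  ok <- logical(n)
  rc_seqs <- rev_comp(r2$seq)
  for (i in seq_len(n)) {
    rc_qual <- rev(r2$qual[[i]])
    hit <- cpp_best_overlap(r1$seq[i], rc_seqs[i],
                            cfg$min_overlap, cfg$max_overlap)
    if (hit[1L] < 0L || hit[2L] / hit[1L] > 1 - cfg$merge_identity + 1e-12)
      next
    m <- cpp_merge_at(r1$seq[i], rc_seqs[i], r1$qual[[i]], rc_qual, hit[1L])
    ids[i] <- r1$id[i]; seqs[i] <- m$sequence
    quals[[i]] <- m$qualities; ovl[i] <- hit[1L]
    ok[i] <- TRUE
  }
  list(amplicons = list(id = ids[ok], seq = seqs[ok], qual = quals[ok],
                        overlap = ovl[ok]),
       merged = ok, n_failed = sum(!ok))
}
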