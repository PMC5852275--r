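# Direct-repeat detection and leader-end spacer extraction from merged
# amplicon representatives. Coordinates are 0-based half-open throughout;
# spacer positions_from_leader are 1-based ranks (1 = newest spacer).

#' Locate direct repeats in an amplicon
#'
#' Finds all non-overlapping full matches of the configured direct repeat
#' with Hamming distance <= `repeat_max_mismatch`, scanning left to right;
#' groups of mutually overlapping candidate windows are resolved by fewest
#' mismatches, then leftmost start. At most one terminal partial repeat of
#' at least `min_partial_repeat` bases is additionally reported at the 3'
#' end (mismatch allowance scaled down proportionally to its length).
#'
#' @param seq DNA string.
#' @param cfg a [pipeline_config] with `repeat_sequence` set.
#' @return data.frame with columns `start` (0-based), `end` (exclusive),
#'   `mismatches`, `partial` (logical), sorted by `start`. Zero rows when
#'   nothing matches.
#' @export
locate_repeats <- function(seq, cfg) {
  rep_seq <- cfg$repeat_sequence
  m <- nchar(rep_seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0), partial = logical(0))
  if (!nzchar(seq)) return(empty)
  mm <- cpp_hamming_scan(seq, rep_seq)
  cand <- which(mm <= cfg$repeat_max_mismatch) - 1L   # 0-based starts
  picked <- integer(0)
  while (length(cand)) {
    c0 <- cand[1L]
    grp <- cand[cand < c0 + m]             # candidates overlapping the first
    best <- grp[which.min(mm[grp + 1L])]   # fewest mismatches, then leftmost
    picked <- c(picked, best)
    cand <- cand[cand >= best + m]         # drop everything overlapping pick
  }
  out <- data.frame(start = picked, end = picked + m,
                    mismatches = mm[picked + 1L],
                    partial = rep(FALSE, length(picked)))
  # terminal partial repeat truncated by the 3' read end
  n <- nchar(seq)
  tail_start <- if (nrow(out)) max(out$end) else 0L
  max_k <- min(m - 1L, n - tail_start)
  part <- NULL
  if (max_k >= cfg$min_partial_repeat) {
    for (k in max_k:cfg$min_partial_repeat) {
      allowed <- floor(cfg$repeat_max_mismatch * k / m)
      d <- cpp_hamming(substr(seq, n - k + 1L, n), substr(rep_seq, 1L, k))
      if (d <= allowed) {
        part <- data.frame(start = n - k, end = n, mismatches = d,
                           partial = TRUE)
        break
      }
    }
  }
  out <- rbind(out, part)
  out[order(out$start), , drop = FALSE]
}

#' Extract ordered leader-end spacers from an amplicon
#'
#' Spacers are the segments between consecutive repeat matches whose length
#' lies within `[spacer_min_len, spacer_max_len]`; segments outside the
#' bounds are dropped and flagged. The segment 5' of the first repeat is
#' leader sequence, never a spacer. Reads are assumed oriented leader-first;
#' when no repeat is found on the given strand the reverse complement is
#' tried before declaring failure.
#'
#' @param amplicon_id identifier recorded with each spacer.
#' @param seq DNA string of the merged amplicon.
#' @param cfg a [pipeline_config].
#' @return A list: `spacers` (data.frame `sequence`, `position_from_leader`,
#'   `source_amplicon`), `status` (`"ok"`, `"no_repeats"`, or
#'   `"no_valid_spacers"`), `dropped` (data.frame of out-of-bounds
#'   segments), `repeats` (the repeat table used), `rc_used` (logical).
#' @export
extract_spacers <- function(amplicon_id, seq, cfg) {
  rc_used <- FALSE
  reps <- locate_repeats(seq, cfg)
  if (!nrow(reps)) {
    rc <- rev_comp(seq)
    reps_rc <- locate_repeats(rc, cfg)
    if (nrow(reps_rc)) {
      seq <- rc
      reps <- reps_rc
      rc_used <- TRUE
    }
  }
  no_spacer <- data.frame(sequence = character(0),
                          position_from_leader = integer(0),
                          source_amplicon = character(0))
  no_drop <- data.frame(sequence = character(0), start = integer(0),
                        end = integer(0), reason = character(0))
  if (nrow(reps) < 2L)
    return(list(spacers = no_spacer, status = "no_repeats", dropped = no_drop,
                repeats = reps, rc_used = rc_used))
  seg_start <- reps$end[-nrow(reps)]
  seg_end <- reps$start[-1L]
  seg_seq <- substr(rep(seq, length(seg_start)), seg_start + 1L, seg_end)
  seg_len <- seg_end - seg_start
  ok <- seg_len >= cfg$spacer_min_len & seg_len <= cfg$spacer_max_len
  spacers <- if (any(ok)) {
    data.frame(sequence = seg_seq[ok],
               position_from_leader = seq_len(sum(ok)),
               source_amplicon = amplicon_id)
  } else no_spacer
  dropped <- if (any(!ok)) {
    data.frame(sequence = seg_seq[!ok], start = seg_start[!ok],
               end = seg_end[!ok],
               reason = ifelse(seg_len[!ok] < cfg$spacer_min_len,
                               "too_short", "too_long"))
  } else no_drop
  status <- if (nrow(spacers)) "ok" else "no_valid_spacers"
  list(spacers = spacers, status = status, dropped = dropped,
       repeats = reps, rc_used = rc_used)
}
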