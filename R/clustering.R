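# Greedy incremental clustering of merged amplicons into representative
# sequences (first-fit against existing representatives, longest first).

#' Ungapped pairwise identity and coverage
#'
#' Computes the best ungapped (end-gap-free, substitution-only) alignment of
#' two sequences over every relative offset, maximizing matches (ties: the
#' longer overlap, then the smaller offset). Identity is matches / aligned
#' columns; coverage is aligned columns / length of the shorter sequence.
#'
#' @param a,b non-empty DNA strings.
#' @return Named numeric vector `c(identity, coverage)`.
#' @export
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")  # identity 1, coverage 1
pairwise_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  r <- cpp_best_offset(a, b)
  c(identity = r[1L] / r[2L], coverage = r[2L] / min(nchar(a), nchar(b)))
}

#' Greedy incremental clustering
#'
#' Sequences are processed in decreasing length (ties: lexicographic id).
#' Each sequence joins the first existing cluster (in founding order) whose
#' representative satisfies, on the best ungapped alignment (the one
#' [pairwise_identity] reports), identity >= `cluster_identity` and aligned
#' columns / length of the LONGER sequence >= `cluster_coverage`; otherwise
#' it founds a new cluster with itself as representative. The coverage
#' denominator is deliberately the representative (longer) length so that a
#' short leader-end fragment cannot be absorbed into an arbitrary longer
#' array sharing its first spacer — clusters then correspond to whole array
#' types, which downstream variant fractions require. Identical sequences
#' are collapsed before scanning, which cannot change the first-fit
#' outcome. Internally a cheap early-bailing scan rejects hopeless
#' representatives before the exact best-alignment check runs; a
#' representative with no qualifying offset cannot have a qualifying best
#' alignment, so the shortcut is lossless.
#'
#' @param ids character vector of sequence identifiers (unique).
#' @param seqs character vector of DNA sequences, parallel to `ids`.
#' @param cfg a [pipeline_config].
#' @return A list of clusters in founding order, each a list with
#'   `representative_id`, `representative_seq`, `member_ids`, `size`.
#' @export
cluster_greedy <- function(ids, seqs, cfg) {
  stopifnot(length(ids) == length(seqs), !anyDuplicated(ids))
  if (!length(ids)) return(list())
  ord <- order(-nchar(seqs), ids, method = "radix")
  ids <- ids[ord]; seqs <- seqs[ord]
  # collapse exact duplicates, keeping the first-processed id as group leader
  first <- !duplicated(seqs)
  grp <- match(seqs, seqs[first])
  u_seq <- seqs[first]
  u_members <- split(ids, grp)            # members in processing order
  nu <- length(u_seq)
  rep_seq <- character(0)
  clusters <- list()
  assign_to <- integer(nu)
  for (i in seq_len(nu)) {
    hit <- 0L
    for (j in seq_along(rep_seq)) {
      if (cpp_cluster_hit(rep_seq[j], u_seq[i],
                          cfg$cluster_identity, cfg$cluster_coverage) &&
          cpp_best_offset_qualifies(rep_seq[j], u_seq[i],
                                    cfg$cluster_identity,
                                    cfg$cluster_coverage)) {
        hit <- j
        break
      }
    }
    if (hit == 0L) {
      rep_seq <- c(rep_seq, u_seq[i])
      hit <- length(rep_seq)
      clusters[[hit]] <- list(representative_id = u_members[[i]][1L],
                              representative_seq = u_seq[i],
                              member_ids = character(0), size = 0L)
    }
    assign_to[i] <- hit
  }
  for (i in seq_len(nu)) {
    j <- assign_to[i]
    clusters[[j]]$member_ids <- c(clusters[[j]]$member_ids, u_members[[i]])
  }
  for (j in seq_along(clusters)) {
    clusters[[j]]$size <- length(clusters[[j]]$member_ids)
  }
  clusters
}

#' Tabulate clusters
#'
#' @param clusters result of [cluster_greedy].
#' @return data.frame with columns `cluster_id`, `representative_id`,
#'   `member_id`.
#' @export
cluster_table <- function(clusters) {
  if (!length(clusters))
    return(data.frame(cluster_id = integer(0), representative_id = character(0),
                      member_id = character(0)))
  do.call(rbind, lapply(seq_along(clusters), function(j) {
    data.frame(cluster_id = j,
               representative_id = clusters[[j]]$representative_id,
               member_id = clusters[[j]]$member_ids)
  }))
}
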