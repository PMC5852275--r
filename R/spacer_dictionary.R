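# Mismatch-tolerant spacer dictionary: unify observed spacer sequences into
# numbered identities (star topology around an abundance-ranked canonical).

#' Build a spacer dictionary
#'
#' Unique sequences are processed in decreasing total weight (ties:
#' lexicographic sequence). A sequence joins the first existing identity (in
#' founding order) whose canonical sequence has the same length and Hamming
#' distance <= `spacer_max_mismatch`; otherwise it founds a new identity
#' with itself as canonical. Matching is star-shaped: members are compared
#' to the canonical only, never chained. Sequences of different lengths are
#' always distinct identities (substitution errors dominate short-read
#' chemistry; indel variants intentionally found new IDs).
#'
#' When a reference `catalog` is supplied its canonical spacer sequences are
#' pre-seeded as identities under their catalog IDs (abundance 0), and new
#' IDs continue numbering after the catalog's largest ID, so catalog IDs are
#' stable across runs.
#'
#' @param sequences character vector of observed spacer sequences.
#' @param weights numeric vector of read weights (cluster sizes), parallel
#'   to `sequences`.
#' @param cfg a [pipeline_config].
#' @param catalog optional `"ct_catalog"` whose `spacer_seq` seeds the
#'   dictionary.
#' @return A list: `identities` (data.frame `spacer_id`, `sequence`,
#'   `abundance`), `map` (named integer vector: observed sequence ->
#'   spacer ID).
#' @export
build_dictionary <- function(sequences, weights = rep(1, length(sequences)),
                             cfg = pipeline_config(), catalog = NULL) {
  stopifnot(length(sequences) == length(weights))
  ids_can <- integer(0); seq_can <- character(0); abun <- numeric(0)
  next_id <- 1L
  if (!is.null(catalog) && length(catalog$spacer_seq)) {
    seed_ids <- as.integer(names(catalog$spacer_seq))
    ord <- order(seed_ids)
    ids_can <- seed_ids[ord]
    seq_can <- unname(catalog$spacer_seq[ord])
    abun <- numeric(length(ids_can))
    next_id <- max(seed_ids) + 1L
  }
  map <- integer(0)
  if (length(sequences)) {
    w <- tapply(weights, sequences, sum)
    useq <- names(w)
    ord <- order(-as.numeric(w), useq, method = "radix")
    useq <- useq[ord]; uw <- as.numeric(w)[ord]
    ulen <- nchar(useq)
    clen <- nchar(seq_can)
    map <- setNames(integer(length(useq)), useq)
    for (i in seq_along(useq)) {
      hit <- 0L
      same_len <- which(clen == ulen[i])
      for (j in same_len) {
        if (cpp_hamming(seq_can[j], useq[i]) <= cfg$spacer_max_mismatch) {
          hit <- j
          break
        }
      }
      if (hit == 0L) {
        ids_can <- c(ids_can, next_id)
        seq_can <- c(seq_can, useq[i])
        clen <- c(clen, ulen[i])
        abun <- c(abun, 0)
        hit <- length(ids_can)
        next_id <- next_id + 1L
      }
      abun[hit] <- abun[hit] + uw[i]
      map[i] <- ids_can[hit]
    }
  }
  list(identities = data.frame(spacer_id = ids_can, sequence = seq_can,
                               abundance = abun),
       map = map)
}

#' Spacer arrays from extraction results
#'
#' Builds one ordered spacer-ID array per amplicon with extraction status
#' `"ok"`, preserving leader-first order and carrying the cluster weight.
#'
#' @param extractions named list of [extract_spacers] results (names are
#'   amplicon IDs).
#' @param map named integer vector from [build_dictionary] (sequence -> ID).
#' @param weights named numeric vector of cluster weights per amplicon ID
#'   (defaults to 1).
#' @return data.frame with columns `amplicon_id`, `weight`, and list-column
#'   `ids` (integer vectors, leader-end first).
#' @export
arrays_from_amplicons <- function(extractions, map, weights = NULL) {
  empty <- data.frame(amplicon_id = character(0), weight = numeric(0))
  empty$ids <- list()
  if (!length(extractions)) return(empty)
  ok <- vapply(extractions, function(e) e$status == "ok", logical(1))
  extractions <- extractions[ok]
  if (!length(extractions)) return(empty)
  amp_ids <- names(extractions)
  if (is.null(weights)) weights <- setNames(rep(1, length(amp_ids)), amp_ids)
  ids <- lapply(extractions, function(e) {
    s <- e$spacers$sequence[order(e$spacers$position_from_leader)]
    v <- unname(map[s])
    if (anyNA(v))
      stop("internal consistency error: spacer occurrence without a ",
           "dictionary assignment in amplicon ",
           e$spacers$source_amplicon[1L])
    v
  })
  out <- data.frame(amplicon_id = amp_ids,
                    weight = as.numeric(weights[amp_ids]))
  out$ids <- unname(ids)
  rownames(out) <- NULL
  out
}

# canonical string key of an ID array (used for singleton bookkeeping)
array_key <- function(ids) paste(ids, collapse = ",")
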