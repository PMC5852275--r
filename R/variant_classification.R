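# Leader-end variant classes within a CT: origin / new_plus / proto /
# others. Classification is relative to the CT's origin repertoire and
# independent of array weight.

#' Classify the leader-end variant of an assigned array
#'
#' The array is split into a maximal leading block of novel IDs (IDs absent
#' from the origin repertoire) followed by the remainder, then classified:
#' \describe{
#'   \item{origin}{no leading novel IDs and the remainder is the contiguous
#'     origin prefix `origin[1..k]`, `k >= 1`.}
#'   \item{new_plus}{>= 1 leading novel IDs followed by the contiguous
#'     origin prefix `origin[1..k]`, `k >= 1` (newly acquired leader-end
#'     spacer(s) in front of the ancestral repertoire).}
#'   \item{proto}{no leading novel IDs and the remainder is a contiguous
#'     origin block `origin[j..j+k-1]` starting at `j >= 2` (the ancestral
#'     state before the newest spacers were acquired).}
#'   \item{others}{every other assigned pattern: internal novel IDs,
#'     deletions / non-contiguous matches, novel IDs after known ones.}
#' }
#'
#' @param ids integer vector of spacer IDs, leader-end first (non-empty,
#'   assigned to this CT).
#' @param origin the CT's origin repertoire (integer vector, leader-end
#'   first).
#' @return A list: `variant` (one of `"origin"`, `"new_plus"`, `"proto"`,
#'   `"others"`), `leading_novel` (count), `start_position_in_origin`
#'   (1-based index, `NA` for `others`).
#' @export
classify_variant <- function(ids, origin) {
  stopifnot(length(origin) >= 1L)
  if (!length(ids))
    stop("internal error: empty array reached the variant classifier")
  novel <- !(ids %in% origin)
  if (all(novel)) {
    # whole array novel relative to this origin: a leading block with no
    # remainder fits none of origin/new_plus/proto
    return(list(variant = "others", leading_novel = length(ids),
                start_position_in_origin = NA_integer_))
  }
  lead <- if (novel[1L]) {
    r <- rle(novel)
    r$lengths[1L]
  } else 0L
  remainder <- ids[(lead + 1L):length(ids)]
  pos <- match(remainder, origin)
  contiguous <- !anyNA(pos) &&
    (length(pos) == 1L || all(diff(pos) == 1L))
  if (contiguous && pos[1L] == 1L) {
    variant <- if (lead == 0L) "origin" else "new_plus"
    return(list(variant = variant, leading_novel = as.integer(lead),
                start_position_in_origin = 1L))
  }
  if (lead == 0L && contiguous && pos[1L] >= 2L) {
    return(list(variant = "proto", leading_novel = 0L,
                start_position_in_origin = as.integer(pos[1L])))
  }
  list(variant = "others", leading_novel = as.integer(lead),
       start_position_in_origin = NA_integer_)
}

#' Classify every assigned array
#'
#' @param assignments data.frame with columns `amplicon_id`, `label`,
#'   `weight` and list-column `ids` (only rows whose `label` is a catalog
#'   CT are classified).
#' @param catalog a `"ct_catalog"` supplying each CT's origin repertoire.
#' @return data.frame `amplicon_id`, `ct_label`, `variant`,
#'   `leading_novel`, `start_position_in_origin`, `weight`.
#' @export
classify_variants <- function(assignments, catalog) {
  rows <- assignments$label %in% names(catalog$entries)
  sub <- assignments[rows, , drop = FALSE]
  if (!nrow(sub))
    return(data.frame(amplicon_id = character(0), ct_label = character(0),
                      variant = character(0), leading_novel = integer(0),
                      start_position_in_origin = integer(0),
                      weight = numeric(0)))
  calls <- lapply(seq_len(nrow(sub)), function(i) {
    classify_variant(sub$ids[[i]], catalog$entries[[sub$label[i]]])
  })
  data.frame(amplicon_id = sub$amplicon_id,
             ct_label = sub$label,
             variant = vapply(calls, `[[`, "", "variant"),
             leading_novel = vapply(calls, `[[`, 0L, "leading_novel"),
             start_position_in_origin =
               vapply(calls, `[[`, 0L, "start_position_in_origin"),
             weight = sub$weight)
}

#' Per-sample, per-CT variant fractions
#'
#' @param calls data.frame from [classify_variants] with an added `sample`
#'   column.
#' @return data.frame `sample`, `ct_label`, `origin`, `new_plus`, `proto`,
#'   `others` (weight fractions summing to 1 per row), `total_weight`.
#'   Rows with zero total weight (CT absent from a sample) are omitted.
#' @export
variant_trajectories <- function(calls) {
  stopifnot("sample" %in% names(calls))
  if (!nrow(calls))
    return(data.frame(sample = character(0), ct_label = character(0),
                      origin = numeric(0), new_plus = numeric(0),
                      proto = numeric(0), others = numeric(0),
                      total_weight = numeric(0)))
  agg <- aggregate(weight ~ sample + ct_label + variant, data = calls,
                   FUN = sum)
  keys <- unique(agg[c("sample", "ct_label")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- agg[agg$sample == keys$sample[i] &
               agg$ct_label == keys$ct_label[i], ]
    tot <- sum(sub$weight)
    w <- setNames(rep(0, 4), c("origin", "new_plus", "proto", "others"))
    w[sub$variant] <- sub$weight
    data.frame(sample = keys$sample[i], ct_label = keys$ct_label[i],
               origin = w[["origin"]] / tot, new_plus = w[["new_plus"]] / tot,
               proto = w[["proto"]] / tot, others = w[["others"]] / tot,
               total_weight = tot)
  }))
  rownames(out) <- NULL
  out[order(out$sample, out$ct_label), , drop = FALSE]
}
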