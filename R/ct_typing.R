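# CRISPR genotype (CT) assignment: shared leader-end spacer order against a
# reference catalog, singleton discard, and definition of new CTs.

#' Assign one spacer array to a CT
#'
#' Let K be the array IDs found in the catalog. If K maps to two or more
#' distinct CTs the array is `unassigned_ambiguous` (disjointness makes this
#' a chimera/catalog-fault signal, never resolved by majority). If K maps to
#' exactly one CT and those IDs appear in the array in the same relative
#' order (subsequence, contiguity not required) as in that CT's repertoire,
#' the array gets that CT's label; scrambled order is
#' `unassigned_ambiguous`. If K is empty the array is `candidate_new` when
#' it carries at least `new_ct_min_novel` novel spacers, otherwise
#' `discarded_novel_1or2`.
#'
#' @param ids integer vector of spacer IDs, leader-end first.
#' @param catalog a `"ct_catalog"` (validated: disjoint).
#' @param cfg a [pipeline_config].
#' @return A list: `label`, `novel_count`, `matched_ids`.
#' @export
assign_ct <- function(ids, catalog, cfg = pipeline_config()) {
  lookup <- catalog_lookup(catalog)
  assign_ct_impl(ids, catalog, lookup, cfg)
}

assign_ct_impl <- function(ids, catalog, lookup, cfg) {
  cts <- lookup[as.character(ids)]
  known <- !is.na(cts)
  novel_count <- sum(!known)
  matched <- ids[known]
  if (!any(known)) {
    label <- if (novel_count >= cfg$new_ct_min_novel) "candidate_new"
             else "discarded_novel_1or2"
    return(list(label = label, novel_count = novel_count,
                matched_ids = integer(0)))
  }
  hit_cts <- unique(cts[known])
  if (length(hit_cts) > 1L)
    return(list(label = "unassigned_ambiguous", novel_count = novel_count,
                matched_ids = matched))
  repertoire <- catalog$entries[[hit_cts]]
  pos <- match(matched, repertoire)
  if (anyNA(pos) || is.unsorted(pos, strictly = TRUE))
    return(list(label = "unassigned_ambiguous", novel_count = novel_count,
                matched_ids = matched))
  list(label = hit_cts, novel_count = novel_count, matched_ids = matched)
}

#' Assign every array in a table
#'
#' @param arrays data.frame from [arrays_from_amplicons] (columns
#'   `amplicon_id`, `weight`, list-column `ids`).
#' @param catalog a `"ct_catalog"`.
#' @param cfg a [pipeline_config].
#' @return `arrays` with added columns `label`, `novel_count`.
#' @export
assign_cts <- function(arrays, catalog, cfg = pipeline_config()) {
  validate_catalog(catalog)
  lookup <- catalog_lookup(catalog)
  res <- lapply(arrays$ids, assign_ct_impl, catalog = catalog,
                lookup = lookup, cfg = cfg)
  arrays$label <- vapply(res, `[[`, "", "label")
  arrays$novel_count <- vapply(res, `[[`, 0L, "novel_count")
  arrays
}

#' Discard dataset-wide singleton arrays
#'
#' Any distinct ID array whose total weight across the whole dataset is 1 is
#' relabelled `discarded_singleton` (a single observation cannot be told
#' apart from a sequencing artefact).
#'
#' @param assignments data.frame from [assign_cts].
#' @return A list: `assignments` (relabelled), `singleton_fraction`
#'   (fraction of total weight), `n_singletons`.
#' @export
discard_singletons <- function(assignments) {
  if (!nrow(assignments))
    return(list(assignments = assignments, singleton_fraction = 0,
                n_singletons = 0L))
  key <- vapply(assignments$ids, array_key, "")
  tot <- tapply(assignments$weight, key, sum)
  singleton <- key %in% names(tot)[tot == 1]
  assignments$label[singleton] <- "discarded_singleton"
  list(assignments = assignments,
       singleton_fraction = sum(assignments$weight[singleton]) /
         sum(assignments$weight),
       n_singletons = sum(singleton))
}

#' Define new CTs from candidate arrays
#'
#' Candidates (arrays with no catalog spacers and enough novel spacers) are
#' agglomerated by shared spacer IDs: processed in decreasing length (ties:
#' decreasing weight, then amplicon id), a candidate sharing IDs with no
#' existing group founds one, with exactly one group joins it, and with two
#' or more groups is left `unassigned_ambiguous` (merging them would break
#' cross-CT disjointness). Each group becomes one new CT whose origin
#' repertoire is the group's longest array (ties: highest weight, then
#' lexicographic amplicon id); labels are assigned sequentially from
#' `next_label` in group-founding order. Catalog disjointness is
#' re-validated on the result.
#'
#' @param candidates data.frame of candidate arrays (`amplicon_id`,
#'   `weight`, list-column `ids`).
#' @param catalog a `"ct_catalog"` to extend.
#' @param next_label first new label, e.g. `"CT36"`; subsequent labels
#'   increment the numeric suffix.
#' @param spacer_seq optional named character vector with sequences for the
#'   novel spacer IDs (recorded in the catalog).
#' @return A list: `catalog` (extended), `assignments` (data.frame
#'   `amplicon_id`, `label`).
#' @export
define_new_cts <- function(candidates, catalog, next_label,
                           spacer_seq = character(0)) {
  if (!nrow(candidates)) {
    return(list(catalog = catalog,
                assignments = data.frame(amplicon_id = character(0),
                                         label = character(0))))
  }
  known <- unique(unlist(catalog$entries))
  if (any(unlist(candidates$ids) %in% known))
    stop("candidate arrays must not contain catalog spacer IDs")
  ord <- order(-lengths(candidates$ids), -candidates$weight,
               candidates$amplicon_id, method = "radix")
  candidates <- candidates[ord, , drop = FALSE]
  group_of <- integer(nrow(candidates))   # 0 = ambiguous bridge
  group_ids <- list()                     # spacer-ID pool per group
  for (i in seq_len(nrow(candidates))) {
    ids <- candidates$ids[[i]]
    touches <- which(vapply(group_ids, function(g) any(ids %in% g),
                            logical(1)))
    if (length(touches) == 0L) {
      group_ids <- c(group_ids, list(ids))
      group_of[i] <- length(group_ids)
    } else if (length(touches) == 1L) {
      g <- touches
      group_ids[[g]] <- union(group_ids[[g]], ids)
      group_of[i] <- g
    } else {
      group_of[i] <- 0L                   # would bridge two groups
    }
  }
  stem <- sub("[0-9]+$", "", next_label)
  first_num <- as.integer(sub("^.*?([0-9]+)$", "\\1", next_label))
  labels <- character(nrow(candidates))
  labels[group_of == 0L] <- "unassigned_ambiguous"
  new_entries <- list()
  new_prov <- character(0)
  for (g in seq_along(group_ids)) {
    members <- which(group_of == g)
    pick <- members[order(-lengths(candidates$ids[members]),
                          -candidates$weight[members],
                          candidates$amplicon_id[members],
                          method = "radix")][1L]
    lab <- paste0(stem, first_num + g - 1L)
    new_entries[[lab]] <- candidates$ids[[pick]]
    new_prov[lab] <- "new_this_run"
    labels[members] <- lab
  }
  out_cat <- ct_catalog(c(catalog$entries, new_entries),
                        c(catalog$provenance, new_prov),
                        c(catalog$spacer_seq,
                          spacer_seq[setdiff(names(spacer_seq),
                                             names(catalog$spacer_seq))]))
  list(catalog = out_cat,
       assignments = data.frame(amplicon_id = candidates$amplicon_id,
                                label = labels))
}
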