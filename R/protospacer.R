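# Protospacer search: exhaustive ungapped scan of spacer sequences against
# user-supplied foreign-element references (phage/plasmid FASTA), replacing
# a remote nucleotide database search at desk scale.

#' Search one spacer against foreign-element references
#'
#' Scans every offset of both strands of every reference, ungapped. The
#' best hit maximizes matches; ties are broken by first reference (input
#' order), forward before reverse strand, then smallest offset. No hit is
#' reported when the best alignment has more than `max_mismatch`
#' mismatches.
#'
#' @param spacer DNA string (the spacer canonical sequence).
#' @param references named character vector of reference sequences.
#' @param max_mismatch maximum tolerated mismatches (default 3).
#' @return One-row data.frame `ref_id`, `strand` (`"+"`/`"-"`), `offset`
#'   (0-based start on the forward reference), `matches`, `length`, or
#'   `NULL` when no hit qualifies.
#' @export
#' @examples
#' search_spacer("ACGTACGTAC", c(ref = "TTTACGTACGTACTTT"), 0)
search_spacer <- function(spacer, references, max_mismatch = 3L) {
  L <- nchar(spacer)
  if (!length(references)) return(NULL)
  best <- NULL
  spacer_rc <- rev_comp(spacer)
  for (i in seq_along(references)) {
    ref <- references[[i]]
    for (strand in c("+", "-")) {
      query <- if (strand == "+") spacer else spacer_rc
      mm <- cpp_query_scan(ref, query)
      if (!length(mm)) next
      off <- which.min(mm) - 1L    # smallest offset among ties
      matches <- L - mm[off + 1L]
      if (is.null(best) || matches > best$matches) {
        best <- data.frame(ref_id = names(references)[i], strand = strand,
                           offset = off, matches = matches, length = L)
      }
    }
  }
  if (is.null(best) || best$length - best$matches > max_mismatch) return(NULL)
  best
}

#' Search a whole spacer dictionary
#'
#' @param identities data.frame from [build_dictionary] (`spacer_id`,
#'   `sequence`).
#' @param references named character vector of reference sequences.
#' @param max_mismatch maximum tolerated mismatches per hit.
#' @return data.frame `spacer_id`, `ref_id`, `strand`, `offset`, `matches`,
#'   `length` (one row per spacer with a qualifying hit).
#' @export
search_spacers <- function(identities, references, max_mismatch = 3L) {
  hits <- lapply(seq_len(nrow(identities)), function(i) {
    h <- search_spacer(identities$sequence[i], references, max_mismatch)
    if (is.null(h)) return(NULL)
    cbind(data.frame(spacer_id = identities$spacer_id[i]), h)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits))
    return(data.frame(spacer_id = integer(0), ref_id = character(0),
                      strand = character(0), offset = integer(0),
                      matches = integer(0), length = integer(0)))
  do.call(rbind, hits)
}
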