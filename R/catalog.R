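# CT catalog: mapping from CRISPR genotype (CT) label to its ordered origin
# spacer repertoire (leader-end first), with spacer sequences. Spacer sets
# must be disjoint across CTs.

#' Construct a CT catalog
#'
#' @param entries named list; each element an integer vector of spacer IDs,
#'   ordered leader-end first.
#' @param provenance named character vector (`"reference"` or
#'   `"new_this_run"`), one per entry; defaults to `"reference"`.
#' @param spacer_seq named character vector of canonical spacer sequences,
#'   names are spacer IDs.
#' @return A list of class `"ct_catalog"`.
#' @export
ct_catalog <- function(entries, provenance = NULL, spacer_seq = character(0)) {
  if (is.null(provenance))
    provenance <- setNames(rep("reference", length(entries)), names(entries))
  cat <- structure(list(entries = lapply(entries, as.integer),
                        provenance = provenance,
                        spacer_seq = spacer_seq),
                   class = "ct_catalog")
  validate_catalog(cat)
}

#' Validate a CT catalog
#'
#' Checks that every repertoire is non-empty and that no spacer ID occurs in
#' more than one CT's repertoire.
#'
#' @param catalog a `"ct_catalog"`.
#' @return The catalog, invisibly checked.
#' @export
validate_catalog <- function(catalog) {
  ent <- catalog$entries
  if (length(ent)) {
    if (is.null(names(ent)) || anyDuplicated(names(ent)))
      stop("catalog entries must have unique CT labels")
    if (any(lengths(ent) == 0L))
      stop("catalog repertoires must be non-empty")
    all_ids <- unlist(ent, use.names = FALSE)
    if (anyDuplicated(all_ids)) {
      dup <- unique(all_ids[duplicated(all_ids)])
      stop("catalog disjointness violated: spacer ID(s) ",
           paste(dup, collapse = ", "), " occur in more than one CT")
    }
  }
  catalog
}

#' Spacer ID -> CT label lookup
#' @param catalog a `"ct_catalog"`.
#' @return Named character vector mapping spacer ID to CT label.
#' @export
catalog_lookup <- function(catalog) {
  ent <- catalog$entries
  if (!length(ent)) return(setNames(character(0), character(0)))
  setNames(rep(names(ent), lengths(ent)),
           as.character(unlist(ent, use.names = FALSE)))
}

#' @export
print.ct_catalog <- function(x, ...) {
  cat("ct_catalog:", length(x$entries), "CTs,",
      length(unique(unlist(x$entries))), "spacer IDs,",
      length(x$spacer_seq), "spacer sequences\n")
  invisible(x)
}

#' Read / write the CT catalog file
#'
#' Plain-text format with two sections: `[spacers]` (`id <TAB> sequence`
#' lines) and `[cts]` (`label <TAB> provenance <TAB> comma-joined spacer
#' IDs, leader-end first`). Lines starting with `#` are comments.
#'
#' @param path catalog file path.
#' @return `read_catalog()`: a `"ct_catalog"`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  spacer_seq <- character(0)
  labels <- character(0); prov <- character(0); reps <- list()
  for (ln in lines) {
    if (ln %in% c("[spacers]", "[cts]")) {
      section <- ln
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (section == "[spacers]") {
      if (length(f) != 2L) stop("malformed [spacers] line: '", ln, "'")
      spacer_seq[f[1L]] <- toupper(f[2L])
    } else if (section == "[cts]") {
      if (length(f) != 3L) stop("malformed [cts] line: '", ln, "'")
      labels <- c(labels, f[1L])
      prov <- c(prov, f[2L])
      reps <- c(reps, list(as.integer(strsplit(f[3L], ",")[[1L]])))
    } else stop("content before a section header: '", ln, "'")
  }
  names(reps) <- labels
  ct_catalog(reps, setNames(prov, labels), spacer_seq)
}

#' @rdname read_catalog
#' @param catalog a `"ct_catalog"`.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ctyper CT catalog", con)
  writeLines("[spacers]", con)
  if (length(catalog$spacer_seq))
    writeLines(paste0(names(catalog$spacer_seq), "\t", catalog$spacer_seq),
               con)
  writeLines("[cts]", con)
  if (length(catalog$entries))
    writeLines(vapply(names(catalog$entries), function(lb) {
      paste(lb, catalog$provenance[[lb]],
            paste(catalog$entries[[lb]], collapse = ","), sep = "\t")
    }, ""), con)
  invisible(path)
}
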