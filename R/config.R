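# Pipeline configuration: every numeric threshold used anywhere in the
# pipeline lives here, so no stage carries hidden constants.

.ct_defaults <- list(
  window_size          = 4L,     # sliding-window width (bases)
  q_threshold_r1       = 10,     # mean-quality cutoff inside the window, R1
  q_threshold_r2       = 20,     # same for R2 (R2 chemistry is usually worse)
  min_len_r1           = 200L,   # post-trim minimum length, R1 (bases)
  min_len_r2           = 70L,    # post-trim minimum length, R2 (bases)
  qual_floor           = 20,     # per-base quality floor for the global filter
  qual_fraction        = 0.80,   # fraction of bases that must reach qual_floor
  min_overlap          = 60L,    # pair merging: minimum overlap (bases)
  max_overlap          = 301L,   # pair merging: maximum overlap (bases)
  merge_identity       = 0.90,   # pair merging: minimum overlap identity
  cluster_identity     = 0.95,   # greedy clustering: identity threshold
  cluster_coverage     = 0.90,   # greedy clustering: length-coverage threshold
  repeat_sequence      = "ACGTTCCAATTAATCTTAAACC", # direct-repeat stand-in;
                                 # override for real data (organism-specific)
  repeat_max_mismatch  = 5L,     # Hamming tolerance for a full repeat match
  min_partial_repeat   = 15L,    # minimum length of a 3' terminal partial repeat
  spacer_min_len       = 20L,    # accepted spacer length bounds (bases)
  spacer_max_len       = 60L,
  spacer_max_mismatch  = 6L,     # spacer dictionary unification tolerance
  new_ct_min_novel     = 3L,     # novel spacers needed to found a new CT
  dominance_threshold  = 0.01,   # pooled fraction above which a CT is dominant
  shannon_base         = exp(1), # log base for the Shannon index (nats)
  chao1_bias_corrected = TRUE,   # bias-corrected vs classic Chao1
  rng_seed             = 1L
)

.fraction_keys <- c("qual_fraction", "merge_identity", "cluster_identity",
                    "cluster_coverage", "dominance_threshold")
.count_keys <- c("window_size", "min_len_r1", "min_len_r2", "min_overlap",
                 "max_overlap", "repeat_max_mismatch", "min_partial_repeat",
                 "spacer_min_len", "spacer_max_len", "spacer_max_mismatch",
                 "new_ct_min_novel")

#' Pipeline configuration
#'
#' Builds a validated configuration object holding every threshold used by
#' the pipeline. Omitted keys take the documented defaults.
#'
#' @param ... named configuration values overriding the defaults (see
#'   Details for the key list).
#'
#' @details Keys and defaults: `window_size` (4), `q_threshold_r1` (10),
#'   `q_threshold_r2` (20), `min_len_r1` (200), `min_len_r2` (70),
#'   `qual_floor` (20), `qual_fraction` (0.80), `min_overlap` (60),
#'   `max_overlap` (301), `merge_identity` (0.90), `cluster_identity`
#'   (0.95), `cluster_coverage` (0.90), `repeat_sequence`,
#'   `repeat_max_mismatch` (5), `min_partial_repeat` (15), `spacer_min_len`
#'   (20), `spacer_max_len` (60), `spacer_max_mismatch` (6),
#'   `new_ct_min_novel` (3), `dominance_threshold` (0.01), `shannon_base`
#'   (e), `chao1_bias_corrected` (TRUE), `rng_seed` (1).
#'
#' @return A list of class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(cluster_identity = 0.97)
#' cfg$cluster_identity
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(.ct_defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(.ct_defaults, over)
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg a configuration list to validate.
#' @export
validate_config <- function(cfg) {
  for (k in .fraction_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("configuration key '", k, "' must be a fraction in [0, 1], got: ",
           format(cfg[[k]]))
  }
  for (k in .count_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v))
      stop("configuration key '", k, "' must be a non-negative count, got: ",
           format(cfg[[k]]))
    cfg[[k]] <- as.integer(v)
  }
  for (k in c("q_threshold_r1", "q_threshold_r2", "qual_floor")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("configuration key '", k, "' must be a non-negative Phred score")
  }
  if (cfg$min_overlap > cfg$max_overlap)
    stop("min_overlap (", cfg$min_overlap, ") exceeds max_overlap (",
         cfg$max_overlap, ")")
  rep_seq <- cfg$repeat_sequence
  if (!is.character(rep_seq) || length(rep_seq) != 1L || nchar(rep_seq) == 0L ||
      grepl("[^ACGT]", rep_seq))
    stop("repeat_sequence must be a non-empty string over {A,C,G,T}")
  if (!is.numeric(cfg$shannon_base) || cfg$shannon_base <= 0 ||
      cfg$shannon_base == 1)
    stop("shannon_base must be positive and != 1")
  cfg$chao1_bias_corrected <- isTRUE(cfg$chao1_bias_corrected)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' The on-disk format is a flat `key = value` (or `key: value`) text file;
#' `#` starts a comment. Unknown keys are an error (typo protection); any
#' omitted key takes its default. `write_config()` followed by
#' `load_config()` round-trips exactly.
#'
#' @param path path to the configuration file.
#' @return `load_config()`: a `"pipeline_config"`; `write_config()`: `path`,
#'   invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    m <- regexpr("[=:]", ln)
    if (m < 0) stop("malformed configuration line (expected key = value): '",
                    ln, "'")
    key <- trimws(substr(ln, 1L, m - 1L))
    val <- trimws(substr(ln, m + 1L, nchar(ln)))
    if (!key %in% names(.ct_defaults))
      stop("unknown configuration key: '", key, "'")
    proto <- .ct_defaults[[key]]
    parsed <- if (is.character(proto)) {
      val
    } else if (is.logical(proto)) {
      as.logical(val)
    } else {
      suppressWarnings(as.numeric(val))
    }
    if (length(parsed) != 1L || (!is.character(parsed) && is.na(parsed)))
      stop("cannot parse value for configuration key '", key, "': '", val, "'")
    over[[key]] <- parsed
  }
  do.call(pipeline_config, over)
}

#' @rdname load_config
#' @param cfg a `"pipeline_config"` object.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  fmt <- function(v) {
    if (is.character(v)) v
    else if (is.logical(v)) as.character(v)
    else format(v, digits = 17)
  }
  lines <- vapply(names(.ct_defaults),
                  function(k) paste0(k, " = ", fmt(cfg[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("ctyper pipeline configuration\n")
  for (k in names(.ct_defaults))
    cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
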