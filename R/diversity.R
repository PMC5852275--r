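# Diversity statistics over CT genotype abundances: Shannon index, Chao1
# richness and analytic rarefaction.

#' Shannon diversity index
#'
#' H = -sum p_i log(p_i) over categories with positive count, with
#' p_i = count_i / total. Natural log by default (nats).
#'
#' @param counts non-negative per-category abundances, at least one positive.
#' @param base logarithm base (default `exp(1)`).
#' @return The Shannon index (numeric scalar).
#' @export
#' @examples
#' shannon_index(c(5, 5, 5, 5))  # log(4)
shannon_index <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("at least one count must be positive")
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimate
#'
#' Bias-corrected form (default): `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`,
#' where F1 and F2 are the numbers of categories observed exactly once and
#' twice. The classic form `S_obs + F1^2 / (2 F2)` is available; it falls
#' back to the bias-corrected form at F2 = 0.
#'
#' @param counts non-negative per-category abundances.
#' @param bias_corrected use the bias-corrected estimator (default TRUE).
#' @return Estimated richness (>= observed richness).
#' @export
#' @examples
#' chao1_richness(c(1, 1, 1, 2, 2))  # 5 + 3*2/(2*3) = 6
chao1_richness <- function(counts, bias_corrected = TRUE) {
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected || f2 == 0) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + f1^2 / (2 * f2)
  }
}

#' Analytic rarefaction curve
#'
#' Expected number of distinct categories in a random subsample of size n,
#' `E[S_n] = sum_i (1 - C(N - N_i, n) / C(N, n))`, evaluated in log space.
#'
#' @param counts positive per-category abundances (total N).
#' @param grid subsample sizes, each in `[1, N]`.
#' @return data.frame with columns `n` and `expected_richness`.
#' @export
#' @examples
#' rarefaction_curve(c(5, 5), 2)  # 14/9
rarefaction_curve <- function(counts, grid) {
  counts <- counts[counts > 0]
  n_total <- sum(counts)
  if (any(grid < 1 | grid > n_total))
    stop("subsample sizes must lie in [1, N] with N = ", n_total)
  es <- vapply(grid, function(n) {
    sum(1 - exp(lchoose(n_total - counts, n) - lchoose(n_total, n)))
  }, numeric(1))
  data.frame(n = grid, expected_richness = es)
}

#' Per-sample diversity summary
#'
#' @param counts positive per-category (per-CT) abundances.
#' @param grid rarefaction subsample sizes; defaults to ~20 points spanning
#'   `[1, N]` (always including N).
#' @param cfg a [pipeline_config] (supplies `shannon_base` and
#'   `chao1_bias_corrected`).
#' @return A list of class `"diversity_stats"`: `S_obs`, `F1`, `F2`,
#'   `chao1`, `shannon_H`, `rarefaction` (data.frame).
#' @export
diversity_stats <- function(counts, grid = NULL, cfg = pipeline_config()) {
  counts <- counts[counts > 0]
  n_total <- sum(counts)
  if (is.null(grid)) {
    grid <- unique(pmax(1, round(seq(1, n_total, length.out = 20))))
  }
  structure(list(
    S_obs = length(counts),
    F1 = sum(counts == 1),
    F2 = sum(counts == 2),
    chao1 = chao1_richness(counts, cfg$chao1_bias_corrected),
    shannon_H = shannon_index(counts, cfg$shannon_base),
    rarefaction = rarefaction_curve(counts, grid)
  ), class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("S_obs %d  F1 %d  F2 %d  Chao1 %.2f  Shannon %.4f\n",
              x$S_obs, x$F1, x$F2, x$chao1, x$shannon_H))
  invisible(x)
}
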