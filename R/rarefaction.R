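#' Species-abundance summary of a community sample
#'
#' Counts the quantities that drive nonparametric richness estimation: the
#' sample size N, observed richness S_obs, and the numbers of singletons
#' (F1, species seen exactly once) and doubletons (F2, species seen twice).
#'
#' @param community An abundance vector (see [as_abundance()]).
#' @return Object of class `"sad_summary"`: list with `N`, `S_obs`, `F1`,
#'   `F2`.
#' @examples
#' sad_summary(c(a = 1, b = 1, c = 2, d = 3))
#' @export
sad_summary <- function(community) {
  community <- as_abundance(community)
  if (length(community) == 0)
    stop("community is empty", call. = FALSE)
  structure(list(N = sum(community),
                 S_obs = length(community),
                 F1 = sum(community == 1L),
                 F2 = sum(community == 2L)),
            class = "sad_summary")
}

#' @export
print.sad_summary <- function(x, ...) {
  cat(sprintf("SAD summary: N = %d, S_obs = %d, F1 = %d, F2 = %d\n",
              x$N, x$S_obs, x$F1, x$F2))
  invisible(x)
}

#' Chao1 estimate of total species richness
#'
#' Lower-bound estimate of the asymptote of the individual-based rarefaction
#' curve: S_obs + F1^2 / (2 F2). When no doubletons are present the classic
#' form divides by zero, so the standard bias-corrected variant
#' S_obs + F1 (F1 - 1) / (2 (F2 + 1)) is used instead, keeping the estimator
#' defined for every sample. Always >= S_obs.
#'
#' @param x An abundance vector or a [sad_summary()].
#' @return Estimated total richness (double).
#' @examples
#' chao1(c(a = 1, b = 1, c = 2, d = 3))  # 4 + 4/2 = 6
#' @export
chao1 <- function(x) {
  s <- if (inherits(x, "sad_summary")) x else sad_summary(x)
  if (s$S_obs < 1) stop("S_obs must be >= 1", call. = FALSE)
  if (s$F2 > 0) {
    s$S_obs + s$F1^2 / (2 * s$F2)
  } else {
    s$S_obs + s$F1 * (s$F1 - 1) / (2 * (s$F2 + 1))
  }
}

#' Reference sample size for standardizing richness across islands
#'
#' The reference n recipe: n_max is the largest island total, n_min the
#' smallest, the base size n_b doubles the minimum, and the reference
#' n_ref = max(n_max, n_b). Richness rarefied or extrapolated to n_ref is
#' comparable across islands of very different sample sizes.
#'
#' @param island_totals Integer vector of per-island (or per-plot) totals,
#'   all >= 1.
#' @return Object of class `"rarefaction_base"`: list with `n_max`, `n_min`,
#'   `n_b`, `n_ref`.
#' @examples
#' reference_n(c(10, 12, 14))$n_ref  # max(14, 20) = 20
#' @export
reference_n <- function(island_totals) {
  if (length(island_totals) == 0)
    stop("island_totals is empty", call. = FALSE)
  if (anyNA(island_totals) || any(island_totals < 1) ||
      any(island_totals != trunc(island_totals)))
    stop("island_totals must be positive integers", call. = FALSE)
  n_max <- as.integer(max(island_totals))
  n_min <- as.integer(min(island_totals))
  n_b <- 2L * n_min
  structure(list(n_max = n_max, n_min = n_min, n_b = n_b,
                 n_ref = max(n_max, n_b)),
            class = "rarefaction_base")
}

#' @export
print.rarefaction_base <- function(x, ...) {
  cat(sprintf("Reference sample size: n_ref = %d (n_max = %d, n_b = 2 x %d = %d)\n",
              x$n_ref, x$n_max, x$n_min, x$n_b))
  invisible(x)
}

# Analytic expectation of richness in a subsample of n individuals drawn
# without replacement (hypergeometric), in log-binomial arithmetic:
# E[S_n] = sum_i [1 - C(N - N_i, n) / C(N, n)].
.sn_interp <- function(community, n) {
  N <- sum(community)
  sum(1 - exp(lchoose(N - community, n) - lchoose(N, n)))
}

# Chao1-conditional extrapolation beyond the observed sample size:
# S(N + m) = S_obs + f0 * [1 - (1 - F1 / (N f0 + F1))^m], f0 = chao1 - S_obs.
.sn_extrap <- function(community, n) {
  s <- sad_summary(community)
  if (s$F1 == 0) return(as.numeric(s$S_obs))
  f0 <- chao1(s) - s$S_obs
  if (f0 <= 0) return(as.numeric(s$S_obs))
  m <- n - s$N
  s$S_obs + f0 * (1 - (1 - s$F1 / (s$N * f0 + s$F1))^m)
}

.richness_estimate <- function(value, n, N, mode) {
  structure(list(value = value, n = as.integer(n), mode = mode,
                 extrapolation_ratio = n / N),
            class = "richness_estimate")
}

#' Expected richness in a subsample (interpolated rarefaction)
#'
#' Exact hypergeometric expectation of the number of species in n
#' individuals drawn without replacement from the community; computed with
#' log-binomial coefficients so large samples do not overflow.
#'
#' @param community An abundance vector.
#' @param n Target sample size, 1 <= n <= N.
#' @return Object of class `"richness_estimate"` with fields `value`, `n`,
#'   `mode` (one of interpolated/observed/extrapolated) and
#'   `extrapolation_ratio` (n / N).
#' @examples
#' interpolated_richness(c(a = 2, b = 2), 2)$value  # 5/3
#' @export
interpolated_richness <- function(community, n) {
  community <- as_abundance(community)
  N <- sum(community)
  if (N < 1) stop("community is empty", call. = FALSE)
  if (length(n) != 1 || is.na(n) || n < 1 || n > N || n != trunc(n))
    stop(sprintf("n must be an integer in [1, N = %d]", N), call. = FALSE)
  .richness_estimate(.sn_interp(community, n), n, N,
                     if (n == N) "observed" else "interpolated")
}

#' Expected richness beyond the observed sample size (extrapolation)
#'
#' Extrapolates the rarefaction curve to n > N individuals using the
#' Chao1-conditional form, which rises monotonically from S_obs at n = N to
#' the Chao1 asymptote as n grows. With no singletons the curve is already
#' at its asymptote and S_obs is returned.
#'
#' @inheritParams interpolated_richness
#' @param n Target sample size, n > N.
#' @return A `"richness_estimate"` (mode `"extrapolated"`).
#' @examples
#' extrapolated_richness(c(a = 1, b = 1, c = 2, d = 3), 15)$value  # ~5.3128
#' @export
extrapolated_richness <- function(community, n) {
  community <- as_abundance(community)
  N <- sum(community)
  if (N < 1) stop("community is empty", call. = FALSE)
  if (length(n) != 1 || is.na(n) || n <= N || n != trunc(n))
    stop(sprintf("extrapolation requires integer n > N = %d; use interpolated_richness for n <= N",
                 N), call. = FALSE)
  .richness_estimate(.sn_extrap(community, n), n, N, "extrapolated")
}

#' Expected richness at any sample size (dispatch)
#'
#' Delegates to [interpolated_richness()] for n <= N and
#' [extrapolated_richness()] for n > N, recording the mode and the
#' extrapolation ratio n / N. Extrapolating beyond twice the observed sample
#' size is permitted (the reference-n recipe can require it for small
#' islands) but a warning is emitted because reliability degrades there.
#'
#' @inheritParams interpolated_richness
#' @param n Target sample size, n >= 1.
#' @param warn Warn when n > 2 N (default TRUE).
#' @return A `"richness_estimate"`.
#' @export
expected_richness <- function(community, n, warn = TRUE) {
  community <- as_abundance(community)
  N <- sum(community)
  if (N < 1) stop("community is empty", call. = FALSE)
  est <- if (n <= N) interpolated_richness(community, n)
         else extrapolated_richness(community, n)
  if (warn && n > 2 * N)
    warning(sprintf("extrapolating to n = %d, %.1f x the observed sample size N = %d",
                    as.integer(n), n / N, N), call. = FALSE)
  est
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("S_n = %.4f at n = %d (%s, n/N = %.2f)\n",
              x$value, x$n, x$mode, x$extrapolation_ratio))
  invisible(x)
}
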