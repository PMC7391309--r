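#' Log-log regression of a diversity metric on island area
#'
#' Ordinary least squares of ln(metric) on ln(area), the linearized power
#' law S = C * Area^z. Natural logarithms on both axes; unweighted fit.
#' Pairs with a non-finite or non-positive value on either axis (e.g.
#' islands whose S_PIE is undefined) are dropped pairwise with a logged
#' count. The adjusted R-squared is reported as computed and can be
#' negative for a null predictor; it is never clamped.
#'
#' @param area Island areas (km^2), all > 0.
#' @param metric Matching diversity metric values, all > 0.
#' @return Object of class `"loglog_fit"`: list with `intercept` (ln C),
#'   `slope` (z), `se_intercept`, `se_slope`, `r2`, `r2_adj`, `p_slope`
#'   (two-sided p for z = 0), `n_points`, `n_dropped`, and the underlying
#'   `model` (an `lm`).
#' @examples
#' a <- c(1, 10, 100, 1000, 10000)
#' fit_loglog(a, 2 * a^0.25)  # slope 0.25, intercept ln 2, R2 = 1
#' @export
fit_loglog <- function(area, metric) {
  if (length(area) != length(metric))
    stop("area and metric must have equal length", call. = FALSE)
  keep <- is.finite(area) & is.finite(metric) & area > 0 & metric > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("fit_loglog: dropped %d island(s) with undefined or non-positive values",
                    n_dropped))
  if (sum(keep) < 3)
    stop("need at least 3 usable (area, metric) pairs", call. = FALSE)
  la <- log(area[keep])
  ly <- log(metric[keep])
  if (stats::var(la) == 0)
    stop("zero variance in log(area): slope is not identifiable", call. = FALSE)
  model <- stats::lm(ly ~ la)
  # summary.lm warns on numerically perfect fits; those are legitimate here
  # (noiseless power laws) and handled explicitly below
  sm <- suppressWarnings(summary(model))
  co <- sm$coefficients
  p_slope <- co[2, 4]
  if (diff(range(ly)) < 1e-10 * (1 + max(abs(ly)))) {
    # constant response up to floating-point noise: no relationship
    p_slope <- 1
  } else if (!is.finite(p_slope)) {
    p_slope <- if (abs(co[2, 1]) < 1e-12) 1 else 0
  }
  structure(list(intercept = unname(co[1, 1]),
                 slope = unname(co[2, 1]),
                 se_intercept = unname(co[1, 2]),
                 se_slope = unname(co[2, 2]),
                 r2 = sm$r.squared,
                 r2_adj = sm$adj.r.squared,
                 p_slope = p_slope,
                 n_points = sum(keep),
                 n_dropped = n_dropped,
                 model = model),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, digits = 4, ...) {
  cat(sprintf("log-log OLS (n = %d): logC = %.*f +/- %.*f, z = %.*f +/- %.*f\n",
              x$n_points, digits, x$intercept, digits, x$se_intercept,
              digits, x$slope, digits, x$se_slope))
  cat(sprintf("  adj. R2 = %.*f, p(slope) = %.4g\n", digits, x$r2_adj, x$p_slope))
  invisible(x)
}

#' @export
coef.loglog_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.loglog_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(stats::predict(object$model))
  area <- if (is.data.frame(newdata)) newdata$area_km2 else newdata
  exp(object$intercept + object$slope * log(area))
}
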