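#' Per-island diversity table
#'
#' Computes, for every non-empty island, the three diversity metrics whose
#' area-scaling separates ISAR mechanisms: S_total (Chao1 estimate of total
#' richness), S_n (expected richness rarefied or extrapolated to the common
#' reference sample size n_ref), and S_PIE (effective number of species of
#' the probability of interspecific encounter). n_ref follows the
#' reference-n recipe over the island totals of the taxon unless supplied.
#'
#' @param dataset An [archipelago()] dataset.
#' @param n_ref Optional reference sample size; default computed by
#'   [reference_n()] over the island totals.
#' @return data.frame with one row per island: `island_id`, `area_km2`,
#'   `N`, `S_obs`, `S_total`, `S_n`, `sn_mode`, `extrapolation_ratio`,
#'   `S_PIE`. Islands where a metric is undefined carry `NA`/`Inf` there
#'   and are dropped from the corresponding regression only. The
#'   `"n_ref"`/`"rarefaction_base"` attributes record the standardization.
#' @export
island_diversity_table <- function(dataset, n_ref = NULL) {
  stopifnot(inherits(dataset, "archipelago"))
  comms <- island_communities(dataset, drop_empty = TRUE)
  if (length(comms) == 0) stop("no non-empty islands", call. = FALSE)
  totals <- vapply(comms, sum, numeric(1))
  base <- reference_n(totals)
  if (is.null(n_ref)) n_ref <- base$n_ref

  rows <- lapply(names(comms), function(id) {
    comm <- comms[[id]]
    est <- expected_richness(comm, n_ref, warn = FALSE)
    spie <- if (sum(comm) >= 2) suppressWarnings(calc_spie(comm)) else NA_real_
    data.frame(island_id = id,
               N = sum(comm),
               S_obs = length(comm),
               S_total = chao1(comm),
               S_n = est$value,
               sn_mode = est$mode,
               extrapolation_ratio = est$extrapolation_ratio,
               S_PIE = spie,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- merge(dataset$metadata[c("island_id", "area_km2")], tab,
               by = "island_id", sort = TRUE)
  attr(tab, "n_ref") <- as.integer(n_ref)
  attr(tab, "rarefaction_base") <- base
  tab
}

#' Classify the ISAR mechanism from the fitted area slopes
#'
#' Decision logic mapping the S_n and S_PIE area slopes to a mechanism:
#' if the S_n slope is not significantly positive, passive sampling cannot
#' be rejected (larger islands gain species only because they hold more
#' individuals); if S_n increases significantly but S_PIE does not, only
#' the rarer species respond to island area (disproportionate effects on
#' rare species); if both increase significantly, common species shift too.
#' Independently, a significantly positive area slope of either
#' within-island beta-diversity ratio implicates compositional
#' heterogeneity as a co-verdict flag.
#'
#' @param fits Named list of [fit_loglog()] results with elements
#'   `S_total`, `S_n`, `S_PIE`.
#' @param beta_fits Optional named list with elements `beta_S_n`,
#'   `beta_S_PIE` from [beta_area_regression()].
#' @param alpha_level Significance threshold for the slope tests
#'   (default 0.05).
#' @return Object of class `"mechanism_verdict"`: list with `verdict` (one
#'   of `"passive_sampling_not_rejected"`, `"disproportionate_rare"`,
#'   `"disproportionate_common_and_rare"`), `heterogeneity_implicated`
#'   (logical; `NA` without beta fits), `alpha_level` and the supporting
#'   fits.
#' @export
classify_mechanism <- function(fits, beta_fits = NULL, alpha_level = 0.05) {
  if (!all(c("S_total", "S_n", "S_PIE") %in% names(fits)))
    stop("fits must contain elements S_total, S_n and S_PIE", call. = FALSE)
  if (length(alpha_level) != 1 || alpha_level <= 0 || alpha_level >= 1)
    stop("alpha_level must lie in (0, 1)", call. = FALSE)
  sig_pos <- function(f) {
    if (is.null(f)) stop("missing regression fit", call. = FALSE)
    is.finite(f$p_slope) && f$p_slope <= alpha_level && f$slope > 0
  }
  verdict <- if (!sig_pos(fits$S_n)) {
    "passive_sampling_not_rejected"
  } else if (!sig_pos(fits$S_PIE)) {
    "disproportionate_rare"
  } else {
    "disproportionate_common_and_rare"
  }
  hetero <- NA
  if (!is.null(beta_fits))
    hetero <- any(vapply(beta_fits, sig_pos, logical(1)))
  structure(list(verdict = verdict,
                 heterogeneity_implicated = hetero,
                 alpha_level = alpha_level,
                 fits = fits,
                 beta_fits = beta_fits),
            class = "mechanism_verdict")
}

#' @export
print.mechanism_verdict <- function(x, ...) {
  cat(sprintf("ISAR mechanism verdict (alpha = %.3g): %s\n",
              x$alpha_level, x$verdict))
  if (!is.na(x$heterogeneity_implicated))
    cat(sprintf("  within-island heterogeneity implicated: %s\n",
                x$heterogeneity_implicated))
  invisible(x)
}

#' Fit the island species-area relationship and classify its mechanism
#'
#' The package's central model fit. Builds the per-island diversity table
#' (S_total, S_n at n_ref, S_PIE), regresses the natural log of each metric
#' on the natural log of island area, optionally partitions within-island
#' beta-diversity from plot data, and classifies the mechanism behind the
#' ISAR with [classify_mechanism()].
#'
#' @param dataset An [archipelago()] dataset (at least 3 islands).
#' @param alpha Significance threshold for slope tests (default 0.05).
#' @param n_ref Optional reference sample size override.
#' @param beta Compute the plot-based beta-diversity analysis when plot
#'   data are present (default).
#' @param min_plot_n Minimum individuals per plot for inclusion in the beta
#'   analysis (default 2).
#' @return Object of class `"isar"`: list with `taxon`, `diversity` (the
#'   per-island table), `fits` (list of three [fit_loglog()] objects),
#'   `beta` (beta-profile table or NULL), `beta_fits`, `verdict`
#'   (a `"mechanism_verdict"`), `alpha`, `n_ref`.
#' @examples
#' cfg <- scenario_config("passive", island_areas = 10^seq(-1, 3, length.out = 12),
#'                        seed = 1)
#' fit <- isar(simulate_archipelago(cfg))
#' summary(fit)
#' @seealso [island_diversity_table()], [beta_table()], [run_isar_analysis()]
#' @export
isar <- function(dataset, alpha = 0.05, n_ref = NULL, beta = TRUE,
                 min_plot_n = 2) {
  stopifnot(inherits(dataset, "archipelago"))
  if (nrow(dataset$metadata) < 3)
    stop("at least 3 islands are required for ISAR regression", call. = FALSE)
  div <- island_diversity_table(dataset, n_ref = n_ref)
  fits <- list(S_total = fit_loglog(div$area_km2, div$S_total),
               S_n = fit_loglog(div$area_km2, div$S_n),
               S_PIE = fit_loglog(div$area_km2, div$S_PIE))
  beta_tab <- NULL
  beta_fits <- NULL
  if (beta && !is.null(dataset$plots)) {
    beta_tab <- tryCatch(beta_table(dataset, min_plot_n = min_plot_n),
                         error = function(e) {
                           message("beta analysis skipped: ", conditionMessage(e))
                           NULL
                         })
    if (!is.null(beta_tab) && nrow(beta_tab) >= 3)
      beta_fits <- beta_area_regression(beta_tab)
    else if (!is.null(beta_tab))
      message("beta analysis skipped: fewer than 3 islands with usable plots")
  }
  verdict <- classify_mechanism(fits, beta_fits, alpha_level = alpha)
  structure(list(taxon = dataset$taxon,
                 diversity = div,
                 fits = fits,
                 beta = beta_tab,
                 beta_fits = beta_fits,
                 verdict = verdict,
                 alpha = alpha,
                 n_ref = attr(div, "n_ref")),
            class = "isar")
}

#' Table-1 style regression summary for an ISAR fit
#'
#' @param object An `"isar"` fit.
#' @param ... Unused.
#' @return Object of class `"summary.isar"` carrying a data.frame `table`
#'   with one row per response (intercept, slope, SEs, adjusted R2, slope
#'   p-value, n) and the mechanism verdict.
#' @export
summary.isar <- function(object, ...) {
  all_fits <- c(object$fits, object$beta_fits)
  tab <- do.call(rbind, lapply(names(all_fits), function(nm) {
    f <- all_fits[[nm]]
    data.frame(response = nm,
               intercept = f$intercept, se_intercept = f$se_intercept,
               slope = f$slope, se_slope = f$se_slope,
               r2_adj = f$r2_adj, p_slope = f$p_slope,
               n_islands = f$n_points,
               stringsAsFactors = FALSE)
  }))
  structure(list(taxon = object$taxon, table = tab, verdict = object$verdict,
                 n_ref = object$n_ref, alpha = object$alpha),
            class = "summary.isar")
}

#' @export
print.summary.isar <- function(x, digits = 3, ...) {
  cat(sprintf("Island species-area relationship%s — log(metric) ~ log(area), n_ref = %d\n",
              if (nzchar(x$taxon)) paste0(" [", x$taxon, "]") else "", x$n_ref))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print(tab, row.names = FALSE)
  print(x$verdict)
  invisible(x)
}

#' @export
print.isar <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' @export
coef.isar <- function(object, ...) {
  t(vapply(object$fits, function(f) c(intercept = f$intercept, slope = f$slope),
           numeric(2)))
}

#' @export
predict.isar <- function(object, newdata, metric = c("S_n", "S_total", "S_PIE"),
                         ...) {
  metric <- match.arg(metric)
  if (missing(newdata)) newdata <- object$diversity$area_km2
  predict(object$fits[[metric]], newdata)
}

#' @export
residuals.isar <- function(object, metric = c("S_n", "S_total", "S_PIE"), ...) {
  metric <- match.arg(metric)
  stats::residuals(object$fits[[metric]]$model)
}

#' Plot an ISAR fit
#'
#' One log-log panel per diversity metric: island points and the fitted
#' power-law line, annotated with slope and p-value.
#'
#' @param x An `"isar"` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.isar <- function(x, ...) {
  metrics <- c("S_total", "S_n", "S_PIE")
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(old))
  for (m in metrics) {
    y <- x$diversity[[m]]
    keep <- is.finite(y) & y > 0
    f <- x$fits[[m]]
    graphics::plot(x$diversity$area_km2[keep], y[keep], log = "xy",
                   xlab = "Island area (km2)", ylab = m,
                   main = sprintf("%s: z = %.3f (p = %.3g)", m, f$slope,
                                  f$p_slope), ...)
    a <- range(x$diversity$area_km2[keep])
    aa <- exp(seq(log(a[1]), log(a[2]), length.out = 50))
    graphics::lines(aa, exp(f$intercept + f$slope * log(aa)))
  }
  invisible(x)
}
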