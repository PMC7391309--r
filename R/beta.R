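#' Common rarefaction size for the plot (alpha) scale
#'
#' Applies the reference-n recipe at plot grain: over the per-plot totals of
#' all islands with at least two plots, n_alpha = max(largest plot total,
#' 2 x smallest plot total). Plot-scale richness standardized to n_alpha is
#' comparable across plots and, via pooling, across scales.
#'
#' @param plots Plot table (data.frame with island_id, plot_id, species_id,
#'   abundance).
#' @return Integer n_alpha.
#' @export
alpha_scale_n <- function(plots) {
  n_per_island <- tapply(plots$plot_id, plots$island_id,
                         function(p) length(unique(p)))
  keep <- names(n_per_island)[n_per_island >= 2]
  if (length(keep) == 0)
    stop("no islands with >= 2 plots", call. = FALSE)
  sub <- plots[plots$island_id %in% keep, , drop = FALSE]
  totals <- tapply(sub$abundance, paste(sub$island_id, sub$plot_id, sep = "\r"),
                   sum)
  reference_n(as.integer(totals))$n_ref
}

#' Within-island beta-diversity profile for one island
#'
#' Partitions island diversity across scales: alpha is the mean per-plot
#' expected richness (and per-plot S_PIE) at the common size n_alpha, gamma
#' is the same metric on the community pooled across the island's plots,
#' and beta = gamma / alpha. Beta near 1 means plots are random samples of
#' the island community; beta > 1 indicates species are spatially clumped
#' within the island.
#'
#' @param plots Plot table.
#' @param island_id Island to profile (needs >= 2 usable plots).
#' @param n_alpha Common rarefaction size at plot grain (see
#'   [alpha_scale_n()]).
#' @param min_plot_n Plots with fewer individuals are excluded with a
#'   warning (default 2, the smallest sample for which S_PIE exists).
#' @return One-row data.frame: `island_id`, `n_alpha`, `plot_count`,
#'   `alpha_S_n`, `gamma_S_n`, `beta_S_n`, `alpha_S_PIE`, `gamma_S_PIE`,
#'   `beta_S_PIE`; or NULL (with a warning) when fewer than 2 usable plots
#'   remain.
#' @export
beta_profile <- function(plots, island_id, n_alpha, min_plot_n = 2) {
  comms <- plot_communities(plots, island_id)
  usable <- comms[vapply(comms, sum, numeric(1)) >= min_plot_n]
  if (length(usable) < length(comms))
    warning(sprintf("island '%s': %d plot(s) below %d individuals excluded",
                    island_id, length(comms) - length(usable), min_plot_n),
            call. = FALSE)
  if (length(usable) < 2) {
    warning(sprintf("island '%s' excluded: fewer than 2 usable plots",
                    island_id), call. = FALSE)
    return(NULL)
  }
  pooled <- as_abundance(unlist(unname(lapply(usable, function(v)
    structure(as.numeric(v), names = names(v))))))
  sn <- function(comm) expected_richness(comm, n_alpha, warn = FALSE)$value
  alpha_sn <- mean(vapply(usable, sn, numeric(1)))
  gamma_sn <- sn(pooled)
  spie_vals <- vapply(usable, function(c) suppressWarnings(calc_spie(c)),
                      numeric(1))
  finite <- is.finite(spie_vals)
  if (!all(finite))
    warning(sprintf("island '%s': %d plot(s) with undefined S_PIE excluded from averaging",
                    island_id, sum(!finite)), call. = FALSE)
  alpha_spie <- if (sum(finite) >= 1) mean(spie_vals[finite]) else NA_real_
  gamma_spie <- suppressWarnings(calc_spie(pooled))
  data.frame(island_id = island_id,
             n_alpha = as.integer(n_alpha),
             plot_count = length(usable),
             alpha_S_n = alpha_sn, gamma_S_n = gamma_sn,
             beta_S_n = gamma_sn / alpha_sn,
             alpha_S_PIE = alpha_spie, gamma_S_PIE = gamma_spie,
             beta_S_PIE = gamma_spie / alpha_spie,
             stringsAsFactors = FALSE)
}

#' Beta-diversity table for all islands with plot data
#'
#' Computes [beta_profile()] for every island holding at least two plots,
#' at a common plot-grain rarefaction size, and attaches island areas.
#'
#' @param dataset An [archipelago()] dataset with plot data, or a plot
#'   table plus `metadata`.
#' @param metadata Optional metadata data.frame (island_id, area_km2) when
#'   `dataset` is a raw plot table.
#' @param n_alpha Common rarefaction size; default [alpha_scale_n()].
#' @param min_plot_n See [beta_profile()].
#' @return data.frame of beta profiles with `area_km2`.
#' @export
beta_table <- function(dataset, metadata = NULL, n_alpha = NULL,
                       min_plot_n = 2) {
  if (inherits(dataset, "archipelago")) {
    plots <- dataset$plots
    metadata <- dataset$metadata
  } else {
    plots <- dataset
  }
  if (is.null(plots) || nrow(plots) == 0)
    stop("no plot data available", call. = FALSE)
  if (is.null(n_alpha)) n_alpha <- alpha_scale_n(plots)
  n_per_island <- tapply(plots$plot_id, plots$island_id,
                         function(p) length(unique(p)))
  ids <- sort(names(n_per_island)[n_per_island >= 2])
  profiles <- lapply(ids, function(id)
    beta_profile(plots, id, n_alpha, min_plot_n = min_plot_n))
  profiles <- profiles[!vapply(profiles, is.null, logical(1))]
  if (length(profiles) == 0)
    stop("no islands with >= 2 usable plots", call. = FALSE)
  tab <- do.call(rbind, profiles)
  if (!is.null(metadata))
    tab <- merge(metadata[c("island_id", "area_km2")], tab, by = "island_id",
                 sort = TRUE)
  tab
}

#' Regress within-island beta-diversity on island area
#'
#' Log-log OLS of each beta ratio on island area. A significantly positive
#' slope indicates that within-island compositional heterogeneity grows
#' with island size and may contribute to the ISAR.
#'
#' @param profiles A [beta_table()] data.frame (needs `area_km2`), or a
#'   profile data.frame plus `areas`.
#' @param areas Optional vector of island areas matching `profiles` rows.
#' @return Named list of two [fit_loglog()] objects: `beta_S_n`,
#'   `beta_S_PIE`.
#' @export
beta_area_regression <- function(profiles, areas = NULL) {
  if (is.null(areas)) {
    if (!"area_km2" %in% names(profiles))
      stop("profiles lack area_km2; supply areas", call. = FALSE)
    areas <- profiles$area_km2
  }
  list(beta_S_n = fit_loglog(areas, profiles$beta_S_n),
       beta_S_PIE = fit_loglog(areas, profiles$beta_S_PIE))
}
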