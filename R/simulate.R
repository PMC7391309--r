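#' Sample a regional species pool from a lognormal SAD
#'
#' Draws relative abundances for a regional species pool from a lognormal
#' species-abundance distribution — the standard macroecological default —
#' and normalizes them to sum to one. `sad_shape` is the lognormal standard
#' deviation on the log scale: 0 gives a perfectly even pool, values around
#' 1-1.5 give realistic dominance structure.
#'
#' @param s_pool Number of species in the pool (>= 2).
#' @param sad_shape Lognormal sdlog parameter (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `"regional_pool"`: list with `rel_abund`
#'   (named, sums to 1) and `sad_shape`.
#' @export
sample_regional_pool <- function(s_pool, sad_shape = 1, seed = NULL) {
  if (length(s_pool) != 1 || s_pool < 2 || s_pool != trunc(s_pool))
    stop("s_pool must be an integer >= 2", call. = FALSE)
  if (sad_shape < 0) stop("sad_shape must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rlnorm(s_pool, meanlog = 0, sdlog = sad_shape)
  p <- x / sum(x)
  names(p) <- sprintf("sp%03d", seq_len(s_pool))
  structure(list(rel_abund = p, sad_shape = sad_shape),
            class = "regional_pool")
}

#' @export
print.regional_pool <- function(x, ...) {
  cat(sprintf("Regional pool: %d species, sad_shape = %.3g, dominance (max/median) = %.2f\n",
              length(x$rel_abund), x$sad_shape,
              max(x$rel_abund) / stats::median(x$rel_abund)))
  invisible(x)
}

#' Configure a synthetic archipelago scenario
#'
#' Defines one simulated archipelago under a named ISAR-generating
#' mechanism. Generation is two-stage. First the island community: a
#' census of K_i = round(k0 * area) individuals drawn multinomially from
#' the island-specific relative abundances — larger islands hold
#' proportionally more individuals, which is the passive-sampling null's
#' engine (island richness is the richness realized among those K_i
#' individuals). Second the survey: J_i = round(j0 * area^d) individuals
#' sampled from the island community; the survey is what the analysis
#' sees. Survey effort grows far more slowly than the census (d = 0.0625
#' by default), keeping every island's reference-n extrapolation near the
#' reliable <= 2x range while the underlying communities still span orders
#' of magnitude in size.
#'
#' Only the effect parameter of the named scenario may be nonzero; the
#' others are forced to neutral values so every scenario with its effect at
#' zero coincides with the passive-sampling null:
#'
#' * `passive` — every island samples the shared regional pool.
#' * `disproportionate_rare` — species rarer than the pool's
#'   60th-percentile abundance are retained with probability decaying on
#'   smaller islands (`rare_boost` sets the strength); the dominant
#'   species are untouched.
#' * `evenness_shift` — relative abundances are raised to a power
#'   theta(area) decreasing from 1 to 1 - `evenness_gradient` as area
#'   grows, flattening the SAD on larger islands.
#' * `heterogeneity` — island communities are passive, but individuals are
#'   clumped among plots with strength increasing with area up to
#'   `clumping`.
#'
#' @param scenario One of `"passive"`, `"disproportionate_rare"`,
#'   `"evenness_shift"`, `"heterogeneity"`.
#' @param island_areas Island areas in km^2 (>= 3 values, all > 0).
#' @param s_pool,sad_shape Regional pool settings (see
#'   [sample_regional_pool()]).
#' @param k0 Census individuals (community size) on an island of 1 km^2;
#'   the census scales linearly with area.
#' @param j0 Individuals surveyed on an island of 1 km^2.
#' @param d Survey-effort exponent of J ~ area^d.
#' @param rare_boost Strength of area-dependent rare-species retention
#'   (active only under `disproportionate_rare`).
#' @param evenness_gradient Area-dependence of SAD evenness in `[0, 1)`
#'   (active only under `evenness_shift`).
#' @param clumping Maximum within-island aggregation in `[0, 1)` (active
#'   only under `heterogeneity`).
#' @param plots_per_island Function mapping (area rank, island count) to a
#'   plot count; default increases from 2 on the smallest island to 10 on
#'   the largest. Plots are simulated only under `heterogeneity` unless
#'   `force_plots = TRUE`.
#' @param force_plots Simulate plots in every scenario.
#' @param seed Master seed; all randomness derives from it.
#' @return Object of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario = c("passive", "disproportionate_rare",
                                         "evenness_shift", "heterogeneity"),
                            island_areas,
                            s_pool = 3200, sad_shape = 2,
                            k0 = 2e6, j0 = 2000, d = 0.0625,
                            rare_boost = 0.15,
                            evenness_gradient = 0.5,
                            clumping = 0.8,
                            plots_per_island = NULL,
                            force_plots = FALSE,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  if (length(island_areas) < 3 || any(island_areas <= 0))
    stop("island_areas must hold >= 3 positive areas", call. = FALSE)
  if (j0 <= 0 || d < 0) stop("j0 must be > 0 and d >= 0", call. = FALSE)
  if (k0 <= 0) stop("k0 must be > 0", call. = FALSE)
  if (round(k0 * max(island_areas)) > .Machine$integer.max)
    stop("k0 * max(area) exceeds the largest representable census size",
         call. = FALSE)
  if (rare_boost < 0) stop("rare_boost must be >= 0", call. = FALSE)
  if (evenness_gradient < 0 || evenness_gradient >= 1)
    stop("evenness_gradient must lie in [0, 1)", call. = FALSE)
  if (clumping < 0 || clumping >= 1)
    stop("clumping must lie in [0, 1)", call. = FALSE)
  # parameters not belonging to the named scenario are forced neutral
  if (scenario != "disproportionate_rare") rare_boost <- 0
  if (scenario != "evenness_shift") evenness_gradient <- 0
  if (scenario != "heterogeneity") clumping <- 0
  if (is.null(plots_per_island))
    plots_per_island <- function(rank, n)
      as.integer(round(2 + 8 * (rank - 1) / max(1, n - 1)))
  structure(list(scenario = scenario,
                 island_areas = as.numeric(island_areas),
                 s_pool = as.integer(s_pool), sad_shape = sad_shape,
                 k0 = k0, j0 = j0, d = d,
                 rare_boost = rare_boost,
                 evenness_gradient = evenness_gradient,
                 clumping = clumping,
                 plots_per_island = plots_per_island,
                 force_plots = isTRUE(force_plots),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Island-specific relative abundances under each mechanism.
# disproportionate_rare kernel: species rarer than the pool's 60th-percentile
# abundance p_ref get retention weight
# w_s = (area / area_max)^(rare_boost * ln(p_ref / p_s)), i.e. the rarer the
# species and the smaller the island, the lower its retention; on the
# largest island the pool is unchanged. After winnowing, abundances are
# renormalized; the dominant species keep their relative structure, so
# PIE/S_PIE responds only weakly (through the small mass the rare guild
# held).
# evenness_shift kernel: p^theta(area) with theta falling linearly in
# ln(area) from 1 to 1 - evenness_gradient; theta < 1 flattens the SAD.
.island_probs <- function(pool_p, area, config) {
  areas <- config$island_areas
  switch(config$scenario,
    passive = ,
    heterogeneity = pool_p,
    disproportionate_rare = {
      if (config$rare_boost == 0) return(pool_p)
      p_ref <- stats::quantile(pool_p, 0.6, names = FALSE)
      expo <- config$rare_boost * pmax(0, log(p_ref / pool_p))
      w <- pmin(1, (area / max(areas))^expo)
      q <- pool_p * w
      q / sum(q)
    },
    evenness_shift = {
      if (config$evenness_gradient == 0) return(pool_p)
      lo <- log(min(areas)); hi <- log(max(areas))
      frac <- if (hi > lo) (log(area) - lo) / (hi - lo) else 0.5
      theta <- 1 - config$evenness_gradient * frac
      q <- pool_p^theta
      q / sum(q)
    })
}

#' Simulate one island's surveyed community
#'
#' Two-stage draw. Census stage: K = round(k0 * area) individuals are
#' drawn multinomially from the island-specific relative abundances
#' implied by the scenario (see [scenario_config()] for the mechanism
#' kernels); these K individuals are the island's community, and the
#' species among them are the island's true richness. Survey stage:
#' J = round(j0 * area^d) individuals are sampled from that community
#' (multinomially from its realized composition; survey effort is a small
#' fraction of the census). The survey is what the analysis observes.
#'
#' @param pool A [sample_regional_pool()] result.
#' @param area Island area in km^2 (> 0).
#' @param config A [scenario_config()].
#' @param island_seed Integer seed for this island's draw.
#' @param census Return the census community instead of the survey
#'   (ground truth for tests).
#' @return An abundance vector of the surveyed (or census) community.
#' @export
simulate_island <- function(pool, area, config, island_seed = NULL,
                            census = FALSE) {
  stopifnot(inherits(pool, "regional_pool"), inherits(config, "scenario_config"))
  if (area <= 0) stop("area must be > 0", call. = FALSE)
  if (!is.null(island_seed)) set.seed(island_seed)
  K <- max(1L, as.integer(round(config$k0 * area)))
  probs <- .island_probs(pool$rel_abund, area, config)
  comm <- as.integer(stats::rmultinom(1, K, probs))
  names(comm) <- names(pool$rel_abund)
  if (census) return(as_abundance(comm))
  J <- max(1L, min(K, as.integer(round(config$j0 * area^config$d))))
  survey <- .rmvhyper(comm, J)
  names(survey) <- names(pool$rel_abund)
  as_abundance(survey)
}

# Multivariate hypergeometric draw: J distinct individuals sampled without
# replacement from a census with per-species counts `counts`. Sequential
# conditional rhyper draws; exact and O(S).
.rmvhyper <- function(counts, J) {
  S <- length(counts)
  out <- integer(S)
  remaining <- sum(counts)
  need <- as.integer(J)
  for (s in seq_len(S)) {
    if (need == 0L) break
    remaining <- remaining - counts[s]
    if (remaining <= 0) {
      out[s] <- need
      need <- 0L
      break
    }
    x <- as.integer(stats::rhyper(1, counts[s], remaining, need))
    out[s] <- x
    need <- need - x
  }
  out
}

#' Distribute an island community over survey plots
#'
#' Allocates every species' individuals to plots with a
#' Dirichlet-multinomial: per-plot weights are drawn from a symmetric
#' Dirichlet with concentration (1 - clumping) / clumping. As clumping -> 0
#' the weights become uniform and placement is random (the passive limit);
#' as clumping -> 1 each species piles into few plots. Counts are conserved
#' exactly: per-species plot sums equal the island counts.
#'
#' @param island_community An abundance vector.
#' @param plot_count Number of plots (>= 2).
#' @param clumping Aggregation strength in `[0, 1)`.
#' @param seed Optional integer seed.
#' @param island_id Island id recorded on the output rows.
#' @return data.frame of plot records (island_id, plot_id, species_id,
#'   abundance).
#' @export
simulate_plots <- function(island_community, plot_count, clumping = 0,
                           seed = NULL, island_id = "island") {
  island_community <- as_abundance(island_community)
  if (plot_count < 2 || plot_count != trunc(plot_count))
    stop("plot_count must be an integer >= 2", call. = FALSE)
  if (clumping < 0 || clumping >= 1)
    stop("clumping must lie in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(plot_count)
  plot_ids <- sprintf("plot%02d", seq_len(k))
  counts <- vapply(island_community, function(n_sp) {
    if (clumping == 0) {
      w <- rep(1 / k, k)
    } else {
      conc <- (1 - clumping) / clumping
      g <- stats::rgamma(k, shape = conc)
      if (sum(g) == 0) g[sample.int(k, 1)] <- 1   # numeric underflow at tiny conc
      w <- g / sum(g)
    }
    as.integer(stats::rmultinom(1, n_sp, w))
  }, integer(k))                    # k x S matrix
  keep <- which(counts > 0, arr.ind = TRUE)
  out <- data.frame(island_id = island_id,
                    plot_id = plot_ids[keep[, 1]],
                    species_id = names(island_community)[keep[, 2]],
                    abundance = counts[keep],
                    stringsAsFactors = FALSE)
  out[order(out$plot_id, out$species_id), , drop = FALSE]
}

#' Simulate a whole archipelago under a named mechanism
#'
#' Draws the regional pool, then each island community (and, under the
#' heterogeneity scenario or on request, its plots) with per-island seeds
#' derived deterministically from the master seed, and assembles an
#' [archipelago()] dataset. Under `heterogeneity`, per-island clumping
#' rises linearly in log area from 0 on the smallest island to the
#' configured maximum on the largest. The generating config is attached as
#' the `"ground_truth"` attribute.
#'
#' @param config A [scenario_config()].
#' @return An [archipelago()] dataset (`taxon` = the scenario name).
#' @export
simulate_archipelago <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- length(config$island_areas)
  seeds <- sample.int(.Machine$integer.max, 2 * n + 1)
  pool <- sample_regional_pool(config$s_pool, config$sad_shape,
                               seed = seeds[1])
  areas <- config$island_areas
  ids <- sprintf("isl%03d", seq_len(n))
  rank <- rank(areas, ties.method = "first")

  ab_rows <- vector("list", n)
  plot_rows <- vector("list", n)
  want_plots <- config$scenario == "heterogeneity" || config$force_plots
  lo <- log(min(areas)); hi <- log(max(areas))
  for (i in seq_len(n)) {
    comm <- simulate_island(pool, areas[i], config, island_seed = seeds[1 + i])
    ab_rows[[i]] <- data.frame(island_id = ids[i],
                               species_id = names(comm),
                               abundance = as.integer(comm),
                               stringsAsFactors = FALSE)
    if (want_plots) {
      frac <- if (hi > lo) (log(areas[i]) - lo) / (hi - lo) else 0.5
      c_i <- if (config$scenario == "heterogeneity")
        config$clumping * frac else config$clumping
      k_i <- max(2L, config$plots_per_island(rank[i], n))
      plot_rows[[i]] <- simulate_plots(comm, k_i, clumping = c_i,
                                       seed = seeds[1 + n + i],
                                       island_id = ids[i])
    }
  }
  ds <- archipelago(do.call(rbind, ab_rows),
                    data.frame(island_id = ids, area_km2 = areas,
                               stringsAsFactors = FALSE),
                    plots = if (want_plots) do.call(rbind, plot_rows) else NULL,
                    taxon = config$scenario)
  attr(ds, "ground_truth") <- config
  ds
}

#' Write a simulated dataset with its ground-truth sidecar
#'
#' Emits the CSV layout [read_island_table()] reads plus a JSON sidecar
#' recording the generating scenario, parameters and seed.
#'
#' @param dataset A simulated [archipelago()] dataset (with a
#'   `"ground_truth"` attribute).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(abundances = file.path(dir, "abundances.csv"),
                metadata = file.path(dir, "metadata.csv"),
                plots = if (!is.null(dataset$plots))
                  file.path(dir, "plots.csv") else NULL,
                ground_truth = file.path(dir, "ground_truth.json"))
  write_island_table(dataset, paths$abundances, paths$metadata, paths$plots)
  gt <- attr(dataset, "ground_truth")
  if (!is.null(gt)) {
    gt_out <- gt[setdiff(names(gt), "plots_per_island")]
    jsonlite::write_json(gt_out, paths$ground_truth, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(paths)
}
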