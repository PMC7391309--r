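test_that("regional pools are normalized, reproducible and shaped by sad_shape", {
  pool <- sample_regional_pool(100, 1.5, seed = 3)
  expect_equal(sum(pool$rel_abund), 1, tolerance = 1e-12)
  expect_identical(pool, sample_regional_pool(100, 1.5, seed = 3))
  # near-degenerate shape: almost even pool
  even <- sample_regional_pool(50, 1e-4, seed = 3)
  expect_lt(max(even$rel_abund) / min(even$rel_abund), 1.01)
  # realistic dominance at shape 1.5 (checked over several pools)
  doms <- vapply(1:5, function(s) {
    p <- sample_regional_pool(100, 1.5, seed = s)$rel_abund
    max(p) / stats::median(p)
  }, numeric(1))
  expect_true(all(doms > 10))
  expect_error(sample_regional_pool(1), ">= 2")
})

test_that("scenario configs force off-scenario parameters to neutral values", {
  areas <- c(1, 10, 100)
  cfg <- scenario_config("passive", areas, rare_boost = 0.5, clumping = 0.5,
                        evenness_gradient = 0.3)
  expect_identical(cfg$rare_boost, 0)
  expect_identical(cfg$evenness_gradient, 0)
  expect_identical(cfg$clumping, 0)
  cfg <- scenario_config("disproportionate_rare", areas, rare_boost = 0.5)
  expect_identical(cfg$rare_boost, 0.5)
  expect_identical(cfg$clumping, 0)
  expect_error(scenario_config("passive", c(1, 10)), ">= 3")
  expect_error(scenario_config("passive", areas, clumping = 1), "clumping")
  expect_error(scenario_config("heterogeneity", areas, clumping = -0.1),
               "clumping")
})

test_that("identical configs reproduce bit-identical archipelagos", {
  cfg <- scenario_config("heterogeneity", 10^seq(-1, 2, length.out = 5),
                         s_pool = 80, sad_shape = 1, k0 = 1e4, j0 = 200,
                         seed = 21)
  ds1 <- simulate_archipelago(cfg)
  ds2 <- simulate_archipelago(cfg)
  expect_identical(ds1$abundances, ds2$abundances)
  expect_identical(ds1$plots, ds2$plots)
  expect_identical(ds1$metadata, ds2$metadata)
})

test_that("survey sizes follow round(j0 * area^d) and plots conserve island counts", {
  areas <- c(0.5, 5, 50)
  cfg <- scenario_config("heterogeneity", areas, s_pool = 60, sad_shape = 1,
                         k0 = 1e5, j0 = 400, d = 0.25, clumping = 0.6,
                         seed = 8)
  ds <- simulate_archipelago(cfg)
  comms <- island_communities(ds)
  for (i in seq_along(areas)) {
    id <- ds$metadata$island_id[i]
    expect_identical(sum(comms[[id]]),
                     as.integer(round(400 * areas[i]^0.25)))
    pooled <- pool_plots(ds$plots, id)
    expect_identical(sort(pooled), sort(comms[[id]]))
  }
})

test_that("neutral effect parameters reproduce the passive scenario exactly", {
  areas <- 10^seq(-1, 2, length.out = 5)
  base <- scenario_config("passive", areas, s_pool = 80, sad_shape = 1,
                          k0 = 1e4, j0 = 200, seed = 5)
  ds_passive <- simulate_archipelago(base)
  for (scen in c("disproportionate_rare", "evenness_shift")) {
    cfg <- scenario_config(scen, areas, s_pool = 80, sad_shape = 1,
                           k0 = 1e4, j0 = 200, seed = 5)
    cfg[[if (scen == "disproportionate_rare") "rare_boost"
         else "evenness_gradient"]] <- 0
    ds <- simulate_archipelago(cfg)
    expect_identical(ds$abundances, ds_passive$abundances)
  }
})

test_that("plot allocation is uniform without clumping and aggregated with it", {
  comm <- stats::setNames(rep(500L, 8), paste0("s", 1:8))
  pl <- simulate_plots(comm, 4, clumping = 0, seed = 2, island_id = "A")
  prof <- beta_profile(pl, "A", n_alpha = 500)
  expect_equal(prof$beta_S_n, 1, tolerance = 0.05)
  # strong clumping: pooled scale holds far more species than single plots
  set.seed(31)
  betas <- vapply(1:20, function(i) {
    pl <- simulate_plots(comm, 4, clumping = 0.8, island_id = "A")
    suppressWarnings(beta_profile(pl, "A", n_alpha = 500)$beta_S_n)
  }, numeric(1))
  expect_gt(mean(betas), 1.15)
  expect_gt(mean(betas > 1), 0.9)
  # conservation holds species by species
  pl <- simulate_plots(comm, 5, clumping = 0.9, seed = 4, island_id = "A")
  expect_identical(sort(pool_plots(pl, "A")), sort(comm))
  expect_error(simulate_plots(comm, 1, 0), "plot_count")
  expect_error(simulate_plots(comm, 4, 1), "clumping")
})

test_that("passive islands share one rarefaction curve regardless of area", {
  # the defining property of random placement: expected richness at a
  # common n is independent of island size
  areas <- c(0.1, 10, 1000)
  cfg <- scenario_config("passive", areas, s_pool = 150, sad_shape = 1.2,
                         k0 = 2e4, j0 = 120, d = 0.5, seed = 77)
  set.seed(77)
  sn <- matrix(NA_real_, 60, 2)
  pool <- sample_regional_pool(150, 1.2, seed = 99)
  for (r in 1:60)
    for (j in 1:2)
      sn[r, j] <- interpolated_richness(
        simulate_island(pool, areas[c(1, 3)][j], cfg), 30)$value
  expect_lt(abs(mean(sn[, 1]) - mean(sn[, 2])),
            3 * sqrt(sum(apply(sn, 2, var)) / 60))
})

test_that("the evenness gradient raises realized S_PIE with area", {
  areas <- 10^seq(-1, 3, length.out = 10)
  cfg <- scenario_config("evenness_shift", areas, s_pool = 200,
                         sad_shape = 1.5, k0 = 1e5, j0 = 500,
                         evenness_gradient = 0.5, seed = 13)
  ds <- simulate_archipelago(cfg)
  spie <- vapply(island_communities(ds), calc_spie, numeric(1))
  expect_gt(cor(log(ds$metadata$area_km2), log(spie), method = "spearman"),
            0.5)
})

test_that("ground truth rides along and survives the CSV sidecar", {
  cfg <- scenario_config("passive", c(1, 10, 100), s_pool = 50, sad_shape = 1,
                         k0 = 1e4, j0 = 100, seed = 4)
  ds <- simulate_archipelago(cfg)
  expect_identical(attr(ds, "ground_truth")$scenario, "passive")
  dir <- withr::local_tempdir()
  paths <- write_simulation(ds, dir)
  expect_true(file.exists(paths$ground_truth))
  gt <- jsonlite::read_json(paths$ground_truth)
  expect_identical(gt$scenario, "passive")
  expect_identical(gt$seed, 4L)
  ds2 <- read_island_table(paths$abundances, paths$metadata)
  expect_identical(island_communities(ds2), island_communities(ds))
})
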