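test_that("noiseless power laws are recovered exactly", {
  a <- c(1, 10, 100, 1000, 10000)
  fit <- fit_loglog(a, 2 * a^0.25)
  expect_equal(fit$slope, 0.25, tolerance = 1e-10)
  expect_equal(fit$intercept, log(2), tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lt(fit$p_slope, 1e-8)
})

test_that("constant responses give a null slope and non-positive adjusted R2", {
  fit <- fit_loglog(1:10, rep(5, 10))
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_lte(fit$r2_adj, 0)
  expect_equal(fit$p_slope, 1)
})

test_that("adjusted R2 is reported as computed, unclamped and possibly negative", {
  set.seed(11)
  a <- 10^runif(10, -1, 3)
  y <- exp(rnorm(10, mean = 1, sd = 0.3))  # no area relationship
  fit <- fit_loglog(a, y)
  expect_equal(fit$r2_adj, summary(fit$model)$adj.r.squared)
  # over repeated nulls, negative adjusted R2 values must occur and survive
  set.seed(12)
  r2s <- replicate(50, fit_loglog(a, exp(rnorm(10)))$r2_adj)
  expect_true(any(r2s < 0))
})

test_that("undefined metric values are dropped pairwise with a logged count", {
  a <- c(1, 10, 100, 1000)
  y <- c(2, 4, Inf, 8)
  expect_message(fit <- fit_loglog(a, y), "dropped 1")
  expect_identical(fit$n_points, 3L)
  expect_identical(fit$n_dropped, 1L)
  expect_error(suppressMessages(fit_loglog(a, c(1, 2, NA, Inf))), "at least 3")
  expect_error(fit_loglog(rep(2, 5), 1:5), "zero variance")
})

test_that("slope estimation is unbiased and its 2-SE interval has t coverage", {
  set.seed(33)
  n <- 200
  reps <- 1000
  slopes <- numeric(reps)
  for (r in seq_len(reps)) {
    x <- exp(runif(n, 0, 5))
    y <- exp(1.5 + 0.25 * log(x) + rnorm(n, sd = 0.1))
    slopes[r] <- fit_loglog(x, y)$slope
  }
  expect_lt(abs(mean(slopes) - 0.25), 0.01)

  # small-sample coverage: +/- 2 estimated SE around the truth covers the
  # estimate at the t(18) reference rate (~0.94), not the normal 0.954
  set.seed(34)
  n <- 20
  cover <- logical(1000)
  for (r in seq_len(1000)) {
    x <- exp(runif(n, 0, 5))
    y <- exp(1.5 + 0.25 * log(x) + rnorm(n, sd = 0.2))
    f <- fit_loglog(x, y)
    cover[r] <- abs(f$slope - 0.25) <= 2 * f$se_slope
  }
  t_ref <- 1 - 2 * pt(-2, df = n - 2)
  expect_lt(abs(mean(cover) - t_ref), 0.025)
})

test_that("mechanism classification is total over the slope/significance truth table", {
  fake <- function(slope, p) structure(list(slope = slope, p_slope = p),
                                       class = "loglog_fit")
  cases <- expand.grid(sn_slope = c(0.1, -0.1), sn_p = c(0.01, 0.5),
                       sp_slope = c(0.1, -0.1), sp_p = c(0.01, 0.5))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    fits <- list(S_total = fake(0.2, 0.001),
                 S_n = fake(cs$sn_slope, cs$sn_p),
                 S_PIE = fake(cs$sp_slope, cs$sp_p))
    v <- classify_mechanism(fits, alpha_level = 0.05)
    sn_sig <- cs$sn_p <= 0.05 && cs$sn_slope > 0
    sp_sig <- cs$sp_p <= 0.05 && cs$sp_slope > 0
    want <- if (!sn_sig) "passive_sampling_not_rejected"
            else if (!sp_sig) "disproportionate_rare"
            else "disproportionate_common_and_rare"
    expect_identical(v$verdict, want)
    expect_true(is.na(v$heterogeneity_implicated))
  }
})

test_that("classification reproduces the published-style taxon outcomes", {
  fake <- function(slope, p) structure(list(slope = slope, p_slope = p),
                                       class = "loglog_fit")
  base <- list(S_total = fake(0.14, 1e-4))
  # rarefied richness rises, evenness does not: rare species drive the ISAR
  birds <- c(base, list(S_n = fake(0.08, 1e-4), S_PIE = fake(0.05, 0.15)))
  expect_identical(classify_mechanism(birds)$verdict, "disproportionate_rare")
  # both rise: common species shift too
  butterflies <- c(base, list(S_n = fake(0.11, 0.04), S_PIE = fake(0.17, 0.02)))
  expect_identical(classify_mechanism(butterflies)$verdict,
                   "disproportionate_common_and_rare")
  # S_n flat: sampling alone explains the ISAR
  flat <- c(base, list(S_n = fake(0.02, 0.6), S_PIE = fake(0.01, 0.8)))
  expect_identical(classify_mechanism(flat)$verdict,
                   "passive_sampling_not_rejected")
})

test_that("beta fits set the heterogeneity co-verdict flag", {
  fake <- function(slope, p) structure(list(slope = slope, p_slope = p),
                                       class = "loglog_fit")
  fits <- list(S_total = fake(0.2, 0.001), S_n = fake(0.1, 0.01),
               S_PIE = fake(0, 0.9))
  beta_pos <- list(beta_S_n = fake(0.2, 0.01), beta_S_PIE = fake(0, 0.9))
  beta_null <- list(beta_S_n = fake(0.01, 0.7), beta_S_PIE = fake(-0.1, 0.02))
  expect_true(classify_mechanism(fits, beta_pos)$heterogeneity_implicated)
  expect_false(classify_mechanism(fits, beta_null)$heterogeneity_implicated)
  expect_error(classify_mechanism(fits[1:2]), "S_PIE")
  expect_error(classify_mechanism(fits, alpha_level = 1.2), "alpha_level")
})
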