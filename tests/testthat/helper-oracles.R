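# Independent oracles used across tests. These deliberately avoid the
# package's analytic code paths: rarefaction is checked against Monte-Carlo
# subsampling of individuals, PIE against exhaustive pair enumeration.

# Random community with S_obs <= s_max species and total N <= n_max.
random_community <- function(s_max = 10, n_max = 60) {
  s <- sample(2:s_max, 1)
  # counts >= 1 per species, total capped at n_max
  counts <- 1L + stats::rpois(s, lambda = stats::runif(1, 0, n_max / s))
  while (sum(counts) > n_max) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  names(counts) <- paste0("sp", seq_len(s))
  counts
}

# Monte-Carlo mean richness of subsamples without replacement, for every
# n in 1..N at once: each permutation of the individuals yields a full
# species-accumulation curve.
mc_rarefaction_curve <- function(community, n_draws = 20000) {
  ind <- rep(seq_along(community), community)
  N <- length(ind)
  acc <- numeric(N)
  for (b in seq_len(n_draws)) {
    acc <- acc + cumsum(!duplicated(sample(ind)))
  }
  acc / n_draws
}

# Exact probability that two individuals drawn without replacement belong
# to different species, by enumeration of all unordered pairs.
pairwise_pie <- function(community) {
  ind <- rep(seq_along(community), community)
  N <- length(ind)
  pairs <- utils::combn(N, 2)
  mean(ind[pairs[1, ]] != ind[pairs[2, ]])
}

# Tiny archipelago data.frames used by data-model and pipeline tests.
toy_tables <- function() {
  list(
    abundances = data.frame(
      island_id = c("A", "A", "A", "B", "B", "C"),
      species_id = c("x", "y", "z", "x", "w", "x"),
      abundance = c(1, 2, 3, 4, 1, 7),
      stringsAsFactors = FALSE),
    metadata = data.frame(
      island_id = c("A", "B", "C"),
      area_km2 = c(10, 100, 1000),
      stringsAsFactors = FALSE),
    plots = data.frame(
      island_id = c("A", "A", "A", "B", "B", "C"),
      plot_id = c("p1", "p1", "p2", "p1", "p2", "p1"),
      species_id = c("x", "y", "x", "x", "w", "x"),
      abundance = c(1, 2, 3, 4, 1, 7),
      stringsAsFactors = FALSE))
}
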