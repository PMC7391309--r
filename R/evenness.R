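#' Probability of interspecific encounter (PIE)
#'
#' Hurlbert's PIE: the probability that two individuals drawn from the
#' community without replacement belong to different species,
#' PIE = N/(N-1) * (1 - sum p_i^2) with p_i = N_i / N. PIE is weighted by
#' the common species and nearly insensitive to rare ones.
#'
#' @param community An abundance vector with total N >= 2.
#' @return PIE in `[0, 1]`.
#' @examples
#' calc_pie(c(a = 2, b = 2))  # (4/3) * (1 - 1/2) = 2/3
#' @export
calc_pie <- function(community) {
  community <- as_abundance(community)
  N <- sum(community)
  if (N < 2)
    stop("PIE requires at least 2 individuals", call. = FALSE)
  p <- community / N
  N / (N - 1) * (1 - sum(p^2))
}

#' Effective number of species of PIE (S_PIE)
#'
#' Converts PIE to an effective number of species, S_PIE = 1 / (1 - PIE)
#' (proportional to the inverse Simpson index). S_PIE equals S for a
#' perfectly even community in the large-N limit and is dominated by the
#' common species. When every individual is a different species PIE = 1 and
#' S_PIE is undefined; `Inf` is returned with a warning and such communities
#' are dropped from S_PIE regressions downstream (any finite substitute
#' would bias the S_PIE-area slope).
#'
#' @inheritParams calc_pie
#' @return S_PIE >= 1, or `Inf` when PIE = 1.
#' @examples
#' calc_spie(c(a = 2, b = 2))  # 3
#' @export
calc_spie <- function(community) {
  pie <- calc_pie(community)
  if (pie >= 1) {
    warning("all individuals are singletons: PIE = 1, S_PIE undefined (Inf)",
            call. = FALSE)
    return(Inf)
  }
  1 / (1 - pie)
}
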