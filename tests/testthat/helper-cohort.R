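# Shared fixture builders. Cohorts are cached per test run so expensive
# simulations are not repeated across test files.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(config)
  }
  .cohort_cache[[key]]
}

# Minimal counts row constructor.
counts_row <- function(individual = "i1", marker = "m1", pos = 1L,
                       nA = 0L, nC = 0L, nG = 0L, nT = 0L) {
  tibble::tibble(
    individual = individual, marker = marker, pos = pos,
    nA = nA, nC = nC, nG = nG, nT = nT
  )
}

# Small single-population config helper.
one_pop_config <- function(n_LL = 0, n_RR = 0, n_LR = 0, n_LLR = 0, n_RRL = 0,
                           popsys = "L-E", n_snps = 1, seed = 1, ...) {
  sim_config(
    snp_panel = default_snp_panel(n_snps),
    populations = tibble::tibble(
      population = "P1", popsys = popsys, region = "r1",
      lat = 50, lon = 14,
      n_LL = n_LL, n_RR = n_RR, n_LR = n_LR, n_LLR = n_LLR, n_RRL = n_RRL
    ),
    seed = seed,
    ...
  )
}

# Clean five-population parental cohort used by several modules: no
# sequencing error, high coverage, both parental species present.
parental_cohort <- function() {
  pops <- tibble::tibble(
    population = c("A", "B", "C", "D", "E"),
    popsys = c("all-R", "all-R", "R-E", "L-E", "L-E"),
    region = c("s", "s", "o", "c", "c"),
    lat = c(42, 43, 53, 49, 44), lon = c(27, 25, 14, 14, 16),
    n_LL = c(0, 0, 0, 30, 30), n_RR = c(30, 30, 30, 0, 0),
    n_LR = c(0, 0, 10, 10, 0), n_LLR = 0, n_RRL = 0
  )
  cached_cohort(
    "parental",
    sim_config(
      populations = pops, error_rate = 0, coverage_mean = 100,
      coverage_dispersion = 1e6, seed = 101
    )
  )
}

# Unit-level grouped-frequency data for association tests: `k` units per
# population system, binomial unit frequencies around system means.
unit_freq_data <- function(means = c("L-E" = 0.5, "E" = 0.5, "R-E" = 0.5),
                           k = 8, n = 40, lat_range = c(42, 54),
                           lon_range = c(12, 28)) {
  sys <- rep(names(means), each = k)
  tibble::tibble(
    unit = paste0("u", seq_along(sys)),
    popsys = sys,
    lat = stats::runif(length(sys), lat_range[1], lat_range[2]),
    lon = stats::runif(length(sys), lon_range[1], lon_range[2]),
    n = n,
    f = stats::rbinom(length(sys), n, means[sys]) / n
  )
}

# Known-truth classification for the default diagnostic panel: the
# designated (L) allele is expected fixed in LL and absent in RR.
panel_truth_classification <- function(panel) {
  tibble::tibble(
    snp = panel$snp, category = "species_specific",
    expected_LL = 1, expected_RR = 0
  )
}
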