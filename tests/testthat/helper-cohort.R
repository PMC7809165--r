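# Shared fixtures, built in code and memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small neutral cohort (no planted effects) for structural checks.
small_cohort <- function() {
  memo("small_cohort", function() {
    simulate_cohort(sim_config(n_individuals = 150, n_markers = 12,
                               n_otus = 10, n_pens = 30, seed = 101))
  })
}

# Cohort with one planted mediation chain, plus its analysis table.
chain_cohort <- function() {
  memo("chain_cohort", function() {
    simulate_cohort(sim_config(
      n_individuals = 400, n_markers = 8, n_otus = 10, n_pens = 60,
      effects = list(
        alpha = data.frame(marker = "snp_3", otu = "otu_4", effect = 0.5),
        beta = data.frame(otu = "otu_4", response = "bf1", effect = 0.4),
        gamma = data.frame(marker = "snp_3", response = "bf1", effect = 0.1)),
      seed = 202))
  })
}

chain_data <- function() {
  memo("chain_data", function() mediation_data(chain_cohort(), min_total = 50))
}

standardize_oracle <- function(x) (x - mean(x)) / sd(x)

covs_m_of <- function(feature) c(paste0("cgb_", feature), "damline",
                                 paste0("sr_", feature))
covs_p_of <- covs_m_of

# Minimal mediation dataset generated directly (no design structure): fast
# enough for calibration loops. True chain alpha * beta with direct gamma.
toy_mediation_data <- function(n, alpha = 0, beta = 0, gamma = 0, seed = 1) {
  withr::with_seed(seed, {
    g <- rbinom(n, 2, 0.3)
    m <- alpha * g + rnorm(n)
    p <- beta * m + gamma * g + rnorm(n)
    tibble::tibble(p = p, m = m, g = g,
                   c1 = rnorm(n), c2 = rnorm(n), c3 = sample(1:2, n, TRUE))
  })
}

toy_fitter <- function() {
  mediation_fitter("p", "m", "g", covariates_m = c("c1", "c3", "c2"),
                   covariates_p = c("c1", "c3", "c2"))
}
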