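# Shared fixtures and independent oracles.

# One random realistic Siler schedule (uses the caller's RNG state).
# Adult mortality is anchored through the hazard at age 80 so draws span
# general-population schedules (e0 roughly 66-78) where an 85+-terminated
# abridged grid is an adequate summary of the death distribution.
random_siler <- function() {
  b2 <- runif(1, 0.09, 0.12)
  h80 <- exp(runif(1, log(0.07), log(0.18)))
  siler_params(a1 = runif(1, 0.004, 0.02), b1 = runif(1, 1, 2.5),
               c = runif(1, 2e-4, 1.2e-3), a2 = h80 / exp(80 * b2), b2 = b2)
}

# Constant-hazard parameters (exponential lifetime with rate `rate`).
constant_hazard <- function(rate = 0.02) {
  siler_params(a1 = 0, b1 = 1, c = rate, a2 = 0, b2 = 0.1)
}

# National-scale synthetic fixture, built once per test run.
.fixture_env <- new.env(parent = emptyenv())
national_fixture <- function() {
  if (is.null(.fixture_env$bundle)) {
    cfg <- scenario_config(counties_per_level = 15, county_pop_scale = 2e4,
                           seed = 20190101)
    .fixture_env$config <- cfg
    .fixture_env$bundle <- make_study_dataset(cfg)
  }
  .fixture_env
}

# Deaths / person-years in one age interval from simulated exact lifetimes:
# the brute-force central-death-rate oracle.
mx_from_lifetimes <- function(lifetimes, lo, hi) {
  alive <- lifetimes[lifetimes > lo]
  deaths <- sum(alive <= hi)
  py <- sum(pmin(alive, hi) - lo)
  c(mx = deaths / py, deaths = deaths)
}
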