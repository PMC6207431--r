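# Shared in-code fixtures for the test suite.

# Monthly series with a pure cosine seasonal cycle (no noise).
cosine_series <- function(years = 1990:1999, amplitude = 0.3, phase = 1,
                          base = 100, period = 12) {
  grid <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  tibble::tibble(
    year = grid$year, month = grid$month,
    rate = base * (1 + amplitude *
                     cos(2 * pi * (grid$month - phase) / period))
  )
}

# Small death table spanning two regions, two causes.
toy_deaths <- function() {
  tibble::tibble(
    year = rep(2015:2016, each = 8),
    month = rep(c(1, 1, 7, 7), 4),
    state = rep(c("FL", "NY"), 8),
    age_group = "65-74",
    sex = rep(c("male", "female"), each = 4, times = 2),
    cause = rep(c("I21", "C34"), times = 8),
    count = seq_len(16)
  )
}

# Simulation settings used by the recovery experiments: ~500 deaths/month,
# flat population, 37 years.
recovery_config <- function(phase = 1, amplitude = 0.2, seed = 1,
                            years = 1980:2016, ...) {
  simulation_config(
    years = years,
    seasonal = tibble::tibble(period = 12, amplitude = amplitude,
                              phase = phase, halflife = NA_real_),
    baseline_rate = 5e-4, population_start = 1e6, population_growth = 0,
    seed = seed, ...
  )
}

# One simulated stratum straight to corrected monthly rates.
simulated_rates <- function(cfg) {
  pop <- simulate_population(cfg)
  suppressMessages(
    stratum_rates(simulate_deaths(cfg, pop), pop)
  )
}

table1_totals <- function() {
  path <- system.file("extdata", "us_cause_totals_1980_2016.csv",
                      package = "mortseason")
  d <- readr::read_csv(path, show_col_types = FALSE)
  dplyr::rename(d, cause = category)
}
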