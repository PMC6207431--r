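# Validation experiments: parameter-recovery and operating-characteristic
# simulation studies for the wavelet test, the circular timing statistics
# and the seasonal-difference trend. These run the full pipeline on data
# from the synthetic generator under its reference conditions (37 years,
# ~500 deaths/month, 12-month amplitude 0.2) and summarise how well the
# planted truth is recovered.

derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(2^31 - 2, n))
}

reference_simulation <- function(phase = 1, amplitude = 0.2, seed = 1,
                                 years = 1980:2016, population = 1e6,
                                 baseline_rate = 5e-4,
                                 amplitude_by_year = NULL) {
  simulation_config(
    years = years,
    seasonal = tibble::tibble(period = 12, amplitude = amplitude,
                              phase = phase, halflife = NA_real_),
    amplitude_by_year = amplitude_by_year,
    baseline_rate = baseline_rate, population_start = population,
    population_growth = 0, seed = seed)
}

reference_rates <- function(cfg) {
  pop <- simulate_population(cfg)
  suppressMessages(stratum_rates(simulate_deaths(cfg, pop), pop))
}

#' Type-I error of the 12-month seasonality test on white noise
#'
#' Runs the full preprocessing-plus-wavelet test on `n_series` independent
#' Gaussian white-noise series and reports how often the 12-month p-value
#' falls at or below `alpha`. For a calibrated test the rejection rate
#' should sit near `alpha` (the plus-one p-value estimator makes the exact
#' attainable level `floor(alpha (n_sims + 1)) / (n_sims + 1)`).
#'
#' @param n_series Number of white-noise series (default 500).
#' @param length_months Series length (default 444, i.e. 37 years).
#' @param n_sims White-noise null simulations per test (default 100).
#' @param degree Detrending degree (default 4).
#' @param alpha Nominal level (default 0.05).
#' @param seed Integer seed.
#' @return A list: `rejection_rate`, `p_values`, `n_series`.
#' @export
wavelet_type1_experiment <- function(n_series = 500, length_months = 444,
                                     n_sims = 100, degree = 4, alpha = 0.05,
                                     seed = 1) {
  p <- withr::with_seed(seed, {
    vapply(seq_len(n_series), function(i) {
      x <- rnorm(length_months)
      cwt <- morlet_cwt(detrend_rescale(x, degree = degree))
      seasonality_pvalue(cwt, n_sims = n_sims)
    }, numeric(1))
  })
  list(rejection_rate = mean(p <= alpha), p_values = p,
       n_series = n_series)
}

#' Recovery of a planted seasonal peak month
#'
#' Simulates a 37-year stratum with a 12-month cosine seasonal cycle
#' peaking in `phase`, runs the rate construction and circular timing
#' statistics, and reports the signed circular errors of the centre of
#' gravity (against `phase`) and the negative centre of gravity (against
#' `phase + 6`).
#'
#' @param phase Planted peak month.
#' @param amplitude Planted relative amplitude (default 0.2).
#' @param seed Integer seed.
#' @return A one-row tibble: `phase`, `cog_month`, `cog_error`,
#'   `ncog_month`, `ncog_error` (errors in signed months, shortest arc).
#' @export
timing_recovery_experiment <- function(phase = 1, amplitude = 0.2, seed = 1) {
  rates <- reference_rates(reference_simulation(phase = phase,
                                                amplitude = amplitude,
                                                seed = seed))
  arc <- function(a, b) ((a - b + 6) %% 12) - 6
  cog <- centre_of_gravity(rates)
  ncog <- negative_centre_of_gravity(rates)
  tibble::tibble(
    phase = phase,
    cog_month = cog$month, cog_error = arc(cog$month, phase),
    ncog_month = ncog$month,
    ncog_error = arc(ncog$month, wrap_month(phase + 6)))
}

#' Coverage of the year-block bootstrap timing interval
#'
#' Repeats [timing_recovery_experiment()]'s data generation `n_reps` times
#' and reports how often the 95% bootstrap CI of the centre of gravity
#' covers the planted peak month.
#'
#' @inheritParams timing_recovery_experiment
#' @param n_reps Replicates (default 200).
#' @param n_boot Bootstrap resamples per CI (default 1000).
#' @return A list: `coverage`, `n_reps`, `mc_se` (binomial Monte-Carlo SE
#'   at nominal 95%).
#' @export
timing_coverage_experiment <- function(n_reps = 200, phase = 1,
                                       amplitude = 0.2, n_boot = 1000,
                                       seed = 1) {
  seeds <- derive_seeds(seed, 2 * n_reps)
  covered <- vapply(seq_len(n_reps), function(i) {
    rates <- reference_rates(reference_simulation(phase = phase,
                                                  amplitude = amplitude,
                                                  seed = seeds[i]))
    ci <- bootstrap_ci(rates, "cog", n = n_boot, seed = seeds[n_reps + i])
    ci_covers_month(ci, phase)
  }, logical(1))
  list(coverage = mean(covered), n_reps = n_reps,
       mc_se = sqrt(0.95 * 0.05 / n_reps))
}

#' Recovery of a planted decline in the seasonal percent difference
#'
#' Plants a linear decline of the true peak-versus-trough percent
#' difference (default 50% down to 25% over 37 years, i.e. a 25-point
#' fall) by setting the per-year amplitude path, and asks how often the
#' inverse-variance-weighted trend's fitted endpoint change lands within
#' 3 standard errors of the truth.
#'
#' @param n_reps Replicates (default 200).
#' @param start_diff,end_diff True percent difference at the first and
#'   last year.
#' @param seed Integer seed.
#' @return A list: `fraction_within_3se`, `mean_change`, `true_change`,
#'   `changes`, `n_reps`.
#' @export
trend_recovery_experiment <- function(n_reps = 200, start_diff = 50,
                                      end_diff = 25, seed = 1) {
  years <- 1980:2016
  target <- seq(start_diff, end_diff, length.out = length(years)) / 100
  amp <- target / (2 + target)  # percent diff of a cosine year: 2A/(1-A)
  seeds <- derive_seeds(seed, n_reps)
  res <- purrr::map_dfr(seq_len(n_reps), function(i) {
    cfg <- reference_simulation(amplitude = amp[1], seed = seeds[i],
                                amplitude_by_year = amp)
    diffs <- suppressMessages(
      yearly_percent_difference(reference_rates(cfg)))
    fit <- fit_weighted_trend(diffs)
    tibble::tibble(change = fit$change,
                   se_change = fit$slope_se * diff(fit$window))
  })
  true_change <- end_diff - start_diff
  list(fraction_within_3se =
         mean(abs(res$change - true_change) <= 3 * res$se_change),
       mean_change = mean(res$change), true_change = true_change,
       changes = res$change, n_reps = n_reps)
}

#' Type-I error of the trend slope under constant seasonality
#'
#' Simulates strata whose seasonal amplitude does not change (a mid-sized
#' national stratum: ~2000 deaths/month, amplitude 0.2) and reports how
#' often the weighted-trend slope is declared nonzero at `alpha`.
#'
#' @param n_strata Simulated strata (default 500).
#' @param alpha Nominal level (default 0.05).
#' @param seed Integer seed.
#' @return A list: `rejection_rate`, `p_values`, `n_strata`.
#' @export
trend_type1_experiment <- function(n_strata = 500, alpha = 0.05, seed = 1) {
  seeds <- derive_seeds(seed, n_strata)
  p <- vapply(seq_len(n_strata), function(i) {
    cfg <- reference_simulation(amplitude = 0.2, seed = seeds[i],
                                population = 4e6)
    diffs <- suppressMessages(
      yearly_percent_difference(reference_rates(cfg)))
    fit_weighted_trend(diffs)$p_value
  }, numeric(1))
  list(rejection_rate = mean(p <= alpha), p_values = p,
       n_strata = n_strata)
}
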