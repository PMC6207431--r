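#' Configure the synthetic mortality generator
#'
#' Builds a validated configuration for simulating stratified monthly death
#' counts with the structure the seasonality analysis assumes: a Poisson
#' count model whose mean combines a per-stratum baseline rate, a log-linear
#' secular trend, multiplicative sinusoidal seasonal components (12-month and
#' optionally 6-month), a month-length effect, and deterministic exponential
#' population growth.
#'
#' The monthly mean for a stratum is
#' \deqn{\mu(y, m) = N(y, m)\, r_0\, e^{\beta (y - y_0)}
#'   \big(1 + \sum_k A_k(y) \cos(2\pi (m - \phi_k) / P_k)\big)
#'   \cdot d(y, m)/31,}
#' where \eqn{N(y, m)} is the July-anchored interpolated monthly population,
#' \eqn{r_0} the baseline rate (deaths per person-month), \eqn{\beta} the
#' yearly log-linear trend, \eqn{A_k(y)} the (possibly decaying) amplitude of
#' the component with period \eqn{P_k} months peaking in month \eqn{\phi_k},
#' and \eqn{d(y, m)} the calendar month length (the last factor is dropped
#' when `month_length_effect = FALSE`). An `amplitude_halflife` makes
#' \eqn{A_k(y)} halve every that many years; `amplitude_by_year` instead
#' fixes the 12-month amplitude path per year explicitly.
#'
#' @param years Integer vector of simulated calendar years (default
#'   1980-2016, the usual 37-year analysis window).
#' @param strata Tibble of stratum keys (`age_group`, `sex`, `cause`,
#'   `region`); may carry per-stratum `baseline_rate` / `trend` columns that
#'   override the scalar defaults.
#' @param baseline_rate Deaths per person-month at `y0` (default `5e-4`,
#'   about 6 deaths per 1000 person-years — a mid-life to older-age stratum).
#' @param trend Log-linear slope per year of the underlying rate (default 0).
#' @param seasonal Tibble with columns `period` (12 or 6 months), `amplitude`
#'   (relative, >= 0), `phase` (peak month in \[1, 12\]) and optionally
#'   `halflife` (years for the amplitude to halve; `NA` = constant).
#' @param amplitude_by_year Optional numeric vector, one amplitude per year,
#'   overriding the 12-month component's amplitude path.
#' @param population_start Population at the first year (default `1e6`).
#' @param population_growth Yearly relative growth (default 0.01).
#' @param month_length_effect Scale means by days-in-month / 31?
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `simulation_config` object (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(years = 2000:2004, seed = 1)
#' head(simulate_deaths(cfg))
simulation_config <- function(years = 1980:2016,
                              strata = tibble::tibble(
                                age_group = "65-74", sex = "male",
                                cause = "all_cause", region = "national"),
                              baseline_rate = 5e-4,
                              trend = 0,
                              seasonal = tibble::tibble(
                                period = 12, amplitude = 0.2, phase = 1,
                                halflife = NA_real_),
                              amplitude_by_year = NULL,
                              population_start = 1e6,
                              population_growth = 0.01,
                              month_length_effect = TRUE,
                              seed = 1L) {
  years <- sort(as.integer(years))
  stopifnot(length(years) >= 1, is.data.frame(strata), nrow(strata) >= 1)
  if (baseline_rate <= 0) abort("baseline_rate must be > 0")
  if (population_start <= 0) abort("population_start must be > 0")
  if (!is.null(seasonal)) {
    stopifnot(all(c("period", "amplitude", "phase") %in% names(seasonal)))
    if (!"halflife" %in% names(seasonal)) seasonal$halflife <- NA_real_
    if (!all(seasonal$period %in% c(12, 6))) {
      abort("seasonal periods must be 12 or 6 months")
    }
    if (any(seasonal$amplitude < 0)) abort("amplitudes must be >= 0")
    if (any(seasonal$phase < 1 | seasonal$phase > 12)) {
      abort("phase must lie in [1, 12]")
    }
  } else {
    seasonal <- tibble::tibble(period = numeric(), amplitude = numeric(),
                               phase = numeric(), halflife = numeric())
  }
  if (!is.null(amplitude_by_year)) {
    if (length(amplitude_by_year) != length(years)) {
      abort("amplitude_by_year needs one value per simulated year")
    }
    if (any(amplitude_by_year < 0)) abort("amplitudes must be >= 0")
  }
  cfg <- structure(
    list(years = years, strata = tibble::as_tibble(strata),
         baseline_rate = baseline_rate, trend = trend, seasonal = seasonal,
         amplitude_by_year = amplitude_by_year,
         population_start = population_start,
         population_growth = population_growth,
         month_length_effect = isTRUE(month_length_effect),
         seed = as.integer(seed)),
    class = "simulation_config")
  # the multiplicative factor 1 + S must stay non-negative in every month
  worst <- min(seasonal_factor(cfg, rep(years, each = 12),
                               rep(1:12, times = length(years))))
  if (worst < 0) {
    abort("seasonal components drive the mean rate negative in some month")
  }
  cfg
}

# amplitude of component k at year y (halflife decay / explicit path)
component_amplitude <- function(cfg, k, years) {
  y0 <- cfg$years[1]
  if (!is.null(cfg$amplitude_by_year) && cfg$seasonal$period[k] == 12) {
    return(cfg$amplitude_by_year[match(years, cfg$years)])
  }
  a <- cfg$seasonal$amplitude[k]
  h <- cfg$seasonal$halflife[k]
  if (is.na(h)) rep(a, length(years)) else a * 2^(-(years - y0) / h)
}

# 1 + sum_k A_k(y) cos(2 pi (m - phi_k) / P_k), vectorised over (years, months)
seasonal_factor <- function(cfg, years, months) {
  s <- rep(1, length(years))
  for (k in seq_len(nrow(cfg$seasonal))) {
    s <- s + component_amplitude(cfg, k, years) *
      cos(2 * pi * (months - cfg$seasonal$phase[k]) / cfg$seasonal$period[k])
  }
  s
}

#' Simulate a yearly population table
#'
#' Deterministic exponential growth: each stratum's population in year
#' \eqn{y} is `population_start * (1 + population_growth)^(y - y0)`.
#'
#' @param config A [simulation_config()].
#' @return A tibble (`year`, `region`, `age_group`, `sex`, `population`).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  y0 <- config$years[1]
  strata <- dplyr::distinct(config$strata, .data$region, .data$age_group,
                            .data$sex)
  tidyr::expand_grid(strata, year = config$years) %>%
    dplyr::mutate(population = config$population_start *
                    (1 + config$population_growth)^(.data$year - y0)) %>%
    dplyr::select("year", "region", "age_group", "sex", "population")
}

#' Simulate a stratified monthly death-count table
#'
#' Draws Poisson monthly counts around the configured mean model (see
#' [simulation_config()] for the formula). Fully reproducible given the
#' config's seed.
#'
#' @param config A [simulation_config()].
#' @param population Yearly population table; defaults to
#'   [simulate_population()] of the same config.
#' @return A death table (`year`, `month`, `region`, `age_group`, `sex`,
#'   `cause`, `count`) in the schema produced by [load_deaths()].
#' @export
simulate_deaths <- function(config, population = simulate_population(config)) {
  stopifnot(inherits(config, "simulation_config"))
  if (!all(config$years %in% population$year)) {
    abort("population table does not cover all simulated years")
  }
  y0 <- config$years[1]
  grid <- tidyr::expand_grid(year = config$years, month = 1:12)

  withr::with_seed(config$seed, {
    purrr::pmap_dfr(config$strata, function(...) {
      stratum <- list(...)
      rate0 <- stratum$baseline_rate %||% config$baseline_rate
      trend <- stratum$trend %||% config$trend
      pop <- population %>%
        dplyr::filter(.data$region == stratum$region,
                      .data$age_group == stratum$age_group,
                      .data$sex == stratum$sex) %>%
        dplyr::select("year", "population")
      pop_m <- interpolate_population_monthly(pop)
      mu <- pop_m$population[match(
        paste(grid$year, grid$month),
        paste(pop_m$year, pop_m$month))] *
        rate0 * exp(trend * (grid$year - y0)) *
        seasonal_factor(config, grid$year, grid$month)
      if (config$month_length_effect) {
        mu <- mu * days_in_month(grid$year, grid$month) / 31
      }
      tibble::tibble(
        year = grid$year, month = grid$month,
        region = stratum$region, age_group = stratum$age_group,
        sex = stratum$sex, cause = stratum$cause %||% "all_cause",
        count = rpois(length(mu), mu))
    })
  })
}

#' Configure the synthetic gridded temperature field
#'
#' @param grid Tibble of grid cells: `cell` id, `region` it belongs to, and
#'   non-negative population `weight`; every region needs at least one cell
#'   with positive weight.
#' @param regions Tibble of per-region climate parameters: `region`,
#'   `mean_c` (annual mean, degrees C), `range_c` (annual range), `peak_month`
#'   (warmest month), `noise_sd` (per-sample Gaussian noise, degrees C).
#' @param samples_per_day Sub-daily sampling frequency (default 4, i.e.
#'   00/06/12/18 UTC).
#' @param seed Integer seed.
#' @return A `temp_field_config` object.
#' @export
temp_field_config <- function(grid, regions, samples_per_day = 4L, seed = 1L) {
  stopifnot(all(c("cell", "region", "weight") %in% names(grid)),
            all(c("region", "mean_c", "range_c", "peak_month",
                  "noise_sd") %in% names(regions)))
  if (any(grid$weight < 0)) abort("cell weights must be >= 0")
  total <- tapply(grid$weight, grid$region, sum)
  if (any(total <= 0)) {
    abort("every region needs at least one cell with positive weight")
  }
  if (!all(grid$region %in% regions$region)) {
    abort("every grid cell must belong to a parameterised region")
  }
  structure(list(grid = tibble::as_tibble(grid),
                 regions = tibble::as_tibble(regions),
                 samples_per_day = as.integer(samples_per_day),
                 seed = as.integer(seed)),
            class = "temp_field_config")
}

#' Simulate a gridded sub-daily temperature field
#'
#' Each cell follows its region's annual cosine cycle,
#' `mean + range/2 * cos(2 pi (m - peak) / 12)`, plus independent Gaussian
#' noise per sub-daily sample. Deterministic under the config seed.
#'
#' @param config A [temp_field_config()].
#' @param years Integer vector of calendar years to simulate.
#' @return A tibble (`cell`, `region`, `timestamp`, `year`, `month`,
#'   `temp_c`) with `samples_per_day` rows per cell-day.
#' @export
simulate_temperature <- function(config, years) {
  stopifnot(inherits(config, "temp_field_config"), length(years) >= 1)
  days <- seq(lubridate::make_date(min(years), 1, 1),
              lubridate::make_date(max(years), 12, 31), by = "day")
  days <- days[lubridate::year(days) %in% years]
  hours <- seq(0, 24 - 24 / config$samples_per_day,
               by = 24 / config$samples_per_day)
  stamps <- rep(as.POSIXct(days, tz = "UTC"), each = length(hours)) +
    rep(hours, times = length(days)) * 3600
  base <- tibble::tibble(timestamp = stamps,
                         year = lubridate::year(stamps),
                         month = lubridate::month(stamps))
  withr::with_seed(config$seed, {
    purrr::pmap_dfr(config$grid, function(cell, region, weight) {
      pars <- config$regions[config$regions$region == region, ]
      clim <- pars$mean_c + pars$range_c / 2 *
        cos(2 * pi * (base$month - pars$peak_month) / 12)
      dplyr::mutate(base, cell = cell, region = region,
                    temp_c = clim + rnorm(nrow(base), 0, pars$noise_sd),
                    .before = 1)
    })
  })
}
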