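make_rates <- function(rate_by_month, years = 2000, count_scale = 1) {
  tidyr::expand_grid(year = years, month = 1:12) %>%
    dplyr::mutate(rate = rep(rate_by_month, length(years)),
                  count = rate * count_scale)
}

test_that("yearly percent difference uses empirical max/min months", {
  rates <- make_rates(c(120, rep(100, 5), 80, rep(100, 5)))
  out <- suppressMessages(yearly_percent_difference(rates))
  expect_equal(out$max_month, 1)
  expect_equal(out$min_month, 7)
  expect_equal(out$percent_diff, 50)

  const <- suppressMessages(yearly_percent_difference(make_rates(rep(7, 12))))
  expect_equal(const$percent_diff, 0)
  expect_equal(const$max_month, 1)  # ties break to the earliest month
  expect_equal(const$min_month, 1)

  tied <- suppressMessages(yearly_percent_difference(
    make_rates(c(120, 120, rep(100, 9), 80))))
  expect_equal(tied$max_month, 1)
  expect_equal(tied$percent_diff, 50)

  # invariant to rescaling all of a year's rates
  doubled <- make_rates(2 * c(120, rep(100, 5), 80, rep(100, 5)))
  expect_equal(
    suppressMessages(yearly_percent_difference(doubled))$percent_diff, 50)

  zero_min <- suppressMessages(yearly_percent_difference(
    make_rates(c(rep(10, 11), 0))))
  expect_true(is.na(zero_min$percent_diff))
  expect_false(zero_min$usable)
})

test_that("the delta-method Poisson SE matches a parametric bootstrap", {
  expect_equal(poisson_se(2, 1, 200, 100), 200 * sqrt(0.015))
  # quadrupling both counts (and populations) halves the SE
  expect_equal(poisson_se(2, 1, 800, 400), poisson_se(2, 1, 200, 100) / 2)
  expect_equal(poisson_se(2, 1, 200, 0), Inf)

  # oracle: simulate independent Poisson pairs and take the SD of the
  # percent difference directly
  sims <- withr::with_seed(10, {
    dmax <- rpois(20000, 200)
    dmin <- rpois(20000, 100)
    100 * (dmax - dmin) / dmin
  })
  expect_equal(sd(sims), poisson_se(2, 1, 200, 100), tolerance = 0.05)
})

test_that("weighted trend is exact on collinear input and matches lm", {
  years <- 1980:2016
  diffs <- tibble::tibble(year = years,
                          percent_diff = 60 - 0.5 * (years - 1980),
                          se = 2, usable = TRUE)
  fit <- fit_weighted_trend(diffs)
  expect_equal(fit$slope, -0.5)
  expect_equal(fit$change, -0.5 * 36)
  expect_equal(fit$fitted_start, 60)
  expect_equal(fit$fitted_end, 42)

  # with unequal weights the point estimate agrees with stats::lm
  diffs2 <- dplyr::mutate(diffs,
                          percent_diff = percent_diff +
                            withr::with_seed(1, rnorm(37, 0, 3)),
                          se = withr::with_seed(2, stats::runif(37, 1, 4)))
  fit2 <- fit_weighted_trend(diffs2)
  ref <- lm(percent_diff ~ year, data = diffs2, weights = 1 / se^2)
  expect_equal(fit2$slope, unname(coef(ref)[2]))
  expect_equal(fit2$intercept, unname(coef(ref)[1]))

  expect_error(fit_weighted_trend(diffs[1:2, ]), "three usable")
})

test_that("tidy/glance/autoplot expose the fit", {
  diffs <- tibble::tibble(year = 2000:2010,
                          percent_diff = 30 + withr::with_seed(3, rnorm(11)),
                          se = 1.5, usable = TRUE)
  fit <- fit_weighted_trend(diffs)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "year"))
  g <- glance(fit)
  expect_equal(g$change, fit$slope * 10)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("trend recovery: a planted linear 25-point decline is estimated", {
  # percent difference declining linearly 50% -> 25% over 37 years
  target_diff <- seq(50, 25, length.out = 37)
  amp <- (target_diff / 100) / (2 + target_diff / 100)
  cfg <- recovery_config(phase = 1, amplitude = amp[1], seed = 21,
                         amplitude_by_year = amp)
  rates <- simulated_rates(cfg)
  diffs <- suppressMessages(yearly_percent_difference(rates))
  fit <- fit_weighted_trend(diffs)
  se_change <- fit$slope_se * 36
  expect_lt(abs(fit$change - (-25)), 3 * se_change)
  expect_lt(fit$p_value, 0.01)
})

test_that("slope inference is calibrated when peak/trough months are stable", {
  # strong amplitude and large counts: the empirical max/min months are
  # effectively fixed, so the delta-method SE's assumption holds and the
  # type-I error of the slope test should be nominal
  f <- function(seed) {
    cfg <- mortseason:::reference_simulation(amplitude = 0.35, seed = seed,
                                             population = 4e7)
    d <- suppressMessages(
      yearly_percent_difference(mortseason:::reference_rates(cfg)))
    fit_weighted_trend(d)$p_value
  }
  seeds <- withr::with_seed(5, sample.int(2^31 - 2, 300))
  p <- vapply(seeds, f, numeric(1))
  band <- 3 * sqrt(0.05 * 0.95 / 300)
  expect_lt(abs(mean(p <= 0.05) - 0.05), band)
})

test_that("temperature gap between mortality peak and trough months", {
  clim <- tibble::tibble(region = "R", month = 1:12,
                         temp_c = 12.5 + 12.5 * cos(2 * pi * (1:12 - 7) / 12))
  expect_equal(peak_minus_trough_temperature(clim, 1, 7, "R"), -25)
  expect_equal(peak_minus_trough_temperature(clim, 4, 4, "R"), 0)
  expect_error(peak_minus_trough_temperature(clim, 1, 7, "S"), "region")
})
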