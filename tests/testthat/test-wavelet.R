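test_that("detrending removes polynomial trends and rescales to [-1, 1]", {
  n <- 120
  line <- tibble::tibble(year = 2000, month = 1, rate = 2 + 0.5 * seq_len(n))
  pre <- detrend_rescale(line, degree = 1)
  expect_equal(pre$values, rep(0, n))

  t_idx <- seq_len(n)
  sine <- sin(2 * pi * t_idx / 12)
  x <- 10 + 0.1 * t_idx + sine
  pre2 <- detrend_rescale(x, degree = 1)
  expect_equal(range(pre2$values), c(-1, 1))
  # residuals should essentially be the sine, rescaled
  expect_gt(cor(pre2$values, sine), 0.99)

  expect_error(detrend_rescale(1:4, degree = 4), "too short")
  expect_error(detrend_rescale(c(1, NA, 3, 4, 5, 6, 7), degree = 1),
               "non-finite")
})

test_that("wavelet power peaks at the driving period", {
  t_idx <- seq_len(444)
  grid <- default_period_grid()
  mid <- 150:300  # well inside the cone of influence everywhere

  for (p0 in c(12, 6)) {
    x <- cos(2 * pi * t_idx / p0)
    res <- morlet_cwt(x, periods = grid)
    peak_period <- grid[apply(res$power[mid, ], 1, which.max)]
    nearest <- grid[which.min(abs(grid - p0))]
    expect_true(all(peak_period == nearest))
  }

  # specificity: a 6-month-only signal leaves little power at 12 months
  x6 <- cos(2 * pi * t_idx / 6)
  res6 <- morlet_cwt(x6, periods = grid)
  j12 <- which.min(abs(grid - 12))
  j6 <- which.min(abs(grid - 6))
  expect_lt(mean(res6$power[mid, j12]), 0.1 * mean(res6$power[mid, j6]))

  expect_equal(morlet_cwt(rep(0, 100), periods = c(6, 12))$power,
               matrix(0, 100, 2))
  expect_error(morlet_cwt(rnorm(50), periods = c(12, 60)), "period grid")
})

test_that("power is non-negative and the cone of influence widens mid-series", {
  res <- morlet_cwt(rnorm(200), periods = default_period_grid())
  expect_true(all(res$power >= 0))
  expect_equal(which.max(res$coi) %in% c(100, 101), TRUE)
  expect_true(res$coi[1] < res$coi[50])
  expect_true(res$coi[200] < res$coi[150])
})

test_that("a strong 12-month signal attains the minimum p-value", {
  t_idx <- seq_len(444)
  x <- withr::with_seed(1,
    cos(2 * pi * (t_idx - 1) / 12) + rnorm(444, 0, 0.05))
  cwt <- morlet_cwt(detrend_rescale(x, degree = 4, col = NULL))
  p <- seasonality_pvalue(cwt, n_sims = 100, seed = 2)
  expect_equal(p, 1 / 101)
  # reproducible under the seed
  expect_identical(p, seasonality_pvalue(cwt, n_sims = 100, seed = 2))
  expect_error(seasonality_pvalue(cwt, n_sims = 0), "n_sims")
})

test_that("the p-value is insensitive to the detrending degree on strong signal", {
  t_idx <- seq_len(444)
  x <- withr::with_seed(3,
    5 + 0.01 * t_idx + cos(2 * pi * t_idx / 12) + rnorm(444, 0, 0.05))
  for (deg in 1:6) {
    cwt <- morlet_cwt(detrend_rescale(x, degree = deg, col = NULL))
    expect_equal(seasonality_pvalue(cwt, n_sims = 50, seed = 4), 1 / 51)
  }
})

test_that("a 6-month-only signal is not significant at the 12-month band", {
  t_idx <- seq_len(444)
  x <- withr::with_seed(5,
    cos(2 * pi * t_idx / 6) + rnorm(444, 0, 0.05))
  cwt <- morlet_cwt(detrend_rescale(x, degree = 4, col = NULL))
  expect_gt(seasonality_pvalue(cwt, n_sims = 100, seed = 6), 0.05)
})

test_that("the AR(1) red-noise null is sterner but still detects clean signal", {
  t_idx <- seq_len(444)
  x <- withr::with_seed(1,
    cos(2 * pi * t_idx / 12) + rnorm(444, 0, 0.05))
  cwt <- morlet_cwt(detrend_rescale(x, degree = 4, col = NULL))
  p_red <- seasonality_pvalue(cwt, n_sims = 50, seed = 2, null = "red")
  expect_equal(p_red, 1 / 51)

  z <- withr::with_seed(3, rnorm(444))
  cwtz <- morlet_cwt(detrend_rescale(z, degree = 4, col = NULL))
  p <- seasonality_pvalue(cwtz, n_sims = 50, seed = 2, null = "red")
  expect_gt(p, 0.05)
  expect_identical(p,
                   seasonality_pvalue(cwtz, n_sims = 50, seed = 2,
                                      null = "red"))
})

test_that("the p-value profile tracks seasonality that fades over time", {
  cfg <- simulation_config(
    years = 1980:2016,
    seasonal = tibble::tibble(period = 12, amplitude = 0.3, phase = 1,
                              halflife = 8),
    baseline_rate = 5e-4, population_start = 1e6, population_growth = 0,
    seed = 4)
  rates <- simulated_rates(cfg)
  cw <- test_seasonality(rates, n_sims = 100, seed = 5)
  expect_equal(cw$p12, 1 / 101)  # overall still clearly seasonal

  pr <- seasonality_profile(cw, n_sims = 100, seed = 5)
  expect_true(all(pr$p > 0 & pr$p <= 1))
  n <- nrow(pr)
  early <- median(pr$p[seq_len(n %/% 3)])
  late <- median(pr$p[(2 * n %/% 3):n])
  expect_lt(early, 0.05)
  expect_gt(late, early)
})

test_that("tidy and glance expose the spectrum and the headline p-value", {
  rates <- cosine_series(1990:1999)
  cwt <- test_seasonality(rates, n_sims = 20, seed = 1,
                          periods = default_period_grid()[1:40])
  td <- tidy(cwt)
  expect_setequal(names(td),
                  c("t", "period", "power", "in_coi", "year", "month"))
  expect_equal(nrow(td), cwt$n * length(cwt$period))
  g <- glance(cwt)
  expect_equal(g$p12, cwt$p12)
  expect_s3_class(autoplot(cwt), "ggplot")
})
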