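test_that("month/angle conversion places twelve points on the circle", {
  expect_equal(month_to_angle(1), 0)
  expect_equal(month_to_angle(7), pi)
  expect_equal(angle_to_month(month_to_angle(12)), 12)
  expect_equal(month_to_angle(12), 11 * pi / 6)
  expect_error(month_to_angle(0), "month")
  expect_error(month_to_angle(12.5), "month")
})

test_that("weighted circular mean matches the complex-sum definition", {
  expect_equal(weighted_circular_mean(1, 1)$month, 1)
  expect_equal(weighted_circular_mean(1, 1)$r_bar, 1)
  # December and February average to January across the wrap-around
  expect_equal(weighted_circular_mean(c(12, 2))$month, 1)
  # direct evaluation of arg(2 e^{i0} + 1 e^{i pi/6})
  expected <- 1 + 12 * Arg(2 + exp(1i * pi / 6)) / (2 * pi)
  expect_equal(weighted_circular_mean(1:2, c(2, 1))$month, expected)
  expect_equal(round(expected, 2), 1.33)

  uniform <- weighted_circular_mean(1:12, rep(1, 12))
  expect_false(uniform$defined)
  expect_true(is.na(uniform$month))

  expect_error(weighted_circular_mean(1:3, c(-1, 1, 1)), "non-negative")
  expect_error(weighted_circular_mean(1:3, rep(0, 3)), "positive")
})

test_that("circular mean agrees with a brute-force oracle and is equivariant", {
  oracle <- function(months, weights) {
    z <- 0 + 0i
    for (j in seq_along(months)) {
      z <- z + weights[j] * exp(1i * 2 * pi * (months[j] - 1) / 12)
    }
    (Arg(z) %% (2 * pi))
  }
  withr::with_seed(99, {
    for (rep in 1:25) {
      m <- sample(1:12, sample(3:12, 1), replace = TRUE)
      w <- stats::runif(length(m), 0.1, 5)
      got <- weighted_circular_mean(m, w)
      expect_equal(got$theta_bar, oracle(m, w), tolerance = 1e-12)

      # rotation equivariance: shifting months by k shifts the mean by k
      k <- sample(1:11, 1)
      shifted <- weighted_circular_mean(((m - 1 + k) %% 12) + 1, w)
      expect_equal(shifted$month,
                   ((got$month - 1 + k) %% 12) + 1, tolerance = 1e-9)

      # scale invariance of direction and concentration
      scaled <- weighted_circular_mean(m, w * 7.3)
      expect_equal(scaled$theta_bar, got$theta_bar)
      expect_equal(scaled$r_bar, got$r_bar)
    }
  })
})

test_that("centre of gravity finds the planted peak month", {
  series <- cosine_series(1990:1999, amplitude = 0.3, phase = 1)
  cog <- centre_of_gravity(series)
  dev <- ((cog$month - 1 + 6) %% 12) - 6
  expect_lt(abs(dev), 0.5)

  june_only <- tibble::tibble(year = rep(2000:2001, each = 12),
                              month = rep(1:12, 2),
                              rate = rep(ifelse(1:12 == 6, 5, 0), 2))
  expect_equal(centre_of_gravity(june_only)$month, 6)

  flat <- tibble::tibble(year = 2000, month = 1:12, rate = 3)
  expect_false(centre_of_gravity(flat)$defined)
})

test_that("negative centre of gravity finds the trough month", {
  one_dip <- tibble::tibble(year = 2000, month = 1:12,
                            rate = ifelse(1:12 == 7, 2, 10))
  expect_equal(negative_centre_of_gravity(one_dip)$month, 7)

  series <- cosine_series(1990:1999, amplitude = 0.3, phase = 1)
  ncog <- negative_centre_of_gravity(series)
  dev <- ((ncog$month - 7 + 6) %% 12) - 6
  expect_lt(abs(dev), 0.5)

  flat <- tibble::tibble(year = rep(2000:2001, each = 12),
                         month = rep(1:12, 2), rate = 3)
  expect_false(negative_centre_of_gravity(flat)$defined)
})

test_that("pooled and per-year-averaged centres of gravity agree on cosine data", {
  series <- cosine_series(1990:2009, amplitude = 0.25, phase = 2)
  noisy <- dplyr::mutate(series,
                         rate = withr::with_seed(7,
                                                 rate + rnorm(nrow(series), 0, 3)))
  pooled <- centre_of_gravity(noisy)
  averaged <- centre_of_gravity(noisy, per_year = TRUE)
  dev <- ((pooled$month - averaged$month + 6) %% 12) - 6
  expect_lt(abs(dev), 0.5)
  # count weighting is available as a sensitivity flag
  with_counts <- centre_of_gravity(dplyr::rename(noisy, count = rate),
                                   col = "count")
  expect_equal(with_counts$month, pooled$month)
})

test_that("maximum and minimum timing are antipodal on pure cosine input", {
  series <- cosine_series(1985:1999, amplitude = 0.4, phase = 4)
  cog <- centre_of_gravity(series)
  ncog <- negative_centre_of_gravity(series)
  gap <- ((ncog$month - cog$month) %% 12)
  expect_equal(gap, 6, tolerance = 1e-8)
})

test_that("year-block bootstrap builds sensible circular intervals", {
  june_only <- tibble::tibble(year = rep(2000:2009, each = 12),
                              month = rep(1:12, 10),
                              rate = rep(ifelse(1:12 == 6, 5, 0), 10))
  ci <- bootstrap_ci(june_only, "cog", n = 200, seed = 1)
  expect_equal(ci$lo, 6)
  expect_equal(ci$hi, 6)
  expect_equal(ci$half_width_months, 0)

  series <- cosine_series(1990:2009, amplitude = 0.2, phase = 11)
  noisy <- dplyr::mutate(series,
                         rate = withr::with_seed(2, rate + rnorm(nrow(series), 0, 5)))
  ci2 <- bootstrap_ci(noisy, "cog", n = 500, seed = 3)
  expect_true(ci_covers_month(ci2, ci2$estimate))
  expect_identical(ci2, bootstrap_ci(noisy, "cog", n = 500, seed = 3))

  flat <- tibble::tibble(year = rep(2000:2004, each = 12),
                         month = rep(1:12, 5), rate = 1)
  expect_error(bootstrap_ci(flat, "cog", n = 50, seed = 1), "undefined")
})

test_that("seasonal_timing summarises both timings with their CIs", {
  series <- cosine_series(1990:2009, amplitude = 0.3, phase = 1)
  row <- seasonal_timing(series, n_boot = 100, seed = 4)
  expect_equal(row$max_month_nearest, 1)
  expect_equal(row$min_month_nearest, 7)
  expect_lt(row$max_circular_variance, 1)
  expect_equal(row$n_bootstrap, 100)
})
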