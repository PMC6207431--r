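#' Detrend and rescale a monthly series for spectral analysis
#'
#' Removes a least-squares polynomial trend in the time index and then maps
#' the residuals affinely onto \[-1, 1\] (minimum to -1, maximum to +1).
#' Detrending stops the secular decline in death rates from leaking power
#' into long periods; the rescale puts strata with very different absolute
#' rates on a common amplitude scale. A degenerate residual range (constant
#' residuals) yields an all-zero series.
#'
#' @param series Tibble with the value column (and optionally `year`,
#'   `month`, carried through), or a bare numeric vector.
#' @param degree Polynomial degree (default 4).
#' @param col Value column name (default `"rate"`).
#' @return A `preprocessed_series` object: the rescaled `values` plus the
#'   fitted trend coefficients and the affine scale parameters.
#' @export
detrend_rescale <- function(series, degree = 4, col = "rate") {
  if (is.data.frame(series)) {
    x <- series[[col]]
    yr <- series[["year"]]
    mo <- series[["month"]]
  } else {
    x <- as.numeric(series)
    yr <- mo <- NULL
  }
  n <- length(x)
  if (!all(is.finite(x))) abort("series contains non-finite values")
  if (n <= degree + 1) abort("series too short for the requested degree")

  t_idx <- seq_len(n)
  fit <- lm(x ~ stats::poly(t_idx, degree, raw = FALSE))
  r <- stats::residuals(fit)
  rng <- range(r)
  half <- (rng[2] - rng[1]) / 2
  mid <- (rng[2] + rng[1]) / 2
  values <- if (half < 1e-12 * max(1, abs(mid))) {
    rep(0, n)
  } else {
    (r - mid) / half
  }
  structure(list(values = values, year = yr, month = mo, degree = degree,
                 trend_coefficients = coef(fit),
                 scale_offset = mid, scale_factor = half),
            class = "preprocessed_series")
}

#' Default wavelet period grid
#'
#' Dyadic periods from 2 to ~72 months with 12 sub-octaves per octave,
#' spanning the 6- and 12-month bands with fine resolution.
#'
#' @return Numeric vector of periods in months.
#' @export
default_period_grid <- function() {
  2 * 2^(seq(0L, floor(12 * log2(36)), by = 1L) / 12)
}

morlet_fourier_factor <- function(omega0) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

# Wavelet power at the given scales via FFT (unit time step, zero padding
# to the next power of two). Returns an n x length(scales) matrix.
morlet_power_matrix <- function(x, scales, omega0 = 6) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xhat <- fft(c(x, rep(0, npad - n)))
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / npad
  pos <- omega > 0
  norm <- pi^(-1 / 4) * sqrt(2 * pi * scales)
  arg <- outer(omega, scales)          # npad x S
  daughter <- matrix(0, npad, length(scales))
  daughter[pos, ] <- exp(-(arg[pos, , drop = FALSE] - omega0)^2 / 2)
  daughter <- sweep(daughter, 2, norm, `*`)
  w <- stats::mvfft(daughter * xhat, inverse = TRUE) / npad
  Mod(w[seq_len(n), , drop = FALSE])^2
}

#' Morlet continuous wavelet transform
#'
#' Computes the wavelet power spectrum of a (preprocessed) monthly series
#' with a Morlet mother wavelet of central frequency `omega0 = 6` — the
#' convention under which scale and Fourier period nearly coincide — using
#' the FFT with zero padding to the next power of two. The cone of influence
#' records, for each time point, the largest period whose e-folding distance
#' (sqrt(2) times the scale) fits inside the series; power outside it is
#' contaminated by edge effects.
#'
#' @param series A [detrend_rescale()] result, a tibble with a value column,
#'   or a numeric vector. Data frames / vectors are transformed as-is
#'   (no detrending).
#' @param periods Period grid in months, strictly inside (2, length).
#' @param omega0 Morlet central frequency (default 6).
#' @param col Value column when `series` is a data frame.
#' @return A `morlet_cwt` object: `power` (time x period matrix), `period`,
#'   `coi` (per-time maximum trustworthy period), `in_coi` (logical matrix),
#'   `year`/`month` if known, and an unset 12-month p-value slot (`p12`);
#'   see [seasonality_pvalue()].
#' @export
morlet_cwt <- function(series, periods = default_period_grid(), omega0 = 6,
                       col = "rate") {
  degree <- NULL
  yr <- mo <- NULL
  if (inherits(series, "preprocessed_series")) {
    x <- series$values
    degree <- series$degree
    yr <- series$year
    mo <- series$month
  } else if (is.data.frame(series)) {
    x <- series[[col]]
    yr <- series[["year"]]
    mo <- series[["month"]]
  } else {
    x <- as.numeric(series)
  }
  n <- length(x)
  if (!all(is.finite(x))) abort("series contains non-finite values")
  if (any(periods < 2) || any(periods >= n)) {
    abort("period grid must lie within [2, series length) months")
  }
  ff <- morlet_fourier_factor(omega0)
  power <- morlet_power_matrix(x, periods / ff, omega0)

  d <- pmin(seq_len(n) - 1, n - seq_len(n))
  coi <- ff / sqrt(2) * pmax(d, 1e-8)
  in_coi <- outer(coi, periods, `>=`)

  structure(list(power = power, period = periods, coi = coi, in_coi = in_coi,
                 n = n, omega0 = omega0, values = x, degree = degree,
                 year = yr, month = mo, p12 = NA_real_, n_sims = NA_integer_),
            class = "morlet_cwt")
}

# statistic for the seasonality test: time-averaged power at the grid
# period nearest `target`, restricted to in-coi times
band_statistic <- function(power, mask) {
  mean(power[mask])
}

# n x n_sims matrix of null power series at one scale: noise of the
# series' length run through the identical preprocessing and transform.
# White noise is iid Gaussian; red noise is AR(1) with the lag-1
# autocorrelation estimated from the analysed series.
null_band_power <- function(result, scale, n_sims, null = "white") {
  n <- result$n
  degree <- result$degree
  qr_x <- if (!is.null(degree)) {
    qr(cbind(1, stats::poly(seq_len(n), degree, raw = FALSE)))
  }
  phi <- 0
  if (null == "red") {
    if (sd(result$values) > 0) {
      phi <- stats::acf(result$values, lag.max = 1, plot = FALSE)$acf[2]
      phi <- min(max(phi, 0), 0.99)
    }
  }
  vapply(seq_len(n_sims), function(i) {
    z <- rnorm(n)
    if (phi > 0) z <- as.numeric(stats::filter(z, phi, method = "recursive"))
    if (!is.null(qr_x)) {
      r <- qr.resid(qr_x, z)
      rng <- range(r)
      half <- (rng[2] - rng[1]) / 2
      z <- if (half < 1e-12) rep(0, n) else (r - mean(rng)) / half
    }
    morlet_power_matrix(z, scale, result$omega0)[, 1]
  }, numeric(n))
}

#' Simulation-based p-value for 12-month seasonality
#'
#' Tests for the presence of seasonality at `target_period` over the whole
#' series: the observed statistic is the time-averaged wavelet power at the
#' grid period nearest the target, over the times where that period lies
#' inside the cone of influence. Its null distribution comes from Gaussian
#' white-noise series of the same length run through the identical
#' preprocessing (same polynomial degree, if the input had been detrended)
#' and the identical transform. The p-value uses the plus-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_sims)`, so the smallest
#' attainable value with 100 simulations is 1/101.
#'
#' @param result A [morlet_cwt()] object.
#' @param target_period Target period in months (default 12).
#' @param n_sims Number of noise simulations (default 100).
#' @param seed Optional integer seed for reproducibility.
#' @param null `"white"` (default, independent Gaussian noise) or `"red"`
#'   (AR(1) noise with the lag-1 autocorrelation estimated from the
#'   analysed series — a sterner null for serially correlated data).
#' @return The p-value (scalar in (0, 1\]).
#' @export
seasonality_pvalue <- function(result, target_period = 12, n_sims = 100,
                               seed = NULL, null = c("white", "red")) {
  null <- match.arg(null)
  stopifnot(inherits(result, "morlet_cwt"))
  if (n_sims < 1) abort("n_sims must be at least 1")
  j <- which.min(abs(result$period - target_period))
  mask <- result$in_coi[, j]
  if (!any(mask)) {
    abort("no time points inside the cone of influence at the target period")
  }
  observed <- band_statistic(result$power[, j], mask)
  scale <- result$period[j] / morlet_fourier_factor(result$omega0)

  run <- function() null_band_power(result, scale, n_sims, null)
  null_power <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  null_stats <- colMeans(null_power[mask, , drop = FALSE])

  (1 + sum(null_stats >= observed)) / (1 + n_sims)
}

#' Per-time diagnostic p-values at the target period
#'
#' A time-resolved companion to [seasonality_pvalue()]: at every time point
#' inside the cone of influence, the pointwise wavelet power at the target
#' period is compared against the same noise null, showing when during the
#' series the periodicity holds up and when it fades. These are diagnostics
#' — the headline test remains the time-averaged statistic of
#' [seasonality_pvalue()].
#'
#' @inheritParams seasonality_pvalue
#' @return A tibble with one row per in-coi time point: `t`, `year`/`month`
#'   when known, `power`, `p`.
#' @export
seasonality_profile <- function(result, target_period = 12, n_sims = 100,
                                seed = NULL, null = c("white", "red")) {
  null <- match.arg(null)
  stopifnot(inherits(result, "morlet_cwt"))
  if (n_sims < 1) abort("n_sims must be at least 1")
  j <- which.min(abs(result$period - target_period))
  mask <- result$in_coi[, j]
  if (!any(mask)) {
    abort("no time points inside the cone of influence at the target period")
  }
  scale <- result$period[j] / morlet_fourier_factor(result$omega0)
  run <- function() null_band_power(result, scale, n_sims, null)
  null_power <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  obs <- result$power[mask, j]
  exceed <- rowSums(null_power[mask, , drop = FALSE] >= obs)
  out <- tibble::tibble(t = which(mask), power = obs,
                        p = (1 + exceed) / (1 + n_sims))
  if (!is.null(result$year)) {
    out$year <- result$year[out$t]
    out$month <- result$month[out$t]
  }
  out
}

#' One-call seasonality test for a monthly rate series
#'
#' Convenience wrapper: [detrend_rescale()], [morlet_cwt()] and
#' [seasonality_pvalue()] in sequence, returning the transform with its
#' `p12` slot filled in.
#'
#' @inheritParams detrend_rescale
#' @inheritParams morlet_cwt
#' @inheritParams seasonality_pvalue
#' @return A `morlet_cwt` object with `p12` and `n_sims` set.
#' @export
#' @examples
#' cfg <- simulation_config(years = 1980:2016, seed = 7)
#' rates <- simulate_deaths(cfg) |>
#'   aggregate_series() |>
#'   month_length_correct() |>
#'   compute_death_rates(interpolate_population_monthly(
#'     simulate_population(cfg)))
#' cwt <- test_seasonality(rates, n_sims = 20, seed = 1)
#' glance(cwt)
test_seasonality <- function(series, degree = 4, col = "rate",
                             periods = default_period_grid(),
                             target_period = 12, n_sims = 100, seed = NULL) {
  pre <- detrend_rescale(series, degree = degree, col = col)
  res <- morlet_cwt(pre, periods = periods)
  res$p12 <- seasonality_pvalue(res, target_period = target_period,
                                n_sims = n_sims, seed = seed)
  res$n_sims <- as.integer(n_sims)
  res
}

#' @export
print.morlet_cwt <- function(x, ...) {
  cat("Morlet wavelet power spectrum\n")
  cat("  series length:", x$n, "months;", length(x$period),
      "periods in [", round(min(x$period), 2), ",",
      round(max(x$period), 2), "] months\n")
  if (!is.na(x$p12)) {
    cat("  12-month seasonality p-value:", format(x$p12, digits = 3),
        "(", x$n_sims, "white-noise simulations )\n")
  }
  invisible(x)
}

#' @rdname tidy.morlet_cwt
#' @method glance morlet_cwt
#' @export
glance.morlet_cwt <- function(x, ...) {
  tibble::tibble(n = x$n, n_periods = length(x$period),
                 p12 = x$p12, n_sims = x$n_sims)
}

#' Tidy a wavelet power spectrum
#'
#' `tidy()` returns the time-by-period power matrix in long form; `glance()`
#' a one-row summary with the 12-month seasonality p-value (if computed).
#'
#' @param x A `morlet_cwt` object.
#' @param ... Unused.
#' @return A tibble with columns `t` (month index from series start),
#'   `year`/`month` when known, `period`, `power` and `in_coi`.
#' @method tidy morlet_cwt
#' @export
tidy.morlet_cwt <- function(x, ...) {
  n <- x$n
  out <- tibble::tibble(
    t = rep(seq_len(n), times = length(x$period)),
    period = rep(x$period, each = n),
    power = as.vector(x$power),
    in_coi = as.vector(x$in_coi)
  )
  if (!is.null(x$year)) {
    out$year <- rep(x$year, times = length(x$period))
    out$month <- rep(x$month, times = length(x$period))
  }
  out
}

#' Plot a wavelet power spectrum
#'
#' Heat map of power over time and period (log2 axis), with the cone of
#' influence drawn as a line; the area above it is edge-affected.
#'
#' @param object A `morlet_cwt` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot morlet_cwt
#' @export
autoplot.morlet_cwt <- function(object, ...) {
  td <- tidy(object)
  coi <- tibble::tibble(t = seq_len(object$n), coi = object$coi)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$t, y = .data$period)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$power)) +
    ggplot2::geom_line(data = coi, ggplot2::aes(y = .data$coi),
                       colour = "white", linetype = 2) +
    ggplot2::scale_y_continuous(trans = "log2",
                                breaks = c(3, 6, 12, 24, 48)) +
    ggplot2::scale_fill_viridis_c(option = "turbo") +
    ggplot2::coord_cartesian(ylim = range(object$period)) +
    ggplot2::labs(x = "month index", y = "period (months)", fill = "power")
}
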