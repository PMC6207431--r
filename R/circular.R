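#' Convert between calendar months and angles on the unit circle
#'
#' Months are placed at 12 equally spaced points, January at angle 0, so
#' that December neighbours January: `theta = 2 pi (month - 1) / 12`.
#' `angle_to_month()` inverts the map, returning a continuous month value in
#' \[1, 13).
#'
#' @param month Numeric vector of months in \[1, 12\] (may be fractional).
#' @param theta Numeric vector of angles in radians.
#' @return Radians, resp. continuous months.
#' @export
#' @examples
#' month_to_angle(c(1, 7))        # 0, pi
#' angle_to_month(11 * pi / 6)    # 12
month_to_angle <- function(month) {
  if (any(month < 1 | month > 12)) abort("month must lie in [1, 12]")
  2 * pi * (month - 1) / months_in_year
}

#' @rdname month_to_angle
#' @export
angle_to_month <- function(theta) {
  wrap_month(1 + months_in_year * theta / (2 * pi))
}

circular_mean_row <- function(z, sum_w, n_obs) {
  r_bar <- if (sum_w > 0) Mod(z) / sum_w else 0
  if (sum_w <= 0 || r_bar < 1e-10) {
    return(tibble::tibble(theta_bar = NA_real_, month = NA_real_,
                          r_bar = NA_real_, circular_variance = NA_real_,
                          defined = FALSE, n = n_obs))
  }
  theta <- Arg(z) %% (2 * pi)
  tibble::tibble(theta_bar = theta, month = angle_to_month(theta),
                 r_bar = r_bar, circular_variance = 1 - r_bar,
                 defined = TRUE, n = n_obs)
}

#' Weighted circular mean of months
#'
#' The mean direction `theta_bar = arg sum_j w_j exp(i theta_j)` of the
#' month angles, with resultant length `R_bar = |sum_j w_j exp(i theta_j)| /
#' sum_j w_j` and circular variance `1 - R_bar`. A vanishing resultant
#' (e.g. perfectly uniform weights) has no mean direction: the result row is
#' flagged `defined = FALSE` with `NA` values rather than a number.
#'
#' @param months Numeric vector of months in \[1, 12\].
#' @param weights Non-negative weights, same length (default all 1).
#' @return A one-row tibble: `theta_bar`, `month` (continuous, in \[1, 13)),
#'   `r_bar`, `circular_variance`, `defined`, `n`.
#' @export
#' @examples
#' weighted_circular_mean(c(12, 2))          # December + February -> January
#' weighted_circular_mean(1:2, c(2, 1))      # ~ 1.33
weighted_circular_mean <- function(months, weights = rep(1, length(months))) {
  stopifnot(length(months) == length(weights), length(months) > 0)
  if (any(weights < 0)) abort("weights must be non-negative")
  if (all(weights == 0)) abort("at least one weight must be positive")
  theta <- month_to_angle(months)
  z <- sum(weights * exp(1i * theta))
  circular_mean_row(z, sum(weights), length(months))
}

# Per-year complex resultants for a series; negative = TRUE uses the
# within-year shortfall below the year's maximum as weight. Precomputing
# these makes the year-block bootstrap a sum over sampled years.
yearly_resultants <- function(series, col = "rate", negative = FALSE) {
  stopifnot(all(c("year", "month", col) %in% names(series)))
  v <- series[[col]]
  if (any(v < 0)) abort("series values must be non-negative")
  w <- if (negative) {
    stats::ave(v, series$year, FUN = max) - v
  } else {
    v
  }
  e <- exp(1i * month_to_angle(series$month))
  tibble::tibble(
    year = sort(unique(series$year)),
    z = as.complex(tapply(w * e, series$year, sum)),
    sum_w = as.numeric(tapply(w, series$year, sum)),
    n = as.integer(tapply(w, series$year, length))
  )
}

#' Timing of maximum mortality (centre of gravity)
#'
#' The circular mean month of death over the whole analysis window, each
#' (year, month) cell weighted by its death rate. Identifies when mortality
#' peaks within the year.
#'
#' @param series Tibble (`year`, `month`, value column).
#' @param col Weight column (default `"rate"`; pass `"count"` for raw-count
#'   weighting).
#' @param per_year If `TRUE`, compute a circular mean per calendar year and
#'   average the yearly mean directions with equal weight, instead of
#'   pooling all cells (sensitivity variant).
#' @return A one-row tibble as in [weighted_circular_mean()]; an all-zero
#'   (or per-year constant, for [negative_centre_of_gravity()]) series has
#'   no defined timing and is returned flagged `defined = FALSE`.
#' @export
centre_of_gravity <- function(series, col = "rate", per_year = FALSE) {
  res <- yearly_resultants(series, col = col, negative = FALSE)
  pooled_timing(res, per_year)
}

#' Timing of minimum mortality (negative centre of gravity)
#'
#' As [centre_of_gravity()], but each month is weighted by the difference
#' between its year's maximum death rate and its own, so the year's peak
#' month gets weight zero and the deepest trough the largest weight.
#'
#' @inheritParams centre_of_gravity
#' @export
negative_centre_of_gravity <- function(series, col = "rate",
                                       per_year = FALSE) {
  res <- yearly_resultants(series, col = col, negative = TRUE)
  pooled_timing(res, per_year)
}

pooled_timing <- function(res, per_year = FALSE) {
  if (per_year) {
    ok <- res$sum_w > 0 & Mod(res$z) / pmax(res$sum_w, 1e-300) >= 1e-10
    if (!any(ok)) return(circular_mean_row(0 + 0i, 0, sum(res$n)))
    unit <- exp(1i * Arg(res$z[ok]))
    return(circular_mean_row(sum(unit), sum(ok), sum(res$n)))
  }
  circular_mean_row(sum(res$z), sum(res$sum_w), sum(res$n))
}

#' Year-block bootstrap CI for a circular timing statistic
#'
#' Resamples calendar years with replacement (keeping months within a year
#' together, to respect within-year dependence), recomputes the timing
#' statistic for each replicate, and forms a percentile interval on the
#' shortest-arc angular deviations from the point estimate. The interval
#' endpoints are reported as months in \[1, 13); `lo` may exceed `hi`
#' numerically when the interval crosses the December-January boundary.
#'
#' @param series Tibble (`year`, `month`, value column).
#' @param statistic `"cog"` (timing of maximum) or `"negative_cog"` (timing
#'   of minimum).
#' @param n Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param conf Coverage level (default 0.95).
#' @param col Weight column.
#' @return A one-row tibble: `statistic`, `estimate` (month), `lo`, `hi`,
#'   `half_width_months`, `n_boot`, `n_undefined`.
#' @export
bootstrap_ci <- function(series, statistic = c("cog", "negative_cog"),
                         n = 1000, seed = NULL, conf = 0.95, col = "rate") {
  statistic <- match.arg(statistic)
  res <- yearly_resultants(series, col = col,
                           negative = statistic == "negative_cog")
  if (nrow(res) < 2) abort("need at least two years to bootstrap")
  point <- pooled_timing(res)
  if (!point$defined) abort("timing statistic undefined on the full series")

  run <- function() {
    vapply(seq_len(n), function(b) {
      idx <- sample.int(nrow(res), nrow(res), replace = TRUE)
      z <- sum(res$z[idx])
      sw <- sum(res$sum_w[idx])
      if (sw <= 0 || Mod(z) / sw < 1e-10) return(NA_real_)
      angle_to_month(Arg(z) %% (2 * pi))
    }, numeric(1))
  }
  boots <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  n_undef <- sum(is.na(boots))
  if (n_undef > n / 2) {
    abort(paste0("timing statistic undefined in ", n_undef, " of ", n,
                 " bootstrap replicates; series too close to uniform"))
  }
  # shortest-arc deviation from the point estimate, in (-6, 6] months
  dev <- ((boots[!is.na(boots)] - point$month + 6) %% 12) - 6
  q <- quantile(dev, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  tibble::tibble(statistic = statistic, estimate = point$month,
                 lo = wrap_month(point$month + q[1]),
                 hi = wrap_month(point$month + q[2]),
                 half_width_months = (q[2] - q[1]) / 2,
                 n_boot = as.integer(n), n_undefined = as.integer(n_undef))
}

#' Timing summary for one stratum
#'
#' Centre of gravity, negative centre of gravity, their circular variances
#' and year-block bootstrap confidence intervals, in one row — the tabular
#' analogue of a timing-arrow diagram.
#'
#' @inheritParams bootstrap_ci
#' @param n_boot Bootstrap replicates for each CI (default 1000).
#' @return A one-row tibble with `max_month`, `max_month_nearest`,
#'   `max_ci_lo`, `max_ci_hi`, `max_circular_variance`, and the same for
#'   `min_*`, plus `n_bootstrap`.
#' @export
seasonal_timing <- function(series, col = "rate", n_boot = 1000,
                            seed = NULL) {
  cog <- centre_of_gravity(series, col = col)
  ncog <- negative_centre_of_gravity(series, col = col)
  ci_max <- bootstrap_ci(series, "cog", n = n_boot, seed = seed, col = col)
  ci_min <- bootstrap_ci(series, "negative_cog", n = n_boot, seed = seed,
                         col = col)
  tibble::tibble(
    max_month = cog$month,
    max_month_nearest = nearest_calendar_month(cog$month),
    max_ci_lo = ci_max$lo, max_ci_hi = ci_max$hi,
    max_circular_variance = cog$circular_variance,
    min_month = ncog$month,
    min_month_nearest = nearest_calendar_month(ncog$month),
    min_ci_lo = ci_min$lo, min_ci_hi = ci_min$hi,
    min_circular_variance = ncog$circular_variance,
    n_bootstrap = as.integer(n_boot)
  )
}

#' Does a circular timing interval cover a month?
#'
#' Containment test for the intervals produced by [bootstrap_ci()], which
#' may cross the December-January boundary. The interval is taken as the
#' arc from `lo` to `hi` that contains the point estimate.
#'
#' @param ci A one-row tibble from [bootstrap_ci()].
#' @param month Month value (continuous, in \[1, 13)).
#' @return Logical.
#' @export
ci_covers_month <- function(ci, month) {
  arc <- function(a, b) ((a - b + 6) %% 12) - 6
  dev <- arc(month, ci$estimate)
  dev >= arc(ci$lo, ci$estimate) & dev <= arc(ci$hi, ci$estimate)
}

nearest_calendar_month <- function(m) {
  out <- as.integer(round(m))
  out[!is.na(out) & out == 13L] <- 1L
  out[is.na(m)] <- NA_integer_
  out
}
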