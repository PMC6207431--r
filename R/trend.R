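#' Poisson delta-method standard error of a percent difference
#'
#' Treats the death counts of the maximum- and minimum-mortality months as
#' independent Poisson variables; the percent difference
#' `100 (r_max - r_min) / r_min` then has approximate standard error
#' `100 (r_max / r_min) sqrt(1/d_max + 1/d_min)` (first-order delta method,
#' which carries the population denominators through the rates). Zero counts
#' give an infinite SE: the year carries no weight in the trend fit.
#'
#' @param r_max,r_min Death rates of the maximum and minimum months.
#' @param d_max,d_min The two months' (corrected) death counts.
#' @return Numeric vector of standard errors, in percentage points.
#' @export
#' @examples
#' poisson_se(2, 1, 200, 100)  # 200 * sqrt(0.015) ~ 24.49
poisson_se <- function(r_max, r_min, d_max, d_min) {
  se <- 100 * (r_max / r_min) * sqrt(1 / d_max + 1 / d_min)
  se[d_max <= 0 | d_min <= 0] <- Inf
  se
}

#' Yearly peak-versus-trough percent mortality difference
#'
#' For each calendar year, finds the empirical maximum- and minimum-rate
#' months (no month is assumed in advance; ties break to the earliest
#' month), and computes the percent difference
#' `100 (r_max - r_min) / r_min` with its Poisson delta-method SE. With
#' `denominator = "max"` the difference is expressed relative to the
#' maximum-month rate instead (sensitivity variant).
#'
#' @param rates Tibble (`year`, `month`, `rate`, `count`) of
#'   month-length-corrected rates and counts, e.g. from
#'   [compute_death_rates()].
#' @param denominator `"min"` (default) or `"max"`.
#' @return A tibble with one row per year: `year`, `max_month`, `min_month`,
#'   `r_max`, `r_min`, `d_max`, `d_min`, `percent_diff`, `se`, `usable`.
#'   Years whose minimum rate is zero have `NA` difference and are flagged
#'   unusable (excluded from the trend fit) with a message.
#' @export
yearly_percent_difference <- function(rates, denominator = c("min", "max")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("year", "month", "rate", "count") %in% names(rates)))
  out <- rates %>%
    dplyr::arrange(.data$year, .data$month) %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(
      max_month = .data$month[which.max(.data$rate)],
      min_month = .data$month[which.min(.data$rate)],
      r_max = max(.data$rate),
      r_min = min(.data$rate),
      d_max = .data$count[which.max(.data$rate)],
      d_min = .data$count[which.min(.data$rate)],
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      percent_diff = dplyr::if_else(
        .data$r_min > 0,
        100 * (.data$r_max - .data$r_min) /
          if (denominator == "min") .data$r_min else .data$r_max,
        NA_real_),
      se = dplyr::if_else(
        .data$r_min > 0,
        poisson_se(.data$r_max, .data$r_min, .data$d_max, .data$d_min) *
          if (denominator == "min") 1 else (.data$r_min / .data$r_max)^2,
        NA_real_),
      usable = is.finite(.data$percent_diff) & is.finite(.data$se) &
        .data$se > 0
    )
  n_bad <- sum(!out$usable)
  if (n_bad > 0) {
    inform(paste0(n_bad, " year(s) with zero minimum rate or zero counts ",
                  "excluded from trend weighting"))
  }
  out
}

#' Inverse-variance-weighted linear trend in the seasonal difference
#'
#' Weighted least squares of the yearly percent difference on calendar year,
#' weights `1 / se^2`. The slope's standard error uses the fixed-variance
#' (inverse-variance weighting) form `sqrt([(X'WX)^-1]_22)` and its p-value
#' the two-sided normal approximation. The fitted line is evaluated at the
#' first and last year of the window to express the change over the study
#' period.
#'
#' @param diffs Output of [yearly_percent_difference()]; unusable years are
#'   dropped.
#' @param window Optional length-2 year range at which to evaluate the
#'   fitted endpoints (default: range of years in `diffs`).
#' @return A `seasonal_trend_fit` object with components `slope` (percentage
#'   points per year), `slope_se`, `p_value`, `fitted_start`, `fitted_end`,
#'   `change` (= slope x span), `intercept`, `window`, `n_years`, `data`.
#' @export
fit_weighted_trend <- function(diffs, window = NULL) {
  stopifnot(all(c("year", "percent_diff", "se", "usable") %in% names(diffs)))
  window <- window %||% range(diffs$year)
  used <- diffs[diffs$usable, , drop = FALSE]
  if (nrow(used) < 3) abort("need at least three usable years to fit a trend")
  w <- 1 / used$se^2
  if (!any(w > 0) || !all(is.finite(w))) abort("all weights zero or undefined")

  x <- used$year
  y <- used$percent_diff
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - swx^2
  slope <- (sw * sxy - swx * swy) / det
  intercept <- (swy - slope * swx) / sw
  slope_se <- sqrt(sw / det)
  p_value <- 2 * pnorm(-abs(slope / slope_se))

  fitted_start <- intercept + slope * window[1]
  fitted_end <- intercept + slope * window[2]
  structure(
    list(slope = slope, slope_se = slope_se, p_value = p_value,
         intercept = intercept,
         fitted_start = fitted_start, fitted_end = fitted_end,
         change = fitted_end - fitted_start,
         window = window, n_years = nrow(used), data = diffs),
    class = "seasonal_trend_fit")
}

#' @export
print.seasonal_trend_fit <- function(x, ...) {
  cat("Weighted linear trend in seasonal percent difference\n")
  cat(sprintf("  slope: %.3f pp/year (SE %.3f, p = %.3g)\n",
              x$slope, x$slope_se, x$p_value))
  cat(sprintf("  fitted %d: %.1f%%  ->  fitted %d: %.1f%%  (change %+.1f pp)\n",
              x$window[1], x$fitted_start, x$window[2], x$fitted_end,
              x$change))
  invisible(x)
}

#' Tidy a fitted seasonal trend
#'
#' `tidy()` gives the regression terms; `glance()` a one-row summary with
#' the fitted endpoint change.
#'
#' @param x A `seasonal_trend_fit`.
#' @param ... Unused.
#' @method tidy seasonal_trend_fit
#' @export
tidy.seasonal_trend_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "year"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$slope_se),
    p.value = c(NA_real_, x$p_value)
  )
}

#' @rdname tidy.seasonal_trend_fit
#' @method glance seasonal_trend_fit
#' @export
glance.seasonal_trend_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, slope_se = x$slope_se,
                 p_value = x$p_value, fitted_start = x$fitted_start,
                 fitted_end = x$fitted_end, change = x$change,
                 n_years = x$n_years)
}

#' Plot yearly seasonal differences with the fitted trend
#'
#' @param object A `seasonal_trend_fit`.
#' @param ... Unused.
#' @return A ggplot object: yearly percent differences with +-1 SE bars and
#'   the weighted fitted line.
#' @method autoplot seasonal_trend_fit
#' @export
autoplot.seasonal_trend_fit <- function(object, ...) {
  d <- object$data[object$data$usable, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$percent_diff)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$percent_diff - .data$se,
                                          ymax = .data$percent_diff + .data$se),
                             linewidth = 0.3, size = 0.3) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(x = "year", y = "peak vs trough difference (%)")
}

#' Temperature gap between mortality peak and trough months
#'
#' The monthly-climatology temperature of the maximum-mortality month minus
#' that of the minimum-mortality month, for a region.
#'
#' @param climatology Tibble (`region`, `month`, `temp_c`) of long-run
#'   monthly mean temperatures, e.g. `regional_climatology()$monthly`.
#' @param max_month,min_month Calendar months (integers), e.g. the
#'   `*_month_nearest` columns of [seasonal_timing()].
#' @param region Region id to look up.
#' @return Temperature difference in degrees C (negative when the mortality
#'   peak falls in the cold season).
#' @export
peak_minus_trough_temperature <- function(climatology, max_month, min_month,
                                          region) {
  stopifnot(all(c("region", "month", "temp_c") %in% names(climatology)))
  rows <- climatology[climatology$region == region, , drop = FALSE]
  if (nrow(rows) == 0) abort(paste0("no climatology for region '", region, "'"))
  t_max <- rows$temp_c[match(max_month, rows$month)]
  t_min <- rows$temp_c[match(min_month, rows$month)]
  if (anyNA(c(t_max, t_min))) {
    abort("climatology does not cover the requested months")
  }
  t_max - t_min
}
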