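#' Days in a calendar month
#'
#' Leap-year aware, vectorised over both arguments.
#'
#' @param year,month Integer vectors.
#' @return Integer vector of month lengths.
#' @export
#' @examples
#' days_in_month(c(1981, 2016), 2)  # 28, 29
days_in_month <- function(year, month) {
  unname(lubridate::days_in_month(lubridate::make_date(year, month, 1)))
}

#' Interpolate yearly populations to months, anchored at July
#'
#' Yearly population counts are treated as the July value of their year;
#' months between two Julys are linearly interpolated, and the months before
#' the first July / after the last July are extrapolated linearly from the
#' two nearest anchors.
#'
#' @param pop Tibble with columns `year` and `population` (one stratum, at
#'   least two years).
#' @param years Months to return, as calendar years; defaults to the anchor
#'   years.
#' @return A tibble (`year`, `month`, `population`) covering every month of
#'   `years`; July values reproduce the input exactly.
#' @export
#' @examples
#' pop <- tibble::tibble(year = 1990:1991, population = c(1000, 1120))
#' interpolate_population_monthly(pop)
interpolate_population_monthly <- function(pop, years = NULL) {
  stopifnot(all(c("year", "population") %in% names(pop)))
  pop <- dplyr::arrange(dplyr::distinct(pop, .data$year, .data$population),
                        .data$year)
  if (nrow(pop) < 2) abort("need at least two yearly population anchors")
  if (anyDuplicated(pop$year)) {
    abort("conflicting population values for the same year")
  }
  if (is.null(years)) years <- seq(min(pop$year), max(pop$year))
  y0 <- min(years)

  # continuous month index; anchor at July (month 7) of each anchor year
  t_anchor <- 12 * (pop$year - y0) + 7
  out <- tidyr::expand_grid(year = sort(years), month = 1:12)
  t_out <- 12 * (out$year - y0) + out$month

  val <- stats::approx(t_anchor, pop$population, xout = t_out,
                       method = "linear", rule = 1)$y
  n <- length(t_anchor)
  lo <- t_out < t_anchor[1]
  hi <- t_out > t_anchor[n]
  slope_lo <- (pop$population[2] - pop$population[1]) /
    (t_anchor[2] - t_anchor[1])
  slope_hi <- (pop$population[n] - pop$population[n - 1]) /
    (t_anchor[n] - t_anchor[n - 1])
  val[lo] <- pop$population[1] + slope_lo * (t_out[lo] - t_anchor[1])
  val[hi] <- pop$population[n] + slope_hi * (t_out[hi] - t_anchor[n])

  if (any(val <= 0)) {
    abort("interpolation/extrapolation produced non-positive population")
  }
  dplyr::mutate(out, population = val)
}

#' Month-length correction
#'
#' Rescales each month's death count to what it would be in a 31-day month:
#' `count * 31 / days_in_month(year, month)`. Leap-year aware; 31-day months
#' are unchanged. This removes the spurious dip that short months (February
#' in particular) would otherwise impose on monthly comparisons.
#'
#' @param counts Tibble with `year`, `month` and the count column.
#' @param col Name of the count column to correct (default `"count"`).
#' @return The input tibble with `col` corrected in place.
#' @export
#' @examples
#' month_length_correct(tibble::tibble(year = 1981, month = 2, count = 56))
month_length_correct <- function(counts, col = "count") {
  stopifnot(all(c("year", "month", col) %in% names(counts)))
  if (any(counts[[col]] < 0)) abort("counts must be non-negative")
  counts[[col]] <- counts[[col]] * 31 /
    days_in_month(counts$year, counts$month)
  counts
}

#' Monthly death rates
#'
#' Divides (month-length-corrected) monthly death counts by the interpolated
#' monthly population and scales to deaths per `per` persons.
#'
#' @param counts Tibble (`year`, `month`, `count`), normally after
#'   [month_length_correct()].
#' @param pop_monthly Tibble (`year`, `month`, `population`) from
#'   [interpolate_population_monthly()].
#' @param per Rate denominator (default 100,000).
#' @return A tibble (`year`, `month`, `count`, `population`, `rate`), sorted.
#' @export
compute_death_rates <- function(counts, pop_monthly, per = 1e5) {
  stopifnot(all(c("year", "month", "count") %in% names(counts)),
            all(c("year", "month", "population") %in% names(pop_monthly)))
  out <- dplyr::inner_join(counts, pop_monthly, by = c("year", "month"))
  if (nrow(out) != nrow(counts)) {
    abort("count and population series do not align on (year, month)")
  }
  out %>%
    dplyr::mutate(rate = .data$count / .data$population * per) %>%
    dplyr::arrange(.data$year, .data$month)
}
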