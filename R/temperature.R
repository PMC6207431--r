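#' Population-weighted monthly regional temperature
#'
#' Averages sub-daily gridded temperatures within each cell-month (all
#' samples equally weighted), then combines cell means into a regional mean
#' using population weights normalised within the region. This turns a
#' reanalysis-style gridded field into one monthly series per climate
#' region.
#'
#' @param grid Long-format tibble of samples: `cell`, `timestamp` (or
#'   `year` + `month` columns directly), `temp_c`.
#' @param weights Tibble (`cell`, `region`, `weight`) of static population
#'   weights; every region needs positive total weight.
#' @return A tibble (`region`, `year`, `month`, `temp_c`), sorted.
#' @export
population_weighted_monthly_temperature <- function(grid, weights) {
  stopifnot(all(c("cell", "temp_c") %in% names(grid)),
            all(c("cell", "region", "weight") %in% names(weights)))
  if (any(weights$weight < 0)) abort("weights must be non-negative")
  totals <- tapply(weights$weight, weights$region, sum)
  if (any(totals <= 0)) abort("some region has zero total population weight")

  if (!all(c("year", "month") %in% names(grid))) {
    grid <- dplyr::mutate(grid,
                          year = lubridate::year(.data$timestamp),
                          month = lubridate::month(.data$timestamp))
  }
  cell_means <- grid %>%
    dplyr::group_by(.data$cell, .data$year, .data$month) %>%
    dplyr::summarise(temp_c = mean(.data$temp_c), .groups = "drop")

  cell_means %>%
    dplyr::inner_join(dplyr::select(weights, "cell", "region", "weight"),
                      by = "cell") %>%
    dplyr::group_by(.data$region, .data$year, .data$month) %>%
    dplyr::summarise(
      temp_c = sum(.data$temp_c * .data$weight) / sum(.data$weight),
      .groups = "drop") %>%
    dplyr::arrange(.data$region, .data$year, .data$month)
}

#' Regional temperature climatology
#'
#' Long-run summaries of a monthly regional temperature series: annual mean
#' (over all complete years), the 12-month climatology (mean of each
#' calendar month over years), its warmest month, and the annual range
#' (climatology max minus min). Incomplete years are excluded with a
#' warning.
#'
#' @param temps Tibble (`region`, `year`, `month`, `temp_c`), e.g. from
#'   [population_weighted_monthly_temperature()].
#' @return A list with `summary` (one row per region: `region`,
#'   `annual_mean`, `annual_range`, `peak_month`) and `monthly` (the
#'   climatology: `region`, `month`, `temp_c`).
#' @export
regional_climatology <- function(temps) {
  stopifnot(all(c("region", "year", "month", "temp_c") %in% names(temps)))
  complete <- temps %>%
    dplyr::group_by(.data$region, .data$year) %>%
    dplyr::filter(dplyr::n_distinct(.data$month) == 12) %>%
    dplyr::ungroup()
  n_dropped <- nrow(temps) - nrow(complete)
  if (n_dropped > 0) {
    warn(paste0("excluding ", n_dropped,
                " month(s) belonging to incomplete years"))
  }
  if (nrow(complete) == 0) abort("no complete years of temperature data")

  monthly <- complete %>%
    dplyr::group_by(.data$region, .data$month) %>%
    dplyr::summarise(temp_c = mean(.data$temp_c), .groups = "drop")
  summary <- monthly %>%
    dplyr::group_by(.data$region) %>%
    dplyr::summarise(annual_mean = mean(.data$temp_c),
                     annual_range = max(.data$temp_c) - min(.data$temp_c),
                     peak_month = .data$month[which.max(.data$temp_c)],
                     .groups = "drop")
  list(summary = summary, monthly = monthly)
}
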