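#' Load a stratified death-count table
#'
#' Reads delimited records of death counts (one row per death or
#' pre-aggregated), maps ICD codes to leaf cause categories and states to
#' climate regions, and aggregates duplicate keys by summing.
#'
#' Required columns: `year`, `month`, `state`, `age_group`, `sex`, `cause`,
#' `count`. An optional `revision` column gives the ICD revision per row;
#' without it, revision 9 is assumed through 1998 and revision 10 from 1999
#' (the switchover year of the US vital registration system). Values in
#' `cause` that are already leaf category ids pass through unmapped. Rows
#' with missing month or state are dropped with a message reporting how many.
#'
#' @param path Path to a CSV file (or a data frame, used as-is).
#' @param cause_map Rule table, see [read_cause_map()].
#' @param region_lookup State-to-region table, see [region_map()].
#' @param unmapped Passed to [map_cause()]: `"error"` (strict, default) or
#'   `"other"` (lenient).
#' @return A tibble with columns `year`, `month`, `region`, `age_group`,
#'   `sex`, `cause` (leaf category) and `count`, one row per unique key.
#' @export
load_deaths <- function(path, cause_map = default_cause_map(),
                        region_lookup = region_map(),
                        unmapped = c("error", "other")) {
  unmapped <- match.arg(unmapped)
  deaths <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  }
  required <- c("year", "month", "state", "age_group", "sex", "cause", "count")
  missing_cols <- setdiff(required, names(deaths))
  if (length(missing_cols) > 0) {
    abort(paste0("death table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  n_dropped <- sum(is.na(deaths$month) | is.na(deaths$state))
  if (n_dropped > 0) {
    inform(paste0("dropping ", n_dropped,
                  " row(s) with unknown month or state"))
    deaths <- dplyr::filter(deaths, !is.na(.data$month), !is.na(.data$state))
  }
  if (any(deaths$month < 1 | deaths$month > 12 |
            deaths$month != floor(deaths$month))) {
    abort("column 'month' must contain integers in 1..12")
  }
  if (any(deaths$count < 0)) {
    abort("column 'count' must be non-negative")
  }
  bad_age <- setdiff(unique(deaths$age_group), age_groups())
  if (length(bad_age) > 0) {
    abort(paste0("unknown age group(s): ", paste(bad_age, collapse = ", ")))
  }

  revision <- if ("revision" %in% names(deaths)) {
    deaths$revision
  } else {
    ifelse(deaths$year <= 1998, 9L, 10L)
  }

  mapped_cause <- deaths$cause
  needs_map <- !(mapped_cause %in% cause_categories())
  if (any(needs_map)) {
    mapped_cause[needs_map] <- map_cause(mapped_cause[needs_map],
                                         revision[needs_map],
                                         cause_map = cause_map,
                                         unmapped = unmapped)
  }

  mapped_region <- map_region(deaths$state, map = region_lookup)
  if (anyNA(mapped_region)) {
    abort(paste0("unknown state code(s): ",
                 paste(sort(unique(deaths$state[is.na(mapped_region)])),
                       collapse = ", ")))
  }

  deaths %>%
    dplyr::mutate(cause = !!mapped_cause, region = !!mapped_region) %>%
    dplyr::group_by(.data$year, .data$month, .data$region, .data$age_group,
                    .data$sex, .data$cause) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' Load a yearly population table
#'
#' @param path Path to a CSV with columns `year`, `state` (or `region`),
#'   `age_group`, `sex`, `population`, or a data frame.
#' @param region_lookup State-to-region table, see [region_map()].
#' @return A tibble keyed by (`year`, `region`, `age_group`, `sex`) with
#'   positive `population`, duplicates summed.
#' @export
load_population <- function(path, region_lookup = region_map()) {
  pop <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  }
  if (!"region" %in% names(pop)) {
    if (!"state" %in% names(pop)) {
      abort("population table needs a 'state' or 'region' column")
    }
    pop$region <- map_region(pop$state, map = region_lookup)
  }
  required <- c("year", "region", "age_group", "sex", "population")
  missing_cols <- setdiff(required, names(pop))
  if (length(missing_cols) > 0) {
    abort(paste0("population table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(pop$population <= 0)) abort("population must be positive")
  pop %>%
    dplyr::group_by(.data$year, .data$region, .data$age_group, .data$sex) %>%
    dplyr::summarise(population = sum(.data$population), .groups = "drop")
}

match_stratum <- function(deaths, stratum) {
  for (field in c("age_group", "sex")) {
    val <- stratum[[field]]
    if (!is.null(val) && !is.na(val)) {
      deaths <- deaths[deaths[[field]] == val, , drop = FALSE]
    }
  }
  region <- stratum[["region"]] %||% "national"
  if (!is.na(region) && region != "national") {
    deaths <- deaths[deaths$region == region, , drop = FALSE]
  }
  deaths
}

#' Aggregate a death table into one monthly count series
#'
#' Selects a stratum (age group, sex, region, cause — each optional; region
#' `"national"` or a cause of `"all_cause"` pool over that dimension), sums
#' counts by calendar month, and returns a contiguous year-month series over
#' the analysis window with absent cells filled with 0.
#'
#' @param deaths Output of [load_deaths()].
#' @param age_group,sex,region Stratum selectors; `NULL` pools over the
#'   dimension (`region = "national"` likewise pools all regions).
#' @param cause Leaf category, a rollup id (`cardiorespiratory`, `injuries`),
#'   or `"all_cause"` (default).
#' @param years Analysis window as an integer vector; defaults to the range
#'   of years present.
#' @return A tibble (`year`, `month`, `count`), sorted, one row per month.
#' @export
aggregate_series <- function(deaths, age_group = NULL, sex = NULL,
                             cause = "all_cause", region = "national",
                             years = NULL) {
  stopifnot(is.data.frame(deaths))
  if (is.null(years)) years <- seq(min(deaths$year), max(deaths$year))
  if (length(years) == 0) abort("empty analysis window")

  rollups <- cause_rollups()
  # pre-aggregated tables may label rows with the rollup id itself
  leaves <- if (cause == "all_cause") {
    c(cause_categories(), names(rollups))
  } else if (cause %in% names(rollups)) {
    c(rollups[[cause]], cause)
  } else if (cause %in% cause_categories()) {
    cause
  } else {
    abort(paste0("unknown cause '", cause, "'"))
  }

  sel <- match_stratum(deaths, list(age_group = age_group, sex = sex,
                                    region = region))
  sel <- sel[sel$cause %in% leaves & sel$year %in% years, , drop = FALSE]
  if (nrow(sel) == 0) {
    warn("stratum has no deaths anywhere in the window; returning zeros")
  }

  grid <- tidyr::expand_grid(year = sort(years), month = 1:12)
  agg <- sel %>%
    dplyr::group_by(.data$year, .data$month) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  n_missing <- nrow(grid) - nrow(agg)
  if (n_missing > 0 && nrow(sel) > 0) {
    inform(paste0(n_missing, " month(s) with no deaths filled with 0"))
  }
  grid %>%
    dplyr::left_join(agg, by = c("year", "month")) %>%
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0)) %>%
    dplyr::arrange(.data$year, .data$month)
}

#' Cause-of-death shares
#'
#' Counts deaths by leaf category and by the derived rollups, and expresses
#' each as a percent of all-cause deaths (reported to one decimal place).
#'
#' @param deaths A death table with columns `cause` (leaf category id) and
#'   `count` (e.g. from [load_deaths()], or a printed summary table).
#' @return A tibble (`category`, `count`, `percent`, `is_rollup`); leaf
#'   counts sum to the `all_cause` row.
#' @export
#' @examples
#' path <- system.file("extdata", "us_cause_totals_1980_2016.csv",
#'                     package = "mortseason")
#' totals <- readr::read_csv(path, show_col_types = FALSE)
#' summarize_cause_shares(dplyr::rename(totals, cause = category))
summarize_cause_shares <- function(deaths) {
  stopifnot(nrow(deaths) > 0, all(c("cause", "count") %in% names(deaths)))
  leaves <- deaths %>%
    dplyr::group_by(category = .data$cause) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  total <- sum(leaves$count)
  rollups <- purrr::imap_dfr(cause_rollups(), function(members, id) {
    tibble::tibble(category = id,
                   count = sum(leaves$count[leaves$category %in% members]))
  })
  dplyr::bind_rows(
    dplyr::mutate(leaves, is_rollup = FALSE),
    dplyr::mutate(rollups, is_rollup = TRUE)
  ) %>%
    dplyr::mutate(percent = round(100 * .data$count / total, 1)) %>%
    dplyr::select("category", "count", "percent", "is_rollup")
}
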