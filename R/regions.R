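#' US climate regions
#'
#' The nine NOAA climate regions of the contiguous-plus-offshore USA, with
#' their constituent states, 2016 resident population and long-run (1980-2016)
#' mean annual temperature. These are the standard groupings used for
#' sub-national aggregation of mortality and temperature series.
#'
#' @return A tibble with one row per region and columns `region`,
#'   `states` (list-column of USPS two-letter codes), `population_2016`,
#'   `mean_annual_temp_c`.
#' @export
#' @examples
#' climate_regions()
climate_regions <- function() {
  tibble::tibble(
    region = c(
      "Central", "East North Central", "Northeast", "Northwest", "South",
      "Southeast", "Southwest", "West", "West North Central"
    ),
    states = list(
      c("IL", "IN", "KY", "MO", "OH", "TN", "WV"),
      c("IA", "MI", "MN", "WI"),
      # DC is grouped with Maryland in the Northeast
      c("CT", "DE", "ME", "MD", "MA", "NH", "NJ", "NY", "PA", "RI", "VT", "DC"),
      c("AK", "ID", "OR", "WA"),
      c("AR", "KS", "LA", "MS", "OK", "TX"),
      c("AL", "FL", "GA", "NC", "SC", "VA"),
      c("AZ", "CO", "NM", "UT"),
      c("CA", "HI", "NV"),
      c("MT", "NE", "ND", "SD", "WY")
    ),
    population_2016 = c(
      50191326, 24418738, 64046741, 13811810, 45388414,
      59356072, 17613981, 43708574, 5168753
    ),
    mean_annual_temp_c = c(11.6, 8.0, 10.6, 8.2, 18.0, 18.4, 13.6, 16.6, 7.6)
  )
}

#' State-to-region lookup table
#'
#' Flat version of [climate_regions()]: one row per state (all 50 states
#' plus the District of Columbia), giving the climate region it belongs to.
#'
#' @return A tibble with columns `state` (USPS code) and `region`.
#' @export
#' @examples
#' region_map()
region_map <- function() {
  climate_regions() %>%
    dplyr::select("region", "states") %>%
    tidyr::unnest_longer("states", values_to = "state") %>%
    dplyr::select("state", "region")
}

#' Map state codes to climate regions
#'
#' @param state Character vector of USPS two-letter state codes (or a region
#'   id, which passes through unchanged).
#' @param map Lookup table as returned by [region_map()].
#' @return Character vector of region ids.
#' @export
#' @examples
#' map_region(c("FL", "NY"))
map_region <- function(state, map = region_map()) {
  out <- map$region[match(state, map$state)]
  # already-aggregated inputs may carry region ids (or "national") directly
  pass <- is.na(out) & state %in% c(map$region, "national")
  out[pass] <- state[pass]
  out
}
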