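test_that("ICD codes map to leaf categories, first matching rule wins", {
  expect_equal(map_cause(c("C34", "J18", "X99", "I21"), 10),
               c("cancers", "respiratory_infections",
                 "injuries_intentional", "cardiovascular"))
  expect_equal(map_cause(c("162.9", "E810", "485"), 9),
               c("cancers", "injuries_unintentional",
                 "respiratory_infections"))
  # J10 sits in both a hypothetical broad chronic range and the infection
  # range; rule order decides
  custom <- tibble::tibble(revision = "10",
                           pattern = c("J00-J99", "J00-J22"),
                           category = c("chronic_respiratory",
                                        "respiratory_infections"))
  expect_equal(map_cause("J10", 10, cause_map = custom), "chronic_respiratory")
})

test_that("unmapped codes error in strict mode, route to other in lenient", {
  no_catchall <- tibble::tibble(revision = "10", pattern = "C00-D48",
                                category = "cancers")
  expect_error(map_cause("Z99", 10, cause_map = no_catchall), "Z99")
  expect_message(
    out <- map_cause(c("C50", "Z99"), 10, cause_map = no_catchall,
                     unmapped = "other"),
    "Z99")
  expect_equal(out, c("cancers", "other"))
})

test_that("load_deaths maps, validates and aggregates", {
  row <- tibble::tibble(year = 2016, month = 2, state = "FL",
                        age_group = "65-74", sex = "female",
                        cause = "I21", count = 3)
  out <- load_deaths(row)
  expect_equal(out$region, "Southeast")
  expect_equal(out$cause, "cardiovascular")

  dup <- dplyr::bind_rows(row, dplyr::mutate(row, count = 5),
                          dplyr::mutate(row, count = 2))
  expect_equal(load_deaths(dup)$count, 10)

  expect_error(load_deaths(dplyr::mutate(row, month = 13)), "month")
  expect_error(load_deaths(dplyr::select(row, -"sex")), "sex")
  expect_error(load_deaths(dplyr::mutate(row, count = -1)), "non-negative")

  with_na <- dplyr::bind_rows(row, dplyr::mutate(row, month = NA))
  expect_message(out <- load_deaths(with_na), "1 row")
  expect_equal(out$count, 3)
})

test_that("every state plus DC maps to exactly one of nine regions", {
  rm <- region_map()
  expect_equal(nrow(rm), 51)
  expect_equal(anyDuplicated(rm$state), 0)
  expect_setequal(unique(rm$region), climate_regions()$region)
  expect_length(unique(rm$region), 9)
  expect_equal(map_region("DC"), "Northeast")
})

test_that("leaf categories partition all-cause and regions partition national", {
  deaths <- load_deaths(toy_deaths())
  all_cause <- suppressWarnings(suppressMessages(aggregate_series(deaths)))
  by_leaf <- lapply(cause_categories(), function(cc) {
    suppressWarnings(suppressMessages(
      aggregate_series(deaths, cause = cc)))$count
  })
  expect_equal(Reduce(`+`, by_leaf), all_cause$count)

  by_region <- lapply(unique(deaths$region), function(r) {
    suppressWarnings(suppressMessages(
      aggregate_series(deaths, region = r)))$count
  })
  expect_equal(Reduce(`+`, by_region), all_cause$count)

  # rollup additivity
  cr <- suppressWarnings(suppressMessages(
    aggregate_series(deaths, cause = "cardiorespiratory")))
  parts <- lapply(cause_rollups()$cardiorespiratory, function(cc) {
    suppressWarnings(suppressMessages(
      aggregate_series(deaths, cause = cc)))$count
  })
  expect_equal(Reduce(`+`, parts), cr$count)
})

test_that("aggregate_series fills a contiguous window and flags empty strata", {
  deaths <- load_deaths(toy_deaths())
  out <- suppressMessages(aggregate_series(deaths, sex = "male"))
  expect_equal(nrow(out), 24)
  expect_equal(unique(out$count[!out$month %in% c(1, 7)]), 0)

  expect_warning(
    zero <- suppressMessages(aggregate_series(deaths, age_group = "0-4")),
    "no deaths")
  expect_true(all(zero$count == 0))
})

test_that("a death table survives a CSV round trip unchanged", {
  deaths <- load_deaths(toy_deaths())
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(deaths, path)
  reread <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(reread), as.data.frame(deaths))
})

test_that("cause shares reproduce printed national totals", {
  shares <- summarize_cause_shares(table1_totals())
  pick <- function(cat) shares$percent[shares$category == cat]
  expect_equal(pick("cardiorespiratory"), 48.1)
  expect_equal(pick("cancers"), 23.2)
  expect_equal(pick("injuries"), 6.8)
  expect_equal(pick("all_cause"), 100)
  leaf_sum <- sum(shares$count[!shares$is_rollup])
  expect_equal(leaf_sum, shares$count[shares$category == "all_cause"])

  single <- summarize_cause_shares(
    tibble::tibble(cause = "cancers", count = 42))
  expect_equal(single$percent[single$category == "cancers"], 100)
})
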