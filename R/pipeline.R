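pop_for_stratum <- function(pop, age_group = NULL, sex = NULL,
                            region = "national") {
  sel <- match_stratum(pop, list(age_group = age_group, sex = sex,
                                 region = region))
  sel %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(population = sum(.data$population), .groups = "drop")
}

#' Build monthly death rates for one stratum
#'
#' Aggregates the death table for a stratum, applies the month-length
#' correction, interpolates the stratum's yearly population to months, and
#' returns corrected monthly death rates — the standard preparation before
#' the wavelet, timing and trend analyses.
#'
#' @param deaths Death table from [load_deaths()] or [simulate_deaths()].
#' @param population Yearly population table from [load_population()] or
#'   [simulate_population()].
#' @inheritParams aggregate_series
#' @param per Rate denominator (default 100,000).
#' @return A tibble (`year`, `month`, `count`, `population`, `rate`) with
#'   month-length-corrected counts and rates.
#' @export
stratum_rates <- function(deaths, population, age_group = NULL, sex = NULL,
                          cause = "all_cause", region = "national",
                          years = NULL, per = 1e5) {
  counts <- aggregate_series(deaths, age_group = age_group, sex = sex,
                             cause = cause, region = region, years = years)
  counts <- month_length_correct(counts)
  pop <- pop_for_stratum(population, age_group = age_group, sex = sex,
                         region = region)
  pop_m <- interpolate_population_monthly(pop, years = unique(counts$year))
  compute_death_rates(counts, pop_m, per = per)
}

default_run_options <- function() {
  list(wavelet = list(degree = 4, n_sims = 100),
       bootstrap = list(n = 1000),
       seeds = list(simulation = 1L, inference = 1L))
}

#' Run the full seasonality pipeline
#'
#' Orchestrates every stage for a set of strata: data simulation (or
#' loading), monthly rate construction, the wavelet 12-month seasonality
#' test, circular timing of maximum/minimum mortality with bootstrap CIs,
#' and the weighted trend in the yearly peak-versus-trough percent
#' difference. A stratum that fails is logged and skipped; the rest
#' complete.
#'
#' @param config A named list (or path to a YAML file with the same
#'   structure) with components:
#'   \describe{
#'     \item{simulation}{arguments for [simulation_config()] (strata may be
#'       a data frame or list of rows); exclusive with `inputs`.}
#'     \item{inputs}{list with paths `deaths` and `population` (CSV), and
#'       optionally `cause_map`; exclusive with `simulation`.}
#'     \item{strata}{list of stratum requests, each a named list with any of
#'       `age_group`, `sex`, `cause`, `region`; defaults to the distinct
#'       strata present in the death table.}
#'     \item{window}{length-2 analysis window in years (optional).}
#'     \item{wavelet}{`degree`, `n_sims` (defaults 4, 100).}
#'     \item{bootstrap}{`n` (default 1000).}
#'     \item{seeds}{`simulation` and `inference` seeds (defaults 1, 1).}
#'     \item{output_dir}{if given, result tables are written there as CSV
#'       plus a `metadata.yaml` with the seeds and config hash.}
#'   }
#' @return A list: `p_values`, `timing`, `trend` and `yearly` tibbles (all
#'   keyed by the stratum columns), the run `log` (character), and
#'   `config_hash`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  has_sim <- !is.null(config$simulation)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    abort("config must specify exactly one of 'simulation' or 'inputs'")
  }
  opts <- utils::modifyList(default_run_options(),
                            config[intersect(names(config),
                                             c("wavelet", "bootstrap",
                                               "seeds"))])
  log <- character()
  note <- function(msg) log <<- c(log, msg)

  if (has_sim) {
    sim_args <- config$simulation
    if (!is.null(sim_args$strata) && !is.data.frame(sim_args$strata)) {
      sim_args$strata <- dplyr::bind_rows(sim_args$strata)
    }
    sim_args$seed <- sim_args$seed %||% opts$seeds$simulation
    sim_cfg <- do.call(simulation_config, sim_args)
    population <- simulate_population(sim_cfg)
    deaths <- simulate_deaths(sim_cfg, population)
    note("simulated deaths and population")
  } else {
    deaths <- load_deaths(config$inputs$deaths,
                          cause_map = if (!is.null(config$inputs$cause_map)) {
                            read_cause_map(config$inputs$cause_map)
                          } else {
                            default_cause_map()
                          })
    population <- load_population(config$inputs$population)
    note("loaded deaths and population from files")
  }

  years <- if (!is.null(config$window)) {
    seq(config$window[1], config$window[2])
  }
  strata <- config$strata
  if (is.null(strata)) {
    strata <- deaths %>%
      dplyr::distinct(.data$age_group, .data$sex, .data$cause, .data$region) %>%
      purrr::transpose()
  }

  results <- purrr::map(strata, function(s) {
    label <- paste(s$age_group %||% "all", s$sex %||% "all",
                   s$cause %||% "all_cause", s$region %||% "national",
                   sep = "/")
    tryCatch({
      counts <- aggregate_series(deaths, age_group = s$age_group,
                                 sex = s$sex,
                                 cause = s$cause %||% "all_cause",
                                 region = s$region %||% "national",
                                 years = years)
      if (all(counts$count == 0)) {
        note(paste0("skipped all-zero stratum ", label))
        return(NULL)
      }
      counts <- month_length_correct(counts)
      pop <- pop_for_stratum(population, age_group = s$age_group,
                             sex = s$sex, region = s$region %||% "national")
      pop_m <- interpolate_population_monthly(pop,
                                              years = unique(counts$year))
      rates <- compute_death_rates(counts, pop_m)
      cwt <- test_seasonality(rates, degree = opts$wavelet$degree,
                              n_sims = opts$wavelet$n_sims,
                              seed = opts$seeds$inference)
      timing <- seasonal_timing(rates, n_boot = opts$bootstrap$n,
                                seed = opts$seeds$inference)
      diffs <- yearly_percent_difference(rates)
      trend <- glance(fit_weighted_trend(diffs))
      key <- tibble::tibble(age_group = s$age_group %||% "all",
                            sex = s$sex %||% "all",
                            cause = s$cause %||% "all_cause",
                            region = s$region %||% "national")
      note(paste0("completed stratum ", label))
      list(p_values = dplyr::bind_cols(key, glance(cwt)),
           timing = dplyr::bind_cols(key, timing),
           trend = dplyr::bind_cols(key, trend),
           yearly = dplyr::bind_cols(key[rep(1, nrow(diffs)), ], diffs))
    }, error = function(e) {
      note(paste0("stratum ", label, " failed: ", conditionMessage(e)))
      NULL
    })
  })
  results <- purrr::compact(results)
  if (length(results) == 0) abort("every stratum failed; see log")

  out <- list(
    p_values = purrr::map_dfr(results, "p_values"),
    timing = purrr::map_dfr(results, "timing"),
    trend = purrr::map_dfr(results, "trend"),
    yearly = purrr::map_dfr(results, "yearly"),
    log = log,
    config_hash = rlang::hash(config)
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("p_values", "timing", "trend", "yearly")) {
      readr::write_csv(out[[nm]],
                       file.path(config$output_dir, paste0(nm, ".csv")))
    }
    yaml::write_yaml(list(config_hash = out$config_hash, seeds = opts$seeds,
                          n_strata = nrow(out$p_values)),
                     file.path(config$output_dir, "metadata.yaml"))
  }
  out
}
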