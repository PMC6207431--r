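#' Leaf cause-of-death categories and their rollups
#'
#' The ten mutually exclusive leaf categories every ICD code maps to, and
#' the derived parents: `cardiorespiratory` (cardiovascular + chronic
#' respiratory + respiratory infections), `injuries` (unintentional +
#' intentional) and `all_cause` (everything).
#'
#' @return `cause_categories()`: character vector of the 10 leaf ids.
#'   `cause_rollups()`: named list mapping each rollup id to its leaf members.
#' @export
#' @examples
#' cause_categories()
#' cause_rollups()$cardiorespiratory
cause_categories <- function() {
  c("cancers", "cardiovascular", "chronic_respiratory",
    "respiratory_infections", "injuries_unintentional",
    "injuries_intentional", "perinatal", "maternal", "substance_use", "other")
}

#' @rdname cause_categories
#' @export
cause_rollups <- function() {
  list(
    cardiorespiratory = c("cardiovascular", "chronic_respiratory",
                          "respiratory_infections"),
    injuries = c("injuries_unintentional", "injuries_intentional"),
    all_cause = cause_categories()
  )
}

#' Read a cause-mapping table
#'
#' A cause map is an ordered rule list with columns `revision` (9, 10 or `*`),
#' `pattern` (a prefix range like `C00-D48` or `140-239`, or the catch-all
#' `*`) and `category` (a leaf id from [cause_categories()]). The first
#' matching rule wins. `default_cause_map()` returns the map shipped with the
#' package, which uses ICD chapter-style ranges and ends each revision with a
#' catch-all to `other`.
#'
#' @param path Path to a delimited file with the three columns above.
#' @return A tibble with columns `revision`, `pattern`, `category`, in rule
#'   order.
#' @export
read_cause_map <- function(path) {
  map <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("revision", "pattern", "category")
  missing <- setdiff(required, names(map))
  if (length(missing) > 0) {
    abort(paste0("cause map is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(map$category), cause_categories())
  if (length(bad) > 0) {
    abort(paste0("cause map has unknown categories: ",
                 paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(map[required])
}

#' @rdname read_cause_map
#' @export
default_cause_map <- function() {
  read_cause_map(system.file("extdata", "cause_map_default.csv",
                             package = "mortseason", mustWork = TRUE))
}

# Reduce an ICD code to the 3-character (4 for ICD-9 E-codes) key used for
# range matching: uppercase, dots stripped.
icd_key <- function(code, width = 3L) {
  code <- toupper(gsub("[. ]", "", code))
  substr(code, 1L, width)
}

# Does `code` fall in the prefix range `lo-hi`? Works lexicographically,
# which is valid for equal-width alphanumeric ICD prefixes.
icd_in_range <- function(code, lo, hi) {
  key <- icd_key(code, width = nchar(lo))
  !is.na(key) & nchar(key) == nchar(lo) & key >= lo & key <= hi
}

#' Map ICD codes to leaf cause categories
#'
#' Applies the first matching rule of `cause_map` for the given ICD revision.
#' Codes are compared on their 3-character prefix (4 characters for ICD-9
#' external-cause E-codes), case-insensitively and ignoring decimal points.
#'
#' @param code Character vector of ICD codes (e.g. `"I21"`, `"E810"`,
#'   `"162.9"`).
#' @param revision ICD revision, 9 or 10 (scalar or vector).
#' @param cause_map Rule table, see [read_cause_map()].
#' @param unmapped `"error"` (strict, default): any code matching no rule
#'   aborts with the offending codes listed; `"other"` (lenient): such codes
#'   are routed to the `other` category with a message.
#' @return Character vector of leaf category ids.
#' @export
#' @examples
#' map_cause(c("C34", "J18", "X99"), 10)
map_cause <- function(code, revision, cause_map = default_cause_map(),
                      unmapped = c("error", "other")) {
  unmapped <- match.arg(unmapped)
  stopifnot(length(code) > 0, all(nzchar(code)))
  revision <- as.character(rep_len(revision, length(code)))
  if (!all(revision %in% c("9", "10"))) {
    abort("ICD revision must be 9 or 10")
  }
  out <- rep(NA_character_, length(code))
  for (i in seq_len(nrow(cause_map))) {
    rule_rev <- cause_map$revision[i]
    pat <- cause_map$pattern[i]
    todo <- is.na(out) & (rule_rev == "*" | revision == rule_rev)
    if (!any(todo)) next
    if (pat == "*") {
      out[todo] <- cause_map$category[i]
    } else {
      parts <- strsplit(pat, "-", fixed = TRUE)[[1]]
      lo <- parts[1]
      hi <- if (length(parts) > 1) parts[2] else parts[1]
      hit <- todo & icd_in_range(code, lo, hi)
      out[hit] <- cause_map$category[i]
    }
  }
  if (anyNA(out)) {
    offending <- sort(unique(code[is.na(out)]))
    if (unmapped == "error") {
      abort(paste0("unmappable ICD code(s): ",
                   paste(offending, collapse = ", ")))
    }
    inform(paste0("routing ", sum(is.na(out)), " death record(s) with ",
                  "unmapped ICD code(s) to 'other': ",
                  paste(offending, collapse = ", ")))
    out[is.na(out)] <- "other"
  }
  out
}
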