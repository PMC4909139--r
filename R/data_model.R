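# Canonical tables, delimited-text IO, validation, and the survey-selection
# filter. Three tables travel through the pipeline:
#   children:   child_id, survey_id, cluster_id, household_id, age_months,
#               sex, haz, weight  (+ derived stunted / flags / wealth_quintile)
#   households: household_id, survey_id, asset_* columns, optional wealth_score
#   surveys:    survey_id, country_iso3, year, source, age_ceiling_months,
#               optional region
# All files are comma-separated UTF-8 with a header row; column names are
# remapped through a user config because DHS and MICS recodes differ.

.child_required <- c("child_id", "survey_id", "cluster_id", "household_id",
                     "age_months", "sex", "haz", "weight")
.survey_required <- c("survey_id", "country_iso3", "year", "source",
                      "age_ceiling_months")

# Rename columns of `df` according to a named map canonical_name = file_name.
apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  for (canon in names(col_map)) {
    src <- col_map[[canon]]
    if (!src %in% names(df)) {
      stop(sprintf("column '%s' (mapped to '%s') not found in file", src, canon))
    }
    names(df)[names(df) == src] <- canon
  }
  df
}

#' Read and validate a child-level microdata table
#'
#' Reads a comma-separated table of measured children, remaps column names,
#' validates every row, and derives the stunting indicator. Rows with missing
#' height-for-age z-scores (HAZ) are retained but flagged; rows with
#' biologically implausible HAZ (|HAZ| beyond `haz_limit`) are flagged and
#' excluded from all downstream estimators. A validation report (counts of
#' flagged rows) is attached as attribute `"validation"`.
#'
#' @param path path to a CSV file with a header row.
#' @param col_map optional named list mapping canonical column names
#'   (`child_id`, `survey_id`, `cluster_id`, `household_id`, `age_months`,
#'   `sex`, `haz`, `weight`) to the file's column names.
#' @param surveys optional survey metadata table (see [read_surveys()]); when
#'   supplied, children referencing unknown surveys raise an error and ages
#'   are checked against each survey's age ceiling.
#' @param haz_limit absolute z-score beyond which HAZ is treated as
#'   implausible (default 6, the usual anthropometric screening cut).
#' @return a `data.frame` of validated child records with derived columns
#'   `stunted` (logical; strictly HAZ < -2), `haz_missing`, `haz_implausible`.
#' @export
read_children <- function(path, col_map = NULL, surveys = NULL, haz_limit = 6) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  df <- apply_col_map(df, col_map)
  validate_children(df, surveys = surveys, haz_limit = haz_limit)
}

#' Validate a child table and derive the stunting indicator
#'
#' @param df data.frame holding the canonical child columns.
#' @inheritParams read_children
#' @return the validated data.frame (see [read_children()]).
#' @export
validate_children <- function(df, surveys = NULL, haz_limit = 6) {
  missing_cols <- setdiff(.child_required, names(df))
  if (length(missing_cols)) {
    stop("missing required child columns: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(df)
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      # +1 for the header: report file line numbers, not row indices
      stop(sprintf("invalid child record at line %d: %s", idx[1] + 1L, what))
    }
  }
  df$weight <- as.numeric(df$weight)
  df$haz <- as.numeric(df$haz)
  df$age_months <- as.integer(df$age_months)
  bad(!is.finite(df$weight) | df$weight <= 0, "weight must be a positive number")
  bad(is.na(df$age_months) | df$age_months < 0, "age_months must be a non-negative integer")
  bad(!df$sex %in% c("male", "female"), "sex must be 'male' or 'female'")

  if (!is.null(surveys)) {
    unknown <- !df$survey_id %in% surveys$survey_id
    bad(unknown, "unknown survey_id")
    ceiling_of <- setNames(surveys$age_ceiling_months, surveys$survey_id)
    bad(df$age_months >= ceiling_of[df$survey_id],
        "age_months at or above the survey's age ceiling")
  }

  df$haz_missing <- !is.finite(df$haz)
  df$haz_implausible <- !df$haz_missing & abs(df$haz) > haz_limit
  usable <- !df$haz_missing & !df$haz_implausible
  input_stunted <- if ("stunted" %in% names(df)) as.logical(df$stunted) else NULL
  df$stunted <- ifelse(usable, df$haz < -2, NA)
  if (!is.null(input_stunted)) {
    clash <- usable & !is.na(input_stunted) & (input_stunted != df$stunted)
    bad(clash, "stunted column contradicts HAZ < -2")
  }
  if ("wealth_quintile" %in% names(df)) {
    q <- df$wealth_quintile
    bad(!is.na(q) & !q %in% 1:5, "wealth_quintile must be in 1..5")
  }
  attr(df, "validation") <- list(
    n_input = n,
    n_haz_missing = sum(df$haz_missing),
    n_haz_implausible = sum(df$haz_implausible),
    n_usable = sum(usable)
  )
  df
}

#' Read a household asset table
#'
#' Asset indicator columns are those matching `asset_prefix`; a
#' `wealth_score` column, if present, is carried through so precomputed
#' survey-team scores can be used directly.
#'
#' @param path path to a CSV file.
#' @param col_map optional named list mapping `household_id`, `survey_id`
#'   (and `wealth_score`) to the file's column names.
#' @param asset_prefix prefix identifying asset indicator columns.
#' @return data.frame with `household_id`, `survey_id`, asset columns and
#'   optionally `wealth_score`.
#' @export
read_households <- function(path, col_map = NULL, asset_prefix = "asset_") {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  df <- apply_col_map(df, col_map)
  for (col in c("household_id", "survey_id")) {
    if (!col %in% names(df)) stop("missing required household column: ", col)
  }
  assets <- grep(paste0("^", asset_prefix), names(df), value = TRUE)
  if (!length(assets) && !"wealth_score" %in% names(df)) {
    stop("household table has neither asset indicator columns nor wealth_score")
  }
  # asset vectors must be conformable within each survey (same columns, no NA)
  for (a in assets) {
    if (anyNA(df[[a]])) stop("missing values in asset column ", a)
  }
  df
}

#' Read and validate the survey metadata table
#'
#' @param path path to a CSV file with columns `survey_id`, `country_iso3`,
#'   `year` (survey midpoint, real-valued for multi-year fieldwork), `source`
#'   (`DHS` or `MICS`), `age_ceiling_months` (36 or 60) and optional `region`.
#' @param col_map optional named list remapping column names.
#' @return validated data.frame of survey metadata.
#' @export
read_surveys <- function(path, col_map = NULL) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  df <- apply_col_map(df, col_map)
  validate_surveys(df)
}

#' @rdname read_surveys
#' @param df data.frame of survey metadata to validate in place.
#' @export
validate_surveys <- function(df) {
  missing_cols <- setdiff(.survey_required, names(df))
  if (length(missing_cols)) {
    stop("missing required survey columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$survey_id)) stop("duplicate survey_id in survey table")
  df$year <- as.numeric(df$year)
  if (any(!is.finite(df$year) | df$year < 1990 | df$year > 2030)) {
    stop("survey year must lie in [1990, 2030]")
  }
  if (!all(df$source %in% c("DHS", "MICS"))) {
    stop("source must be 'DHS' or 'MICS'")
  }
  if (!all(df$age_ceiling_months %in% c(36L, 60L))) {
    stop("age_ceiling_months must be 36 or 60")
  }
  # the same age range must be analysed in every survey of a country
  by_country <- split(df$age_ceiling_months, df$country_iso3)
  inconsistent <- names(by_country)[vapply(by_country, function(x) length(unique(x)) > 1, logical(1))]
  if (length(inconsistent)) {
    stop("inconsistent age ceilings within country: ", paste(inconsistent, collapse = ", "))
  }
  df
}

#' Write canonical tables back to CSV
#'
#' Plain `write.csv` wrappers kept as named functions so the IO convention
#' (UTF-8, header, no row names) is applied uniformly and round-trips with
#' the readers.
#'
#' @param df table to write.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_children <- function(df, path) {
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_children
#' @export
write_households <- function(df, path) {
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_children
#' @export
write_surveys <- function(df, path) {
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Countries eligible for trend analysis
#'
#' A country qualifies when it contributes at least `min_surveys` surveys and
#' the interval between its earliest and latest survey midpoints is at least
#' `min_span` years. The result is order-independent and idempotent.
#'
#' @param surveys survey metadata table (see [read_surveys()]).
#' @param min_surveys minimum number of surveys per country (default 2).
#' @param min_span minimum years between earliest and latest survey
#'   (default 10).
#' @return sorted character vector of eligible `country_iso3` codes.
#' @export
#' @examples
#' s <- data.frame(survey_id = c("a", "b", "c"),
#'                 country_iso3 = c("NPL", "NPL", "BRA"),
#'                 year = c(2001, 2011, 2006),
#'                 source = "DHS", age_ceiling_months = 60L)
#' select_eligible_countries(s)  # "NPL"
select_eligible_countries <- function(surveys, min_surveys = 2L, min_span = 10) {
  spans <- aggregate(year ~ country_iso3, data = surveys,
                     FUN = function(y) c(n = length(y), span = max(y) - min(y)))
  ok <- spans$year[, "n"] >= min_surveys & spans$year[, "span"] >= min_span
  sort(spans$country_iso3[ok])
}
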