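#' Read an annual cold-stun stranding table
#'
#' Reads a comma-delimited table with (at least) `year` and `count` columns
#' into a validated stranding series: one row per calendar year, strictly
#' increasing years with no gaps inside the retained range, and non-negative
#' integer counts. A stranding season spans October through January but is
#' labelled by the calendar year in which it starts.
#'
#' Column matching is case-insensitive and by name, not position, so header
#' variants such as `Year,Count` are accepted.
#'
#' @param path Path to a CSV file with a single header row.
#' @param year_range Optional inclusive `c(first, last)` pair; only rows
#'   inside the range are kept, and every year in the range must be present.
#' @return A tibble with integer columns `year` and `count`.
#' @examples
#' path <- system.file("extdata", "s1_strandings_synthetic.csv",
#'                     package = "coldstunr")
#' read_strandings(path, year_range = c(1982, 2016))
#' @export
read_strandings <- function(path, year_range = NULL) {
  df <- read_named_csv(path, c("year", "count"))
  df$year <- coerce_integer(df$year, "year")
  df$count <- coerce_integer(df$count, "count")
  if (any(df$count < 0)) abort("stranding counts must be non-negative")
  if (!is.null(year_range)) {
    stopifnot(length(year_range) == 2)
    df <- dplyr::filter(df, .data$year >= year_range[1], .data$year <= year_range[2])
    missing <- setdiff(seq(year_range[1], year_range[2]), df$year)
    if (length(missing) > 0) {
      abort(paste0("missing year(s) inside requested range: ",
                   paste(missing, collapse = ", ")))
    }
  }
  df <- dplyr::arrange(df, .data$year)
  check_years_contiguous(df$year, "stranding")
  tibble::as_tibble(df[, c("year", "count")])
}

#' Read an annual hatchling-release table
#'
#' As [read_strandings()] but for `year` and `hatchlings` columns and without
#' a gap requirement beyond strictly increasing, duplicate-free years.
#'
#' @inheritParams read_strandings
#' @return A tibble with integer columns `year` and `hatchlings`.
#' @export
read_hatchlings <- function(path) {
  df <- read_named_csv(path, c("year", "hatchlings"))
  df$year <- coerce_integer(df$year, "year")
  df$hatchlings <- coerce_integer(df$hatchlings, "hatchlings")
  if (any(df$hatchlings < 0)) abort("hatchling counts must be non-negative")
  df <- dplyr::arrange(df, .data$year)
  if (anyDuplicated(df$year)) abort("duplicated year in hatchling table")
  check_years_contiguous(df$year, "hatchling")
  tibble::as_tibble(df[, c("year", "hatchlings")])
}

#' Read a daily regional-mean SST series
#'
#' Expects columns `date` (ISO-8601), `sst` (deg C, regional daily mean) and
#' `sst_err_sd` (deg C, per-day measurement SD). Rows are returned sorted by
#' date; duplicate dates and non-positive error SDs are hard errors. Missing
#' days are tolerated here — window statistics fail loudly later if a
#' requested window is incomplete (silent imputation could bias minima).
#'
#' @inheritParams read_strandings
#' @return A tibble with columns `date` (Date), `sst`, `sst_err_sd`.
#' @export
read_daily_sst <- function(path) {
  df <- read_named_csv(path, c("date", "sst", "sst_err_sd"))
  df$date <- as.Date(df$date)
  if (any(is.na(df$date))) abort("unparseable date in SST table")
  df$sst <- as.numeric(df$sst)
  df$sst_err_sd <- as.numeric(df$sst_err_sd)
  if (any(is.na(df$sst)) || any(is.na(df$sst_err_sd))) {
    abort("non-numeric sst or sst_err_sd value")
  }
  if (any(df$sst_err_sd <= 0)) abort("sst_err_sd must be strictly positive")
  df <- dplyr::arrange(df, .data$date)
  if (anyDuplicated(df$date)) abort("duplicate date in SST table")
  tibble::as_tibble(df[, c("date", "sst", "sst_err_sd")])
}

#' Read a monthly climate-index table (NAO, AMO, ...)
#'
#' Expects columns `year`, `month` (1-12) and `value` (dimensionless index).
#'
#' @inheritParams read_strandings
#' @return A tibble with columns `year`, `month`, `value`.
#' @export
read_monthly_index <- function(path) {
  df <- read_named_csv(path, c("year", "month", "value"))
  df$year <- coerce_integer(df$year, "year")
  df$month <- coerce_integer(df$month, "month")
  df$value <- as.numeric(df$value)
  if (any(is.na(df$value))) abort("non-numeric index value")
  if (any(df$month < 1 | df$month > 12)) abort("month outside 1..12")
  if (anyDuplicated(df[, c("year", "month")])) {
    abort("duplicate (year, month) in index table")
  }
  df <- dplyr::arrange(df, .data$year, .data$month)
  tibble::as_tibble(df[, c("year", "month", "value")])
}

#' Write a pipeline table as CSV
#'
#' Thin wrapper around [readr::write_csv()] so round-tripping through
#' the readers reproduces integer fields exactly and decimals to full
#' printed precision.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

## ---- internal helpers -----------------------------------------------------

read_named_csv <- function(path, required) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) abort(paste0("empty table: ", path))
  names(df) <- tolower(names(df))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  df
}

coerce_integer <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  if (any(is.na(out)) || any(out != round(out))) {
    abort(paste0("non-integer ", what, " value"))
  }
  as.integer(out)
}

check_years_contiguous <- function(years, what) {
  if (anyDuplicated(years)) abort(paste0("duplicated year in ", what, " table"))
  if (length(years) > 1 && any(diff(years) != 1L)) {
    abort(paste0("gap in ", what, " years: series must be contiguous"))
  }
  invisible(years)
}
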