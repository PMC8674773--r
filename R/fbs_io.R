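#' Convert annual per capita supply to daily grams
#'
#' Food balance sheets report per capita supply in kg/year; all vitamin D
#' arithmetic downstream is in g/day. The year length is 365 days by
#' default; leap-day handling is not attempted.
#'
#' @param kg_per_year Non-negative numeric vector, kg/capita/year.
#' @param days_per_year Days used for the conversion (default 365).
#' @return Numeric vector in g/capita/day.
#' @examples
#' annual_to_daily(36.5) # 100 g/d
#' @export
annual_to_daily <- function(kg_per_year, days_per_year = 365) {
  assert_scalar_number(days_per_year, "days_per_year", min = 1)
  if (!is.numeric(kg_per_year)) {
    abort("`kg_per_year` must be numeric.", class = "vitd_validation_error")
  }
  bad <- which(!is.na(kg_per_year) & kg_per_year < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative supply quantity at position(s): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "vitd_validation_error")
  }
  kg_per_year * 1000 / days_per_year
}

#' Construct a supply table
#'
#' A supply table is a tibble of per-country, per-year, per-commodity daily
#' supplies (g/capita/day) with the source dialect ("old_fbs" for sheets up
#' to 2013, "new_fbs" from 2014 on) recorded as an attribute rather than
#' inferred.
#'
#' @param records Data frame with columns `country_code`, `country_name`,
#'   `year`, `commodity_code`, `commodity_name`, `g_per_day`.
#' @param dialect One of `"old_fbs"`, `"new_fbs"`.
#' @param provenance Free-text source description (e.g. a file path).
#' @return A `supply_table` (tibble subclass).
#' @export
supply_table <- function(records, dialect = c("old_fbs", "new_fbs"),
                         provenance = NA_character_) {
  dialect <- match.arg(dialect)
  cols <- c("country_code", "country_name", "year", "commodity_code",
            "commodity_name", "g_per_day")
  assert_has_columns(records, cols, "supply table")
  records <- tibble::as_tibble(records)[cols]
  if (any(!is.na(records$g_per_day) & records$g_per_day < 0)) {
    abort("supply table contains negative g_per_day values.",
          class = "vitd_validation_error")
  }
  key <- paste(records$country_code, records$year, records$commodity_code,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE]
    abort(sprintf(
      "duplicate (country, year, commodity) key(s), e.g. %s / %s / %s",
      dup$country_code[1], dup$year[1], dup$commodity_code[1]),
      class = "vitd_duplicate_key_error")
  }
  structure(records,
            class = c("supply_table", class(records)),
            dialect = dialect, provenance = provenance,
            unit = "g/capita/day")
}

#' @export
print.supply_table <- function(x, ...) {
  cat(sprintf("<supply_table> dialect=%s, %d records, unit=%s\n",
              attr(x, "dialect"), nrow(x), attr(x, "unit")))
  NextMethod()
}

fbs_element_label <- "Food supply quantity (kg/capita/yr)"

#' Read a FAOSTAT food-balance-sheet CSV
#'
#' Reads the FAOSTAT long-format export (columns `Area Code`, `Area`,
#' `Item Code`, `Item`, `Element`, `Year`, `Unit`, `Value`), keeps only the
#' food-supply-quantity rows, converts kg/year to g/day, and returns a
#' [supply_table()]. Every other element (production, imports, kcal/day,
#' ...) is dropped and counted; nothing is discarded silently.
#'
#' @param path Path to the CSV file (UTF-8, "." decimal separator).
#' @param dialect `"old_fbs"` (1961-2013 methodology) or `"new_fbs"`
#'   (2014+); recorded as metadata, never inferred from the data.
#' @param element Element label identifying food-supply-quantity rows.
#' @param days_per_year Year length used by [annual_to_daily()].
#' @param quiet Suppress the dropped-row message.
#' @return A `supply_table`; attribute `dropped_elements` is a named count
#'   of discarded element labels.
#' @export
read_fbs <- function(path, dialect = c("old_fbs", "new_fbs"),
                     element = fbs_element_label,
                     days_per_year = 365, quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("FBS file not found: %s", path), class = "vitd_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  assert_has_columns(raw, c("Area Code", "Area", "Item Code", "Item",
                            "Element", "Year", "Unit", "Value"),
                     sprintf("FBS file '%s'", path))
  keep <- raw$Element == element
  dropped <- table(raw$Element[!keep])
  raw <- raw[keep, , drop = FALSE]
  if (any(grepl(",", raw$Value, fixed = TRUE))) {
    abort("FBS values contain thousands separators; expected plain '.' decimals.",
          class = "vitd_format_error")
  }
  value <- suppressWarnings(as.numeric(raw$Value))
  if (any(is.na(value) & !is.na(raw$Value) & raw$Value != "")) {
    abort("non-numeric supply value(s) in FBS file.",
          class = "vitd_format_error")
  }
  neg <- which(value < 0)
  if (length(neg) > 0) {
    abort(sprintf("negative supply value at data row(s): %s",
                  paste(head(which(keep)[neg], 5), collapse = ", ")),
          class = "vitd_validation_error")
  }
  year <- as.integer(raw$Year)
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  if (any(!is.na(year) & (year < 1961 | year > this_year))) {
    abort("FBS year outside the plausible range [1961, current].",
          class = "vitd_validation_error")
  }
  out <- supply_table(
    tibble::tibble(
      country_code = raw$`Area Code`,
      country_name = raw$Area,
      year = year,
      commodity_code = raw$`Item Code`,
      commodity_name = raw$Item,
      g_per_day = annual_to_daily(value, days_per_year)),
    dialect = dialect, provenance = path)
  attr(out, "dropped_elements") <- dropped
  if (!quiet) {
    inform(sprintf("read_fbs: kept %d food-supply rows, dropped %d other-element rows from %s",
                   nrow(out), sum(dropped), basename(path)))
  }
  out
}

#' Write a supply table back to the FAOSTAT CSV dialect
#'
#' Inverse of [read_fbs()]: emits the long-format FAOSTAT columns with
#' values re-expressed as kg/capita/year, so that
#' `read_fbs(write_fbs(x))` round-trips. Used by the synthetic generator.
#'
#' @param x A `supply_table`.
#' @param path Output CSV path.
#' @param days_per_year Year length (must match the reader's).
#' @return `path`, invisibly.
#' @export
write_fbs <- function(x, path, days_per_year = 365) {
  stopifnot(inherits(x, "supply_table"))
  out <- tibble::tibble(
    `Area Code` = x$country_code,
    Area = x$country_name,
    `Item Code` = x$commodity_code,
    Item = x$commodity_name,
    `Element Code` = "645",
    Element = fbs_element_label,
    Year = x$year,
    Unit = "kg",
    Value = x$g_per_day * days_per_year / 1000)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write the canonical tidy supply CSV
#'
#' @param x A `supply_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_supply_table <- function(x, path) {
  stopifnot(inherits(x, "supply_table"))
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
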