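#' Per-country, per-year vitamin D supply
#'
#' Sums, over all commodities a country supplies in a year, daily supply
#' (g/d) times the vitamin D content of the commodity's composition group
#' (ug/100 g). Commodities without a group mapping contribute zero and are
#' visible via [coverage_report()].
#'
#' @param table A `supply_table`.
#' @param country Country code present in `table`.
#' @param year Year present for that country.
#' @param composition Composition tibble (see [read_composition()]).
#' @param mapping Commodity mapping tibble (see [read_mapping()]).
#' @param opts [bioactivity_options()].
#' @return Scalar, ug vitamin D per capita per day.
#' @export
country_year_supply <- function(table, country, year, composition, mapping,
                                opts = bioactivity_options()) {
  rows <- table[table$country_code == country & table$year == year, ,
                drop = FALSE]
  if (nrow(rows) == 0) {
    abort(sprintf("no supply records for country '%s', year %s.",
                  country, year),
          class = "vitd_not_found_error")
  }
  sum(commodity_ug_day(rows, composition, mapping, opts))
}

# per-record ug/day contributions, aligned with `rows`
commodity_ug_day <- function(rows, composition, mapping, opts) {
  grp <- resolve_group(rows$commodity_code, mapping)
  content <- total_content(composition, opts)
  per100 <- content[match(grp, composition$group_id)]
  per100[is.na(per100)] <- 0
  rows$g_per_day * per100 / 100
}

#' Yearly supply for every country-year in a table
#'
#' @inheritParams country_year_supply
#' @return Tibble: `country_code`, `country_name`, `year`, `ug_per_day`.
#' @export
yearly_supply <- function(table, composition, mapping,
                          opts = bioactivity_options()) {
  contrib <- commodity_ug_day(table, composition, mapping, opts)
  tibble::as_tibble(table) |>
    dplyr::mutate(.ug = contrib) |>
    dplyr::group_by(.data$country_code, .data$country_name, .data$year) |>
    dplyr::summarise(ug_per_day = sum(.data$.ug), .groups = "drop")
}

#' Period mean and SD of yearly supply
#'
#' Aggregates yearly estimates to a period mean with the sample
#' (n - 1) standard deviation across years. Years missing inside the
#' period are tolerated (the mean runs over available years and `n_years`
#' records how many); a period with no overlapping years is an error. A
#' single year yields SD 0.
#'
#' @param yearly Named numeric vector (names = years) or a tibble with
#'   columns `year` and `ug_per_day`.
#' @param period Length-2 integer vector `c(start_year, end_year)`.
#' @return One-row tibble: `period_start`, `period_end`, `mean_ug_day`,
#'   `sd_ug_day`, `n_years`.
#' @examples
#' period_estimate(c("2014" = 3, "2015" = 5), c(2014, 2017))
#' @export
period_estimate <- function(yearly, period) {
  stopifnot(length(period) == 2, period[1] <= period[2])
  if (is.data.frame(yearly)) {
    assert_has_columns(yearly, c("year", "ug_per_day"), "yearly supply")
    vals <- setNames(yearly$ug_per_day, yearly$year)
  } else {
    stopifnot(is.numeric(yearly), !is.null(names(yearly)))
    vals <- yearly
  }
  yrs <- as.integer(names(vals))
  keep <- yrs >= period[1] & yrs <= period[2]
  if (!any(keep)) {
    abort(sprintf("no years overlap the period %d-%d.", period[1], period[2]),
          class = "vitd_not_found_error")
  }
  v <- vals[keep]
  tibble::tibble(period_start = as.integer(period[1]),
                 period_end = as.integer(period[2]),
                 mean_ug_day = mean(v),
                 sd_ug_day = if (length(v) > 1) sd(v) else 0,
                 n_years = length(v))
}

#' Period supply estimates for every country
#'
#' The main entry point of the estimation stage: computes yearly supplies
#' and aggregates them to one estimate per country for the requested
#' period.
#'
#' @inheritParams country_year_supply
#' @param period Length-2 integer vector `c(start_year, end_year)`.
#' @param include_fortification Logical flag recorded in the output (the
#'   fortification increment itself is applied by [apply_policies()]).
#' @return Tibble of supply estimates, one row per country, with
#'   `mean_ug_day`, `sd_ug_day`, `n_years`, `include_ohd`,
#'   `include_fortification`.
#' @export
supply_estimates <- function(table, period, composition, mapping,
                             opts = bioactivity_options(),
                             include_fortification = FALSE) {
  yearly_supply(table, composition, mapping, opts) |>
    dplyr::group_by(.data$country_code, .data$country_name) |>
    dplyr::reframe(period_estimate(
      setNames(.data$ug_per_day, .data$year), period)) |>
    dplyr::mutate(include_ohd = opts$include_ohd,
                  include_fortification = include_fortification)
}

#' Commodity-group contribution shares
#'
#' Shares of the period-mean supply attributable to each composition
#' group. Shares sum to one when the total is positive; a zero total
#' yields an empty breakdown flagged by `zero_total`.
#'
#' @inheritParams country_year_supply
#' @param period Length-2 integer vector.
#' @return Tibble `group_id`, `share` with attribute `zero_total`.
#' @export
contribution_shares <- function(table, country, period, composition, mapping,
                                opts = bioactivity_options()) {
  rows <- table[table$country_code == country &
                  table$year >= period[1] & table$year <= period[2], ,
                drop = FALSE]
  if (nrow(rows) == 0) {
    abort(sprintf("no supply records for country '%s' in %d-%d.",
                  country, period[1], period[2]),
          class = "vitd_not_found_error")
  }
  grp <- resolve_group(rows$commodity_code, mapping)
  contrib <- commodity_ug_day(rows, composition, mapping, opts)
  by_group <- tapply(contrib, factor(ifelse(is.na(grp), "(unmapped)", grp)),
                     sum)
  total <- sum(by_group)
  if (total <= 0) {
    out <- tibble::tibble(group_id = character(), share = numeric())
    attr(out, "zero_total") <- TRUE
    return(out)
  }
  out <- tibble::tibble(group_id = names(by_group),
                        share = as.numeric(by_group) / total) |>
    dplyr::arrange(dplyr::desc(.data$share))
  attr(out, "zero_total") <- FALSE
  out
}

#' 25(OH)D increment of a country's period supply
#'
#' Difference between the period mean including bioactivity-adjusted
#' 25(OH)D3 and the period mean excluding it; non-negative by
#' construction.
#'
#' @inheritParams country_year_supply
#' @param period Length-2 integer vector.
#' @param bioactivity_factor Multiplier on 25(OH)D3 content (default 5).
#' @return Scalar increment, ug/day.
#' @export
ohd_increment <- function(table, country, period, composition, mapping,
                          bioactivity_factor = 5) {
  one <- function(include) {
    opts <- bioactivity_options(include, bioactivity_factor)
    ys <- yearly_supply(
      table[table$country_code == country, , drop = FALSE],
      composition, mapping, opts)
    period_estimate(setNames(ys$ug_per_day, ys$year), period)$mean_ug_day
  }
  one(TRUE) - one(FALSE)
}
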