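#' Packaged reference country supply estimates
#'
#' A transcription of published per capita vitamin D supply estimates
#' (mean and SD, ug/day, 1-decimal precision) for 178 countries and
#' territories over the 2004-2013 ("old") and 2014-2017 ("new")
#' food-balance-sheet periods, with and without the bioactivity-adjusted
#' 25(OH)D contribution. Territories without new-sheet data carry `NA`
#' for 2014-2017 (173 countries have values there). Used as reference
#' data for banding, extremes and increment summaries.
#'
#' @param period `"2004_2013"` or `"2014_2017"`.
#' @param estimate `"less_ohd"` (vitamin D3 only) or `"total"`
#'   (including bioactivity-adjusted 25(OH)D3).
#' @return Tibble: `country`, `mean_ug_day`, `sd_ug_day`; countries
#'   lacking the period are dropped.
#' @export
reference_estimates <- function(period = c("2004_2013", "2014_2017"),
                                estimate = c("less_ohd", "total")) {
  period <- match.arg(period)
  estimate <- match.arg(estimate)
  wide <- reference_estimates_wide()
  prefix <- if (estimate == "less_ohd") "less_ohd" else "total"
  mean_col <- sprintf("mean_%s_%s", prefix, period)
  sd_col <- sprintf("sd_%s_%s", prefix, period)
  out <- tibble::tibble(country = wide$country,
                        mean_ug_day = wide[[mean_col]],
                        sd_ug_day = wide[[sd_col]])
  out[!is.na(out$mean_ug_day), , drop = FALSE]
}

#' @rdname reference_estimates
#' @export
reference_estimates_wide <- function() {
  readr::read_csv(vitd_example_file("global_supply_estimates.csv"),
                  col_types = readr::cols(
                    country = readr::col_character(),
                    .default = readr::col_double()),
                  progress = FALSE)
}

#' Packaged fortified-country reference estimates
#'
#' Supply estimates (2014-2017, ug/day) for the eight countries where
#' vitamin D fortification of a staple vehicle is common -- milk and
#' dairy in Finland, the United States, Canada and Sweden; wheat flour in
#' Jordan, Kuwait, the United Arab Emirates and Saudi Arabia -- from
#' natural foods only and including fortified foods, each with and
#' without bioactivity-adjusted 25(OH)D.
#'
#' @return Tibble, one row per country, columns
#'   `country`, `vehicle`, `region_group`, and mean/SD pairs for the four
#'   estimate variants.
#' @export
reference_fortified_estimates <- function() {
  readr::read_csv(vitd_example_file("fortified_country_estimates.csv"),
                  col_types = readr::cols(
                    country = readr::col_character(),
                    vehicle = readr::col_character(),
                    region_group = readr::col_character(),
                    .default = readr::col_double()),
                  progress = FALSE)
}
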