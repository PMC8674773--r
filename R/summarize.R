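#' The six-band supply classification scheme
#'
#' Countries are classified on their supply estimate rounded half-up to
#' one decimal, into six bands that tile the non-negative 1-decimal grid
#' with no gaps: up to 1.5, 1.6-3.0, 3.1-5.5, 5.6-7.5, 7.6-10.0, and
#' above 10 ug/d. Reading the bottom band as inclusive of 1.5 is what
#' makes the tiling gap-free at the printed precision.
#'
#' @return A `band_scheme` object: tibble of band labels with closed
#'   bounds in tenths of a ug/d.
#' @export
supply_band_scheme <- function() {
  structure(tibble::tibble(
    label = c("<=1.5", "1.6-3.0", "3.1-5.5", "5.6-7.5", "7.6-10.0", ">10.0"),
    lo_tenths = c(0L, 16L, 31L, 56L, 76L, 101L),
    hi_tenths = c(15L, 30L, 55L, 75L, 100L, .Machine$integer.max)),
    class = c("band_scheme", "tbl_df", "tbl", "data.frame"))
}

#' Classify supply estimates into bands
#'
#' @param mean_ug_day Non-negative numeric vector of supply means, ug/day.
#' @param scheme A [supply_band_scheme()].
#' @return Ordered factor of band labels (one level per band, low to
#'   high).
#' @examples
#' classify_band(c(13.3, 7.5, 1.55, 1.54))
#' @export
classify_band <- function(mean_ug_day, scheme = supply_band_scheme()) {
  stopifnot(inherits(scheme, "band_scheme"))
  if (any(mean_ug_day < 0, na.rm = TRUE)) {
    abort("supply means must be >= 0.", class = "vitd_validation_error")
  }
  tenths <- as.integer(round_half_up(mean_ug_day, 1) * 10 + 0.5)
  idx <- findInterval(tenths, scheme$lo_tenths)
  factor(scheme$label[idx], levels = scheme$label, ordered = TRUE)
}

#' Count countries per supply band
#'
#' @param estimates Tibble with one row per country and columns
#'   `country_code` (or `country`) and `mean_ug_day`.
#' @param scheme A [supply_band_scheme()].
#' @return Named integer vector, one count per band (zeros kept); counts
#'   sum to the number of countries.
#' @export
band_counts <- function(estimates, scheme = supply_band_scheme()) {
  key <- estimates[[intersect(c("country_code", "country"),
                              names(estimates))[1]]]
  if (anyDuplicated(key)) {
    abort("band_counts expects one estimate per country.",
          class = "vitd_validation_error")
  }
  table(classify_band(estimates$mean_ug_day, scheme))
}

#' Countries with the lowest and highest supply
#'
#' @param estimates Tibble with columns `country_code`/`country` and
#'   `mean_ug_day`; must be non-empty.
#' @return List with elements `min` and `max`, each a tibble of the
#'   tying countries (more than one row when tied) and their value.
#' @export
extremes <- function(estimates) {
  if (nrow(estimates) == 0) {
    abort("cannot take extremes of an empty estimate table.",
          class = "vitd_validation_error")
  }
  key <- intersect(c("country_code", "country"), names(estimates))[1]
  pick <- function(v) tibble::tibble(
    country = estimates[[key]][estimates$mean_ug_day == v],
    mean_ug_day = v)
  list(min = pick(min(estimates$mean_ug_day)),
       max = pick(max(estimates$mean_ug_day)))
}

#' Read a country-to-region map
#'
#' The package ships a continental (UN M49-style) assignment of the
#' reference countries to Africa, Americas, Asia, Europe and Oceania;
#' special administrative regions and former countries are kept as
#' separate entries.
#'
#' @param path CSV with columns `country`, `region`; defaults to the
#'   packaged map.
#' @return Tibble `country`, `region`.
#' @export
read_region_map <- function(path = vitd_example_file("country_regions.csv")) {
  map <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  assert_has_columns(map, c("country", "region"), "region map")
  if (anyDuplicated(map$country)) {
    abort("a country appears in more than one region.",
          class = "vitd_config_error")
  }
  map
}

#' Regional median and quartile summaries
#'
#' @param estimates Tibble with `country_code`/`country` and
#'   `mean_ug_day`.
#' @param region_map Tibble `country`, `region` (see
#'   [read_region_map()]). Countries without a region are excluded with a
#'   warning.
#' @param type Quantile interpolation type passed to [stats::quantile()]
#'   (default 7, R's linear interpolation).
#' @return Tibble: `region`, `n_countries`, `q25`, `median`, `q75`.
#' @export
region_summary <- function(estimates, region_map = read_region_map(),
                           type = 7) {
  key <- intersect(c("country_code", "country"), names(estimates))[1]
  reg <- region_map$region[match(estimates[[key]], region_map$country)]
  if (any(is.na(reg))) {
    warn(sprintf("%d countr%s without a region assignment excluded: %s",
                 sum(is.na(reg)), if (sum(is.na(reg)) == 1) "y" else "ies",
                 paste(head(estimates[[key]][is.na(reg)], 5),
                       collapse = ", ")))
  }
  tibble::tibble(region = reg, mean_ug_day = estimates$mean_ug_day) |>
    dplyr::filter(!is.na(.data$region)) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_countries = dplyr::n(),
      q25 = quantile(.data$mean_ug_day, 0.25, type = type, names = FALSE),
      median = quantile(.data$mean_ug_day, 0.50, type = type, names = FALSE),
      q75 = quantile(.data$mean_ug_day, 0.75, type = type, names = FALSE),
      .groups = "drop")
}

#' Between-period change in supply estimates
#'
#' Joins two estimate tables on country, takes the difference (second
#' minus first), and classifies its magnitude into the `<0.5`,
#' `0.5-0.99`, `>=1.0` ug/d change categories. Countries present in only
#' one period are returned separately.
#'
#' @param estimates_a,estimates_b Tibbles with `country_code`/`country`
#'   and `mean_ug_day` for the earlier and later period.
#' @return List: `deltas` (tibble `country`, `delta_ug_day`,
#'   `change_class`) and `unmatched` (countries missing a period).
#' @export
period_delta <- function(estimates_a, estimates_b) {
  ka <- intersect(c("country_code", "country"), names(estimates_a))[1]
  kb <- intersect(c("country_code", "country"), names(estimates_b))[1]
  a <- tibble::tibble(country = estimates_a[[ka]],
                      mean_a = estimates_a$mean_ug_day)
  b <- tibble::tibble(country = estimates_b[[kb]],
                      mean_b = estimates_b$mean_ug_day)
  joined <- dplyr::inner_join(a, b, by = "country")
  delta <- joined$mean_b - joined$mean_a
  cls <- cut(abs(delta), breaks = c(-Inf, 0.5 - 1e-9, 1.0 - 1e-9, Inf),
             labels = c("<0.5", "0.5-0.99", ">=1.0"))
  list(deltas = tibble::tibble(country = joined$country,
                               delta_ug_day = delta,
                               change_class = cls),
       unmatched = sort(union(setdiff(a$country, b$country),
                              setdiff(b$country, a$country))))
}
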