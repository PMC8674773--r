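#' Daily vitamin D increment from flour fortification
#'
#' @param vehicle_g_day Per capita flour supply, g/day.
#' @param level_ug_kg Fortification level, ug vitamin D per kg flour.
#' @param coverage Fraction of the vehicle supply actually fortified,
#'   in \[0, 1\].
#' @return Increment in ug/day: `vehicle_g_day * coverage * level_ug_kg /
#'   1000`.
#' @examples
#' flour_increment(300, 10, 1)   # 3 ug/d
#' @export
flour_increment <- function(vehicle_g_day, level_ug_kg, coverage) {
  stopifnot(all(vehicle_g_day >= 0), all(level_ug_kg >= 0))
  assert_fraction(coverage, "coverage")
  vehicle_g_day * coverage * level_ug_kg / 1000
}

#' Daily vitamin D increment from fluid-milk fortification
#'
#' Food balance sheets report milk in its unprocessed form; only the share
#' consumed as the fortified fluid products (milk, and where policy covers
#' them, yoghurt/sourmilk) carries the added vitamin D, so the supply is
#' scaled by `product_share` before the per-litre level is applied.
#'
#' @param milk_g_day Per capita milk supply, g/day.
#' @param level_ug_L Fortification level, ug per litre.
#' @param coverage Fraction of the product supply fortified, in \[0, 1\].
#' @param product_share Share of overall milk supply consumed as the
#'   fortified products, in \[0, 1\].
#' @param density_g_ml Milk density used for the g-to-litre conversion
#'   (default 1.0 g/mL).
#' @return Increment in ug/day.
#' @examples
#' milk_increment(500, 10, 1, 0.6)   # 3 ug/d
#' @export
milk_increment <- function(milk_g_day, level_ug_L, coverage, product_share,
                           density_g_ml = 1.0) {
  stopifnot(all(milk_g_day >= 0), all(level_ug_L >= 0))
  assert_fraction(coverage, "coverage")
  assert_fraction(product_share, "product_share")
  assert_scalar_number(density_g_ml, "density_g_ml")
  if (density_g_ml <= 0) {
    abort("`density_g_ml` must be > 0.", class = "vitd_validation_error")
  }
  (milk_g_day / (density_g_ml * 1000)) * product_share * coverage * level_ug_L
}

policy_vehicles <- c("wheat_flour", "maize_flour", "milk", "oil")

#' Read a fortification policy table
#'
#' CSV schema: `country_code, vehicle, level, level_unit, coverage,
#' start_year, basis, milk_product_share`. `vehicle` is one of
#' `wheat_flour`, `maize_flour`, `milk` or `oil`; `level_unit` is
#' `ug_per_kg` (flours) or `ug_per_L` (milk); `basis` is `mandatory` or
#' `voluntary`. `milk_product_share` is required for milk policies and
#' ignored otherwise.
#'
#' @param path CSV path.
#' @return Validated policy tibble.
#' @export
read_policies <- function(path) {
  pol <- readr::read_csv(path, col_types = readr::cols(
    country_code = readr::col_character(),
    vehicle = readr::col_character(),
    level = readr::col_double(),
    level_unit = readr::col_character(),
    coverage = readr::col_double(),
    start_year = readr::col_integer(),
    basis = readr::col_character(),
    milk_product_share = readr::col_double()), progress = FALSE)
  validate_policies(pol)
}

validate_policies <- function(pol) {
  pol <- tibble::as_tibble(pol)
  assert_has_columns(pol, c("country_code", "vehicle", "level", "coverage",
                            "start_year", "basis"), "policy table")
  if (!"milk_product_share" %in% names(pol)) {
    pol$milk_product_share <- NA_real_
  }
  bad <- setdiff(unique(pol$vehicle), policy_vehicles)
  if (length(bad) > 0) {
    abort(sprintf("unknown fortification vehicle(s): %s",
                  paste(bad, collapse = ", ")),
          class = "vitd_config_error")
  }
  if (any(pol$level < 0) || any(pol$coverage < 0 | pol$coverage > 1)) {
    abort("policy levels must be >= 0 and coverage within [0, 1].",
          class = "vitd_validation_error")
  }
  need_share <- pol$vehicle == "milk"
  if (any(need_share & is.na(pol$milk_product_share))) {
    abort("milk policies require `milk_product_share`.",
          class = "vitd_config_error")
  }
  if (any(!is.na(pol$milk_product_share) &
            (pol$milk_product_share < 0 | pol$milk_product_share > 1))) {
    abort("`milk_product_share` must lie within [0, 1].",
          class = "vitd_validation_error")
  }
  if (!all(pol$basis %in% c("mandatory", "voluntary"))) {
    abort("policy basis must be 'mandatory' or 'voluntary'.",
          class = "vitd_config_error")
  }
  pol
}

default_vehicle_groups <- c(wheat_flour = "wheat", maize_flour = "maize",
                            milk = "milk", oil = "vegetable_oils")

#' Apply fortification policies to a baseline yearly supply
#'
#' For every year at or after a policy's `start_year`, adds the policy's
#' increment to the country's natural-food baseline; earlier years are
#' unchanged. The whole calendar year of `start_year` is treated as
#' fortified. Increments from multiple policies are additive, with no
#' interaction terms. Fortified oils are refused unless a cooking
#' retention factor is supplied explicitly, because vitamin D retention in
#' heated oil is too variable to default.
#'
#' @param baseline Tibble of yearly natural-food supplies
#'   (`country_code`, `year`, `ug_per_day`), as from [yearly_supply()].
#' @param policies Policy tibble (see [read_policies()]).
#' @param table The `supply_table` the baseline was computed from, used to
#'   look up vehicle supplies.
#' @param mapping Commodity mapping tibble.
#' @param vehicle_groups Named character vector, policy vehicle ->
#'   composition group id.
#' @param density_g_ml Milk density for [milk_increment()].
#' @param oil_retention `NULL` (refuse oil policies) or a retention
#'   fraction in \[0, 1\] applied to the oil increment.
#' @return `baseline` with added columns `increment_ug_day`,
#'   `fortified_ug_day` and `basis` (comma-joined bases of the policies
#'   active for that country, `NA` when none).
#' @export
apply_policies <- function(baseline, policies, table, mapping,
                           vehicle_groups = default_vehicle_groups,
                           density_g_ml = 1.0, oil_retention = NULL) {
  assert_has_columns(baseline, c("country_code", "year", "ug_per_day"),
                     "baseline supply")
  policies <- validate_policies(policies)
  if (any(policies$vehicle == "oil")) {
    if (is.null(oil_retention)) {
      abort(paste("oil fortification requires an explicit `oil_retention`",
                  "factor; heated-oil vitamin D retention cannot be assumed."),
            class = "vitd_config_error")
    }
    assert_fraction(oil_retention, "oil_retention")
  }
  out <- tibble::as_tibble(baseline)
  out$increment_ug_day <- 0
  out$basis <- NA_character_
  for (i in seq_len(nrow(policies))) {
    p <- policies[i, ]
    rows <- which(out$country_code == p$country_code)
    if (length(rows) == 0) {
      warn(sprintf("policy for '%s' skipped: country absent from the table.",
                   p$country_code))
      next
    }
    group <- vehicle_groups[[p$vehicle]]
    codes <- mapping$commodity_code[mapping$group_id == group]
    for (r in rows) {
      if (out$year[r] < p$start_year) next
      veh <- table[table$country_code == p$country_code &
                     table$year == out$year[r] &
                     table$commodity_code %in% codes, , drop = FALSE]
      g_day <- sum(veh$g_per_day)
      inc <- switch(p$vehicle,
        wheat_flour = ,
        maize_flour = flour_increment(g_day, p$level, p$coverage),
        milk = milk_increment(g_day, p$level, p$coverage,
                              p$milk_product_share, density_g_ml),
        oil = oil_retention * flour_increment(g_day, p$level, p$coverage))
      out$increment_ug_day[r] <- out$increment_ug_day[r] + inc
      out$basis[r] <- if (is.na(out$basis[r])) p$basis else
        paste(sort(unique(c(strsplit(out$basis[r], ",")[[1]], p$basis))),
              collapse = ",")
    }
  }
  out$fortified_ug_day <- out$ug_per_day + out$increment_ug_day
  out
}
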