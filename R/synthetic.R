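#' Configuration for the synthetic food-balance-sheet generator
#'
#' Describes a small world of countries whose per-commodity supplies are
#' known exactly, so every pipeline stage can be validated against ground
#' truth without any external download. Each country-year supply of a
#' commodity is its profile mean times an independent normal multiplier
#' `N(1, cv)` truncated at zero (truncations are counted); `cv = 0` gives
#' identical years. Defaults sketch a mid-supply diet (staple cereals and
#' milk dominating mass, fish dominating vitamin D).
#'
#' @param n_countries Number of countries to simulate.
#' @param years Integer vector of years.
#' @param commodity_profile Tibble `group_id`, `mean_g_day`, `cv` --
#'   one commodity is generated per composition group listed.
#' @param composition Composition tibble; defaults to the packaged
#'   illustrative table.
#' @param policies Fortification policy tibble (may be empty).
#' @param seed Integer seed; all generation is deterministic given it.
#' @param survey_bias,survey_noise Planted mean offset and SD (ug/day) of
#'   FBS-vs-survey differences for [generate_survey_pairs()].
#' @param n_pairs Number of survey pairs to generate.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_countries = 5,
                             years = 2014:2017,
                             commodity_profile = default_commodity_profile(),
                             composition =
                               read_composition(vitd_example_file("composition_example.csv")),
                             policies = NULL,
                             seed = 1353,
                             survey_bias = 0.5,
                             survey_noise = 0.5,
                             n_pairs = 10) {
  assert_scalar_number(n_countries, "n_countries", min = 1)
  assert_scalar_number(seed, "seed")
  stopifnot(is.numeric(years), length(years) >= 1)
  assert_has_columns(commodity_profile, c("group_id", "mean_g_day", "cv"),
                     "commodity profile")
  if (any(commodity_profile$mean_g_day < 0) || any(commodity_profile$cv < 0)) {
    abort("profile means and CVs must be >= 0.",
          class = "vitd_validation_error")
  }
  missing <- setdiff(commodity_profile$group_id, composition$group_id)
  if (length(missing) > 0) {
    abort(sprintf("profile group(s) absent from composition table: %s",
                  paste(missing, collapse = ", ")),
          class = "vitd_config_error")
  }
  structure(list(n_countries = as.integer(n_countries),
                 years = as.integer(years),
                 commodity_profile = tibble::as_tibble(commodity_profile),
                 composition = composition,
                 policies = policies,
                 seed = as.integer(seed),
                 survey_bias = survey_bias,
                 survey_noise = survey_noise,
                 n_pairs = as.integer(n_pairs)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_commodity_profile <- function() {
  tibble::tribble(
    ~group_id,        ~mean_g_day, ~cv,
    "pelagic_fish",    25,          0.15,
    "demersal_fish",   15,          0.15,
    "freshwater_fish", 10,          0.20,
    "eggs",            25,          0.10,
    "bovine_meat",     40,          0.10,
    "poultry_meat",    50,          0.10,
    "butter",           8,          0.10,
    "milk",           250,          0.05,
    "wheat",          300,          0.05,
    "maize",           50,          0.10,
    "rice",           100,          0.05,
    "vegetable_oils",  30,          0.10,
    "vegetables",     250,          0.05,
    "fruits",         150,          0.10)
}

#' Generate a synthetic food-balance-sheet file with known ground truth
#'
#' Writes a FAOSTAT-dialect CSV readable by [read_fbs()] and returns the
#' exact per-country-year vitamin D supply it implies. The ground truth
#' is computed by a plain per-record loop inside the generator --
#' deliberately not by the estimation pipeline -- so pipeline results can
#' be compared against an independent calculation.
#'
#' @param config A [synthetic_config()].
#' @param path Output CSV path.
#' @param bioactivity_factor Factor used in the ground-truth total-vitamin-D
#'   column (default 5).
#' @return List: `path`, `table` (the generated `supply_table`),
#'   `mapping`, `composition`, and `truth` -- a tibble with
#'   `country_code`, `year`, `ug_total`, `ug_less_ohd`,
#'   `fortified_total`, `fortified_less_ohd`; attribute `n_truncated`
#'   counts zero-truncated draws.
#' @export
generate_fbs <- function(config, path = tempfile(fileext = ".csv"),
                         bioactivity_factor = 5) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  prof <- config$commodity_profile
  countries <- sprintf("SY%02d", seq_len(config$n_countries))
  mapping <- tibble::tibble(
    commodity_code = sprintf("C%03d", seq_len(nrow(prof))),
    commodity_name = prof$group_id,
    group_id = prof$group_id)

  grid <- expand.grid(ci = seq_len(config$n_countries),
                      yi = seq_along(config$years),
                      ki = seq_len(nrow(prof)))
  mult <- rnorm(nrow(grid), mean = 1, sd = prof$cv[grid$ki])
  n_truncated <- sum(mult < 0)
  mult <- pmax(mult, 0)
  records <- tibble::tibble(
    country_code = countries[grid$ci],
    country_name = paste("Synthetic country", grid$ci),
    year = config$years[grid$yi],
    commodity_code = mapping$commodity_code[grid$ki],
    commodity_name = mapping$commodity_name[grid$ki],
    g_per_day = prof$mean_g_day[grid$ki] * mult)
  table <- supply_table(records, dialect = "new_fbs",
                        provenance = "synthetic")
  write_fbs(table, path)

  # independent ground-truth accumulation, one record at a time
  comp <- config$composition
  truth <- expand.grid(country_code = countries, year = config$years,
                       stringsAsFactors = FALSE)
  truth$ug_total <- 0
  truth$ug_less_ohd <- 0
  for (i in seq_len(nrow(records))) {
    j <- which(truth$country_code == records$country_code[i] &
                 truth$year == records$year[i])
    k <- which(comp$group_id ==
                 mapping$group_id[mapping$commodity_code ==
                                    records$commodity_code[i]])
    if (length(k) == 0) next
    g <- records$g_per_day[i]
    truth$ug_less_ohd[j] <- truth$ug_less_ohd[j] +
      g * comp$vitd3_ug_per_100g[k] / 100
    truth$ug_total[j] <- truth$ug_total[j] +
      g * (comp$vitd3_ug_per_100g[k] +
             bioactivity_factor * comp$ohd3_ug_per_100g[k]) / 100
  }
  truth$fortified_total <- truth$ug_total
  truth$fortified_less_ohd <- truth$ug_less_ohd
  if (!is.null(config$policies) && nrow(config$policies) > 0) {
    pol <- validate_policies(config$policies)
    for (i in seq_len(nrow(pol))) {
      p <- pol[i, ]
      group <- default_vehicle_groups[[p$vehicle]]
      code <- mapping$commodity_code[mapping$group_id == group]
      for (j in which(truth$country_code == p$country_code &
                        truth$year >= p$start_year)) {
        g <- sum(records$g_per_day[records$country_code == truth$country_code[j] &
                                     records$year == truth$year[j] &
                                     records$commodity_code %in% code])
        inc <- if (p$vehicle == "milk") {
          (g / 1000) * p$milk_product_share * p$coverage * p$level
        } else {
          g * p$coverage * p$level / 1000
        }
        truth$fortified_total[j] <- truth$fortified_total[j] + inc
        truth$fortified_less_ohd[j] <- truth$fortified_less_ohd[j] + inc
      }
    }
  }
  truth <- tibble::as_tibble(truth)
  attr(truth, "n_truncated") <- n_truncated
  list(path = path, table = table, mapping = mapping,
       composition = comp, truth = truth)
}

#' Generate paired survey-intake / FBS-supply data with a planted bias
#'
#' Survey intakes are drawn uniformly on 1-6 ug/day (the order of
#' magnitude of national survey means); the matching supply estimate is
#' the intake plus `survey_bias` plus `N(0, survey_noise)`, truncated at
#' zero.
#'
#' @param config A [synthetic_config()].
#' @param path Optional CSV output path (written when non-`NULL`).
#' @return Tibble of pairs in the [read_pairs()] schema, with attributes
#'   `true_bias` and `true_noise`.
#' @export
generate_survey_pairs <- function(config, path = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  n <- config$n_pairs
  survey <- stats::runif(n, 1, 6)
  fbs <- pmax(survey + config$survey_bias + rnorm(n, 0, config$survey_noise),
              0)
  pairs <- tibble::tibble(
    country_code = sprintf("SY%02d", seq_len(n)),
    survey_years = "2014-2017",
    survey_intake_ug_day = survey,
    fbs_supply_ug_day = fbs,
    ohd_convention = "less_ohd")
  if (!is.null(path)) readr::write_csv(pairs, path, progress = FALSE)
  attr(pairs, "true_bias") <- config$survey_bias
  attr(pairs, "true_noise") <- config$survey_noise
  pairs
}
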