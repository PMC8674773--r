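#' Read paired survey-intake / FBS-supply estimates
#'
#' CSV schema: `country_code, survey_years, survey_intake_ug_day,
#' fbs_supply_ug_day, ohd_convention`. Each pair should match the supply
#' estimate to the survey's year range and its 25(OH)D inclusion
#' convention; intakes are from food sources only (no supplements), since
#' the balance-sheet approach cannot capture supplemental vitamin D.
#'
#' @param path CSV path.
#' @return Tibble of paired estimates.
#' @export
read_pairs <- function(path) {
  pairs <- readr::read_csv(path, col_types = readr::cols(
    country_code = readr::col_character(),
    survey_years = readr::col_character(),
    survey_intake_ug_day = readr::col_double(),
    fbs_supply_ug_day = readr::col_double(),
    ohd_convention = readr::col_character()), progress = FALSE)
  assert_has_columns(pairs, c("survey_intake_ug_day", "fbs_supply_ug_day"),
                     sprintf("pairs file '%s'", path))
  if (any(pairs$survey_intake_ug_day < 0) || any(pairs$fbs_supply_ug_day < 0)) {
    abort("paired estimates must be >= 0.", class = "vitd_validation_error")
  }
  pairs
}

#' Bland-Altman agreement between supply and intake estimates
#'
#' Computes the mean difference (bias, supply minus intake), its sample
#' SD, the 95% limits of agreement (bias +/- 1.96 SD), the range of
#' per-country differences, and a proportional-bias p value from the
#' ordinary least-squares regression of differences on pair means. With
#' all differences identical the regression is degenerate and the p value
#' is `NA`.
#'
#' @param pairs Tibble with columns `survey_intake_ug_day` and
#'   `fbs_supply_ug_day` (see [read_pairs()]); at least 3 pairs.
#' @return A one-row tibble: `n`, `bias`, `bias_sd`, `loa_low`,
#'   `loa_high`, `bias_min`, `bias_max`, `proportional_bias_p`.
#' @examples
#' pairs <- tibble::tibble(survey_intake_ug_day = c(2, 4, 6),
#'                         fbs_supply_ug_day = c(3, 5, 7))
#' bland_altman(pairs)
#' @export
bland_altman <- function(pairs) {
  assert_has_columns(pairs, c("survey_intake_ug_day", "fbs_supply_ug_day"),
                     "paired estimates")
  n <- nrow(pairs)
  if (n < 3) {
    abort("Bland-Altman analysis needs at least 3 pairs.",
          class = "vitd_validation_error")
  }
  d <- pairs$fbs_supply_ug_day - pairs$survey_intake_ug_day
  m <- (pairs$fbs_supply_ug_day + pairs$survey_intake_ug_day) / 2
  bias <- mean(d)
  bias_sd <- sd(d)
  p <- if (isTRUE(all.equal(sd(d), 0)) || isTRUE(all.equal(sd(m), 0))) {
    NA_real_
  } else {
    summary(lm(d ~ m))$coefficients["m", "Pr(>|t|)"]
  }
  tibble::tibble(n = n, bias = bias, bias_sd = bias_sd,
                 loa_low = bias - 1.96 * bias_sd,
                 loa_high = bias + 1.96 * bias_sd,
                 bias_min = min(d), bias_max = max(d),
                 proportional_bias_p = p)
}
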