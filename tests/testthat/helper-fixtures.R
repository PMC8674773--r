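# Small in-code fixtures shared across test files.

tiny_composition <- function() {
  tibble::tibble(
    group_id = c("pelagic_fish", "eggs", "wheat", "milk"),
    group_name = group_id,
    vitd3_ug_per_100g = c(8.0, 3.0, 0.0, 0.03),
    ohd3_ug_per_100g = c(0.0, 0.2, 0.0, 0.01),
    source = "test")
}

tiny_mapping <- function() {
  tibble::tibble(
    commodity_code = c("F1", "E1", "W1", "M1"),
    commodity_name = c("Pelagic Fish", "Eggs", "Wheat and products",
                       "Milk - Excluding Butter"),
    group_id = c("pelagic_fish", "eggs", "wheat", "milk"))
}

# one country, one year: 50 g/d fish, 30 g/d eggs, 200 g/d wheat
tiny_table <- function(years = 2015L, country = "AAA") {
  grid <- expand.grid(code = c("F1", "E1", "W1"), year = years,
                      stringsAsFactors = FALSE)
  g <- c(F1 = 50, E1 = 30, W1 = 200)
  supply_table(tibble::tibble(
    country_code = country, country_name = "Testland",
    year = grid$year, commodity_code = grid$code,
    commodity_name = grid$code, g_per_day = g[grid$code]),
    dialect = "new_fbs")
}

# write a minimal FAOSTAT-dialect CSV and return its path
write_faostat_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path, progress = FALSE)
  path
}

faostat_row <- function(area = "Testland", code = "1", item = "Wheat",
                        item_code = "2511",
                        element = "Food supply quantity (kg/capita/yr)",
                        year = 2015, value = 36.5) {
  tibble::tibble(`Area Code` = code, Area = area, `Item Code` = item_code,
                 Item = item, `Element Code` = "645", Element = element,
                 Year = year, Unit = "kg", Value = value)
}
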