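test_that("flour and milk increments follow the level-times-coverage rule", {
  expect_equal(flour_increment(300, 10, 1), 3.0)
  expect_equal(flour_increment(250, 20, 0.5), 2.5)
  expect_equal(flour_increment(123, 17, 0), 0)
  expect_error(flour_increment(100, 10, 1.2), class = "vitd_validation_error")

  expect_equal(milk_increment(500, 10, 1, 0.6), 3.0)
  expect_equal(milk_increment(500, 10, 1, 0), 0)
  expect_equal(milk_increment(500, 10, 1, 0.6, density_g_ml = 1.03),
               (500 / 1030) * 0.6 * 10)
  expect_error(milk_increment(500, 10, 1.5, 0.6),
               class = "vitd_validation_error")
})

test_that("applying no policies is the identity", {
  tab <- tiny_table(years = 2014:2017)
  base <- yearly_supply(tab, tiny_composition(), tiny_mapping())
  out <- apply_policies(base, validate_policies(tibble::tibble(
    country_code = character(), vehicle = character(), level = numeric(),
    coverage = numeric(), start_year = integer(), basis = character())),
    tab, tiny_mapping())
  expect_equal(out$fortified_ug_day, base$ug_per_day)
  expect_true(all(out$increment_ug_day == 0))
})

test_that("policies gate on start year and add the per-vehicle increment", {
  tab <- tiny_table(years = 2014:2017)  # flat 200 g/d wheat
  base <- yearly_supply(tab, tiny_composition(), tiny_mapping())
  pol <- tibble::tibble(country_code = "AAA", vehicle = "wheat_flour",
                        level = 10, level_unit = "ug_per_kg", coverage = 1,
                        start_year = 2016L, basis = "mandatory",
                        milk_product_share = NA_real_)
  out <- apply_policies(base, pol, tab, tiny_mapping())
  out <- out[order(out$year), ]
  expect_equal(out$increment_ug_day, c(0, 0, 2, 2))
  expect_equal(out$fortified_ug_day, out$ug_per_day + c(0, 0, 2, 2))
  expect_equal(out$basis, c(NA, NA, "mandatory", "mandatory"))
  # fortified >= baseline always; equality iff no active policy
  expect_true(all(out$fortified_ug_day >= out$ug_per_day))
})

test_that("multi-vehicle increments are additive with no interaction", {
  tab <- tiny_table(years = 2014:2017)
  base <- yearly_supply(tab, tiny_composition(), tiny_mapping())
  wheat <- tibble::tibble(country_code = "AAA", vehicle = "wheat_flour",
                          level = 10, coverage = 1, start_year = 2014L,
                          basis = "mandatory",
                          milk_product_share = NA_real_)
  milk_tab <- supply_table(dplyr::bind_rows(
    tibble::as_tibble(tab),
    tibble::tibble(country_code = "AAA", country_name = "Testland",
                   year = 2014:2017, commodity_code = "M1",
                   commodity_name = "Milk", g_per_day = 500)),
    dialect = "new_fbs")
  base2 <- yearly_supply(milk_tab, tiny_composition(), tiny_mapping())
  milk <- tibble::tibble(country_code = "AAA", vehicle = "milk",
                         level = 10, coverage = 1, start_year = 2014L,
                         basis = "voluntary", milk_product_share = 0.6)
  both <- apply_policies(base2, dplyr::bind_rows(wheat, milk), milk_tab,
                         tiny_mapping())
  only_w <- apply_policies(base2, wheat, milk_tab, tiny_mapping())
  only_m <- apply_policies(base2, milk, milk_tab, tiny_mapping())
  expect_equal(both$increment_ug_day,
               only_w$increment_ug_day + only_m$increment_ug_day)
  expect_equal(sort(unique(both$basis)), "mandatory,voluntary")

  # zero level and zero coverage are exact no-ops
  noop <- dplyr::mutate(wheat, level = 0)
  expect_equal(apply_policies(base2, noop, milk_tab,
                              tiny_mapping())$increment_ug_day,
               rep(0, 4))
  noop2 <- dplyr::mutate(milk, coverage = 0)
  expect_equal(apply_policies(base2, noop2, milk_tab,
                              tiny_mapping())$increment_ug_day,
               rep(0, 4))
})

test_that("policies for absent countries are skipped with a warning", {
  tab <- tiny_table(years = 2014:2015)
  base <- yearly_supply(tab, tiny_composition(), tiny_mapping())
  pol <- tibble::tibble(country_code = "NOWHERE", vehicle = "wheat_flour",
                        level = 10, coverage = 1, start_year = 2014L,
                        basis = "mandatory", milk_product_share = NA_real_)
  expect_warning(out <- apply_policies(base, pol, tab, tiny_mapping()),
                 "skipped")
  expect_equal(out$fortified_ug_day, base$ug_per_day)
})

test_that("oil fortification is refused without an explicit retention factor", {
  tab <- tiny_table(years = 2014:2015)
  base <- yearly_supply(tab, tiny_composition(), tiny_mapping())
  pol <- tibble::tibble(country_code = "AAA", vehicle = "oil",
                        level = 100, coverage = 1, start_year = 2014L,
                        basis = "mandatory", milk_product_share = NA_real_)
  expect_error(apply_policies(base, pol, tab, tiny_mapping()),
               class = "vitd_config_error")
  # with a retention factor it runs (vehicle group absent here -> 0 increment)
  out <- apply_policies(base, pol, tab, tiny_mapping(), oil_retention = 0.5)
  expect_equal(out$increment_ug_day, rep(0, 2))
})

test_that("pipeline fortification agrees with the generator's ground truth", {
  pol <- tibble::tibble(country_code = "SY01", vehicle = "wheat_flour",
                        level = 15, coverage = 0.8, start_year = 2016L,
                        basis = "mandatory", milk_product_share = NA_real_)
  pol2 <- tibble::tibble(country_code = "SY02", vehicle = "milk",
                         level = 10, coverage = 1, start_year = 2015L,
                         basis = "voluntary", milk_product_share = 0.7)
  cfg <- synthetic_config(n_countries = 3, years = 2014:2017,
                          policies = dplyr::bind_rows(pol, pol2), seed = 9)
  gen <- generate_fbs(cfg)
  base <- yearly_supply(gen$table, gen$composition, gen$mapping,
                        bioactivity_options(FALSE))
  out <- apply_policies(base, cfg$policies, gen$table, gen$mapping)
  joined <- dplyr::inner_join(out, gen$truth,
                              by = c("country_code", "year"))
  expect_equal(joined$fortified_ug_day, joined$fortified_less_ohd,
               tolerance = 1e-12)
})
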