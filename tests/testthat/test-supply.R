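test_that("country-year supply matches hand-computed sums", {
  tab <- tiny_table()
  comp <- tiny_composition()
  map <- tiny_mapping()
  # 50*8/100 + 30*(3 + 5*0.2)/100 + 200*0 = 4.0 + 1.2 = 5.2
  expect_equal(country_year_supply(tab, "AAA", 2015, comp, map,
                                   bioactivity_options()), 5.2)
  # excluding 25(OH)D: 4.0 + 0.9 = 4.9
  expect_equal(country_year_supply(tab, "AAA", 2015, comp, map,
                                   bioactivity_options(FALSE)), 4.9)
  # single commodity at 100 g/d in a 2 ug/100 g group
  one <- supply_table(tibble::tibble(
    country_code = "BBB", country_name = "B", year = 2015L,
    commodity_code = "Z1", commodity_name = "Z", g_per_day = 100),
    dialect = "new_fbs")
  comp1 <- tibble::tibble(group_id = "z", group_name = "z",
                          vitd3_ug_per_100g = 2, ohd3_ug_per_100g = 0,
                          source = "t")
  map1 <- tibble::tibble(commodity_code = "Z1", commodity_name = "Z",
                         group_id = "z")
  expect_equal(country_year_supply(one, "BBB", 2015, comp1, map1), 2.0)
  # absence is an error, not a zero
  expect_error(country_year_supply(tab, "AAA", 1999, comp, map),
               class = "vitd_not_found_error")
  expect_error(country_year_supply(tab, "ZZZ", 2015, comp, map),
               class = "vitd_not_found_error")
})

test_that("country-year supply equals a brute-force per-record loop", {
  set.seed(33)
  comp <- tiny_composition()
  map <- tiny_mapping()
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    recs <- tibble::tibble(
      country_code = sample(c("A", "B", "C"), n, replace = TRUE),
      country_name = "x",
      year = sample(2014:2016, n, replace = TRUE),
      commodity_code = sample(c(map$commodity_code, "UNMAPPED"), n,
                              replace = TRUE),
      commodity_name = "x",
      g_per_day = stats::runif(n, 0, 300))
    recs <- recs[!duplicated(recs[c("country_code", "year",
                                    "commodity_code")]), ]
    tab <- supply_table(recs, dialect = "old_fbs")
    cc <- recs$country_code[1]; yy <- recs$year[1]
    # independent oracle: explicit loop over raw records, no grouping
    oracle <- 0
    for (i in seq_len(nrow(recs))) {
      if (recs$country_code[i] != cc || recs$year[i] != yy) next
      k <- which(map$commodity_code == recs$commodity_code[i])
      if (length(k) == 0) next
      j <- which(comp$group_id == map$group_id[k])
      oracle <- oracle + recs$g_per_day[i] *
        (comp$vitd3_ug_per_100g[j] + 5 * comp$ohd3_ug_per_100g[j]) / 100
    }
    expect_equal(country_year_supply(tab, cc, yy, comp, map,
                                     bioactivity_options()),
                 oracle, tolerance = 1e-9)
  }
})

test_that("period aggregation uses the sample SD across available years", {
  flat <- period_estimate(c("2014" = 4, "2015" = 4, "2016" = 4, "2017" = 4),
                          c(2014, 2017))
  expect_equal(flat$mean_ug_day, 4)
  expect_equal(flat$sd_ug_day, 0)
  expect_equal(flat$n_years, 4)

  two <- period_estimate(c("2014" = 3, "2015" = 5), c(2014, 2017))
  expect_equal(two$mean_ug_day, 4)
  expect_equal(two$sd_ug_day, sqrt(2), tolerance = 1e-12)
  expect_equal(two$n_years, 2)

  single <- period_estimate(c("2016" = 7), c(2014, 2017))
  expect_equal(single$sd_ug_day, 0)

  expect_error(period_estimate(c("2010" = 1), c(2014, 2017)),
               class = "vitd_not_found_error")
})

test_that("contribution shares are ratios of group contributions", {
  tab <- tiny_table()
  shares <- contribution_shares(tab, "AAA", c(2014, 2016),
                                tiny_composition(), tiny_mapping())
  expect_equal(sum(shares$share), 1)
  expect_equal(shares$share[shares$group_id == "pelagic_fish"], 4.0 / 5.2)
  expect_equal(shares$share[shares$group_id == "eggs"], 1.2 / 5.2)
  expect_equal(shares$share[shares$group_id == "wheat"], 0)
  expect_false(attr(shares, "zero_total"))

  # all-zero composition -> empty, flagged
  zero_comp <- dplyr::mutate(tiny_composition(), vitd3_ug_per_100g = 0,
                             ohd3_ug_per_100g = 0)
  empty <- contribution_shares(tab, "AAA", c(2014, 2016), zero_comp,
                               tiny_mapping())
  expect_equal(nrow(empty), 0)
  expect_true(attr(empty, "zero_total"))
})

test_that("supply estimates are linear in composition and in supply", {
  cfg <- synthetic_config(n_countries = 3, years = 2014:2016, seed = 5)
  gen <- generate_fbs(cfg)
  est <- supply_estimates(gen$table, c(2014, 2016), gen$composition,
                          gen$mapping)
  doubled_comp <- dplyr::mutate(gen$composition,
                                vitd3_ug_per_100g = 2 * vitd3_ug_per_100g,
                                ohd3_ug_per_100g = 2 * ohd3_ug_per_100g)
  est2 <- supply_estimates(gen$table, c(2014, 2016), doubled_comp,
                           gen$mapping)
  expect_equal(est2$mean_ug_day, 2 * est$mean_ug_day)
  expect_equal(est2$sd_ug_day, 2 * est$sd_ug_day)

  doubled_tab <- gen$table
  doubled_tab$g_per_day <- 2 * doubled_tab$g_per_day
  est3 <- supply_estimates(doubled_tab, c(2014, 2016), gen$composition,
                           gen$mapping)
  expect_equal(est3$mean_ug_day, 2 * est$mean_ug_day)

  # including 25(OH)D never lowers an estimate
  excl <- supply_estimates(gen$table, c(2014, 2016), gen$composition,
                           gen$mapping, bioactivity_options(FALSE))
  expect_true(all(est$mean_ug_day >= excl$mean_ug_day))
})

test_that("the 25(OH)D increment is non-negative and zero without metabolite", {
  tab <- tiny_table(years = 2014:2016)
  inc <- ohd_increment(tab, "AAA", c(2014, 2016), tiny_composition(),
                       tiny_mapping())
  # 30 g/d eggs * 5 * 0.2 ug/100 g = 0.3
  expect_equal(inc, 0.3)
  expect_gte(inc, 0)

  no_ohd <- dplyr::mutate(tiny_composition(), ohd3_ug_per_100g = 0)
  expect_equal(ohd_increment(tab, "AAA", c(2014, 2016), no_ohd,
                             tiny_mapping()), 0)
})
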