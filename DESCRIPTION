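Package: vitdsupply
Title: Per Capita Vitamin D Supply Estimation from Food Balance Sheets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates average per capita daily vitamin D supply (ug/d) from
    FAOSTAT food-balance-sheet exports. Commodity supplies (kg/capita/year)
    are converted to g/d, mapped to food-composition groups carrying vitamin
    D3 and 25-hydroxyvitamin D3 content (with a configurable bioactivity
    factor for the metabolite), and summed to country-year supply estimates.
    Includes fortification-scenario modelling for staple vehicles (wheat
    flour, maize flour, fluid milk), supply-band classification and regional
    summaries, Bland-Altman concordance against survey intake data, and a
    synthetic food-balance-sheet generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
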