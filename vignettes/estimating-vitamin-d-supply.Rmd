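---
title: "Estimating per capita vitamin D supply from food balance sheets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating per capita vitamin D supply from food balance sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdsupply)
library(dplyr)
```

## The problem and the model

Nationally representative vitamin D intake data exist for only a handful of
countries, yet intake adequacy matters most exactly where representative
serum 25-hydroxyvitamin D surveys are missing. FAO food balance sheets
(FBSs) — national accounts of food available per person, per commodity and
year — offer a proxy: if each commodity group is assigned an average vitamin
D content, the population-level *supply* of vitamin D (µg/person/day) can be
computed for essentially every country, and used as a surrogate for intake.

The estimate for country $c$ in year $y$ is a plain weighted sum:

$$ S_{cy} \;=\; \sum_{k} g_{cyk} \cdot \frac{v_k}{100}, $$

where $g_{cyk}$ is the daily per capita supply of commodity $k$ in grams
(the FBS kg/year figure divided by the year length and scaled to grams) and
$v_k$ is the vitamin D content of the commodity's composition group in
µg/100 g. Supply is an upper bound on intake: waste, spoilage and
within-country distribution are not modelled.

Two conventions exist for $v_k$. Some composition tables (notably the UK
one) count the metabolite 25-hydroxyvitamin D3 toward total vitamin D at
five times its mass, others (the US tables) do not. The package computes
both:

$$ v_k = \mathrm{D3}_k + f \cdot \mathrm{25(OH)D3}_k
   \quad\text{or}\quad v_k = \mathrm{D3}_k, $$

with the bioactivity factor $f$ defaulting to 5 but exposed as a parameter
so its influence can be probed. Including the metabolite can never lower an
estimate; the difference between the two conventions (the "25(OH)D
increment") is itself a quantity of interest, largest in countries with
heavy pelagic-fish supply.

Country-year estimates are aggregated to period means with the sample
(n − 1) SD across years — years are the only repeated unit available per
country, so the SD expresses between-year variation in supply. Missing
years inside a period are tolerated (the mean runs over available years and
`n_years` records how many); a constant series has SD exactly 0.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `days_per_year` | 365 | d | FBS kg/yr → g/d conversion; leap days ignored, matching common FBS-derived per-day figures. Configurable. |
| `bioactivity_factor` | 5 | — | Conventional 25(OH)D3 potency multiplier; only 5 is in published use, but sensitivity analyses may vary it. |
| `include_ohd` | TRUE | — | Which content convention an analysis follows; matched to the comparator when validating against surveys. |
| `density_g_ml` (milk) | 1.0 | g/mL | FBS milk is in grams, fortification levels per litre; 1 g ≈ 1 mL is assumed and configurable. |
| quantile `type` | 7 | — | R's default linear interpolation for regional quartiles; the choice is cosmetic at 1-decimal data precision. |

## Composition data and mapping

The package does not redistribute proprietary composition databases. It
ships an **illustrative, synthetic** composition table
(`composition_example.csv`) whose ordering of magnitudes follows the
field's consensus — fish far above eggs and meat, dairy low, plant staples
zero — so that examples and tests are realistic in structure, but absolute
country reproductions require a user-supplied table in the documented CSV
schema. The commodity → group mapping is many-to-one; unmapped commodities
contribute zero vitamin D but are never dropped silently: every run reports
the fraction of supply mass covered by the mapping, and
`coverage_report()` lists what was missed.

## Fortification modelling

Fortification adds vitamin D the FBS cannot see. A policy is a vehicle
(wheat flour, maize flour, or fluid milk), a level (µg/kg or µg/L), a
coverage fraction (share of the vehicle supply actually fortified), a start
year and a mandatory/voluntary basis. Increments are:

* flour: `g/d × coverage × level / 1000`, treating all wheat/maize supply
  as flour available for fortification;
* milk: the supply is first scaled by the share of overall milk consumed
  as the fortified fluid products, then converted to litres and multiplied
  by coverage and level.

Policies gate on whole calendar years (the entire `start_year` counts as
fortified), increments from several policies add with no interaction, and
a zero level or zero coverage is an exact no-op. Fortified **oils** are
refused unless the user supplies an explicit cooking-retention factor:
vitamin D retention in heated oil is too variable to assume a default, so
silently including oils would overstate supply.

## Banding, regions, deltas

Countries are classified on their estimate rounded **half-up to one
decimal** into six bands: ≤1.5, 1.6–3.0, 3.1–5.5, 5.6–7.5, 7.6–10.0 and
>10.0 µg/d. Reading the bottom band as inclusive of 1.5 makes the six
bands tile the 1-decimal grid with no gaps, which is what lets per-band
country counts sum exactly to the number of countries. Rounding half-up
(rather than R's round-half-even) matches how 1-decimal tables are
conventionally printed. Regional summaries use a shipped continental
assignment (UN M49-style, with SARs and former countries as separate
entries) and report median and quartiles; between-period deltas are
classified by absolute change (<0.5, 0.5–0.99, ≥1.0 µg/d).

## Concordance with survey intakes

Where a national survey reports mean vitamin D intake from food sources
(excluding supplements, which balance sheets cannot capture), the matched
FBS estimate — same years, same 25(OH)D convention — can be compared by
Bland-Altman analysis: bias (mean of supply − intake differences), SD of
differences, limits of agreement bias ± 1.96 SD, and a proportional-bias
p value from the OLS regression of differences on pair means. With fewer
than 3 pairs the SD and slope are degenerate and the analysis errors; with
identical differences the regression is degenerate and the p value is `NA`.
The proportional-bias statistic is labelled as such because agreement
"p values" in the literature are often reported without naming the test.

## What the synthetic generator does and does not emulate

`generate_fbs()` builds a FAOSTAT-dialect CSV for a configurable set of
countries, years and commodity groups. Yearly supplies are the profile
mean times an independent normal multiplier N(1, cv) truncated at zero
(truncations are counted); `cv = 0` yields identical years. The defaults —
5 countries, 4 years, 14 commodity groups with staple cereals and milk
dominating mass and fish dominating vitamin D — sketch a mid-supply diet
at the problem sizes the test-suite uses. The generator also computes the
implied vitamin D supply by a plain per-record loop, deliberately separate
from the estimation pipeline, so tests can demand *exact* (1e-9)
agreement: the pipeline is deterministic arithmetic and should reproduce
ground truth with no estimation error.

What passing those tests shows is that the plumbing — parsing, unit
conversion, mapping, summation, gating, aggregation — is correct. What it
cannot show is fidelity to real data: real FBS series have autocorrelated
supplies, revisions, missing commodities and changing country definitions,
and real composition values vary by season, region and husbandry, none of
which the generator models. Survey pairs are likewise idealised
(uniform intakes, Gaussian noise, truncation at zero).

## Numerical choices and degenerate inputs

* All supply arithmetic is done at full double precision; half-up rounding
  to one decimal happens only at report/banding time.
* Duplicate (country, year, commodity) keys are an error, never averaged.
* A requested country/year that is absent raises a not-found error,
  distinct from a legitimate zero supply.
* A zero total supply yields an empty contribution breakdown with an
  explicit flag rather than 0/0 shares.
* Ties in `extremes()` are returned as lists; in the shipped reference
  data the 2004–2013 minimum (0.3 µg/d) is shared by two countries.
* Band edges are compared in integer tenths, so floating-point noise at
  band boundaries cannot reassign a country.

## Reference data

`reference_estimates()` and `reference_fortified_estimates()` load
transcriptions of published 1-decimal country estimates (178 countries for
2004–2013, 173 for 2014–2017, plus eight fortifying countries with
natural-food and fortified variants). They serve as in-package reference
data for the banding, extremes, increment and group-mean summaries; the
underlying FAO downloads and the full commodity-level composition
assignment are not redistributed, so regenerating those tables from raw
FBS files is out of scope here.

## Known limitations

Supply overestimates intake (waste, spoilage); composition averages hide
within-group variability (fatty versus white pelagic fish); no
season/region/husbandry adjustment; voluntary-fortification uptake and
UV-irradiated mushrooms are not modelled; supplements are invisible to the
method. These are properties of the approach, not of the implementation.
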