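#' Bioactivity options for 25-hydroxyvitamin D
#'
#' Some food-composition tables fold 25-hydroxyvitamin D3 (25(OH)D3) into
#' total vitamin D by multiplying the metabolite content by a potency
#' ("bioactivity") factor, conventionally 5. These options control whether
#' and how that adjustment is applied.
#'
#' @param include_ohd Include the 25(OH)D3 contribution? (default TRUE)
#' @param bioactivity_factor Dimensionless multiplier on 25(OH)D3 content
#'   (default 5); must be > 0.
#' @return A `bioactivity_options` list.
#' @export
bioactivity_options <- function(include_ohd = TRUE, bioactivity_factor = 5) {
  stopifnot(is.logical(include_ohd), length(include_ohd) == 1)
  assert_scalar_number(bioactivity_factor, "bioactivity_factor")
  if (bioactivity_factor <= 0) {
    abort("`bioactivity_factor` must be > 0.", class = "vitd_validation_error")
  }
  structure(list(include_ohd = include_ohd,
                 bioactivity_factor = bioactivity_factor),
            class = "bioactivity_options")
}

#' Total vitamin D content of a composition group
#'
#' Returns vitamin D3 plus, when `opts$include_ohd` is TRUE, the
#' bioactivity-adjusted 25(OH)D3 content, per 100 g of food.
#'
#' @param composition Data frame with columns `vitd3_ug_per_100g` and
#'   `ohd3_ug_per_100g` (one row per group); vectorized over rows.
#' @param opts A [bioactivity_options()] object.
#' @return Numeric vector, ug vitamin D per 100 g.
#' @examples
#' comp <- tibble::tibble(vitd3_ug_per_100g = 0.5, ohd3_ug_per_100g = 0.1)
#' total_content(comp, bioactivity_options())                      # 1.0
#' total_content(comp, bioactivity_options(include_ohd = FALSE))   # 0.5
#' @export
total_content <- function(composition, opts = bioactivity_options()) {
  stopifnot(inherits(opts, "bioactivity_options"))
  assert_has_columns(composition, c("vitd3_ug_per_100g", "ohd3_ug_per_100g"),
                     "composition table")
  if (any(composition$vitd3_ug_per_100g < 0, na.rm = TRUE) ||
      any(composition$ohd3_ug_per_100g < 0, na.rm = TRUE)) {
    abort("composition content values must be >= 0.",
          class = "vitd_validation_error")
  }
  if (opts$include_ohd) {
    composition$vitd3_ug_per_100g +
      opts$bioactivity_factor * composition$ohd3_ug_per_100g
  } else {
    composition$vitd3_ug_per_100g
  }
}

#' Read a composition table
#'
#' Schema: `group_id, group_name, vitd3_ug_per_100g, ohd3_ug_per_100g,
#' source`. The package ships an illustrative table (see
#' [vitd_example_file()]) whose magnitudes follow the field's consensus
#' ordering -- fish far above eggs and meat, dairy low, plant staples zero --
#' but it is not a published database; users supply their own for real
#' analyses.
#'
#' @param path CSV path.
#' @return Tibble with one row per composition group.
#' @export
read_composition <- function(path) {
  comp <- readr::read_csv(path, col_types = readr::cols(
    group_id = readr::col_character(),
    group_name = readr::col_character(),
    vitd3_ug_per_100g = readr::col_double(),
    ohd3_ug_per_100g = readr::col_double(),
    source = readr::col_character()), progress = FALSE)
  assert_has_columns(comp, c("group_id", "vitd3_ug_per_100g",
                             "ohd3_ug_per_100g"),
                     sprintf("composition file '%s'", path))
  if (anyDuplicated(comp$group_id)) {
    abort("duplicate group_id in composition table.",
          class = "vitd_config_error")
  }
  if (any(comp$vitd3_ug_per_100g < 0) || any(comp$ohd3_ug_per_100g < 0)) {
    abort("composition content values must be >= 0.",
          class = "vitd_validation_error")
  }
  comp
}

#' Read a commodity-to-group mapping
#'
#' Schema: `commodity_code, commodity_name, group_id`. The mapping is
#' many-to-one: a commodity appearing under two different groups is a
#' configuration error. Commodities absent from the mapping are treated as
#' unmapped (zero vitamin D) downstream, and always reported in the
#' coverage log.
#'
#' @param path CSV path.
#' @return Tibble with one row per commodity.
#' @export
read_mapping <- function(path) {
  map <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  assert_has_columns(map, c("commodity_code", "group_id"),
                     sprintf("mapping file '%s'", path))
  validate_mapping(map)
}

validate_mapping <- function(map) {
  map <- unique(tibble::as_tibble(map))
  if (anyDuplicated(map$commodity_code)) {
    dup <- map$commodity_code[duplicated(map$commodity_code)][1]
    abort(sprintf("commodity '%s' is mapped to more than one group.", dup),
          class = "vitd_config_error")
  }
  map
}

#' Resolve commodity codes to composition groups
#'
#' @param commodity_code Character vector of commodity codes.
#' @param mapping Mapping tibble (see [read_mapping()]).
#' @return Character vector of group ids, `NA` for unmapped commodities.
#' @export
resolve_group <- function(commodity_code, mapping) {
  mapping <- validate_mapping(mapping)
  mapping$group_id[match(commodity_code, mapping$commodity_code)]
}

#' Mapping coverage of a supply table
#'
#' Accounts for every g/day of supply: mapped plus unmapped totals equal
#' the overall total exactly, and unmapped commodities are listed so none
#' is dropped silently.
#'
#' @param table A `supply_table`.
#' @param mapping Mapping tibble.
#' @return List with `mapped_g_day`, `unmapped_g_day`, `coverage`
#'   (fraction of supply mass mapped) and `unmapped_commodities`.
#' @export
coverage_report <- function(table, mapping) {
  grp <- resolve_group(table$commodity_code, mapping)
  mapped <- sum(table$g_per_day[!is.na(grp)])
  unmapped <- sum(table$g_per_day[is.na(grp)])
  total <- mapped + unmapped
  list(mapped_g_day = mapped,
       unmapped_g_day = unmapped,
       coverage = if (total > 0) mapped / total else NA_real_,
       unmapped_commodities =
         sort(unique(table$commodity_name[is.na(grp)])))
}

#' Paths to the packaged example data files
#'
#' @param file File name under `extdata`; `NULL` lists available files.
#' @return Full path (or vector of file names).
#' @export
vitd_example_file <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "vitdsupply"))
  } else {
    path <- system.file("extdata", file, package = "vitdsupply")
    if (path == "") abort(sprintf("no packaged file '%s'", file),
                          class = "vitd_io_error")
    path
  }
}
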