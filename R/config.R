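# Analysis configuration and the study-region (subregion) mapping.
#
# The study region — which countries count as breeding-side Europe (excluding
# Russia) and which as sub-Saharan Africa, and the 4 + 4 subregion groupings —
# is configuration data, not code: a default YAML ships with the package and
# any run can supply its own, so the engine stays generic (synthetic worlds
# use their own generated mapping).

EUROPEAN_SUBREGIONS <- c("western Europe", "central Europe",
                         "northern Europe", "eastern Europe")
AFRICAN_SUBREGIONS  <- c("western Africa", "central Africa",
                         "southern Africa", "eastern Africa")
SPECIES_GROUPS <- c("landbird", "raptor")
DEVICES <- c("GLS", "PTT", "GPS")
SEASONS <- c("breeding", "nonbreeding", "resident")

#' Analysis configuration
#'
#' Bundles the constants of the analysis: the minimum number of migration
#' records a national population needs to enter the link analysis, the
#' subregional population-coverage threshold used when selecting priority
#' countries for future tracking, the projection used for all area and
#' centroid computations, and the random seed.
#'
#' @param min_records_per_population minimum records per population
#'   (species x breeding country) retained; populations below it are excluded
#' @param coverage_threshold_pct target percentage of a subregional
#'   population that tracking records should represent
#' @param equal_area_crs `"cea"` (cylindrical equal-area over lon/lat
#'   degrees, km units) or `"planar"` (coordinates used as-is)
#' @param random_seed integer seed driving every stochastic step
#' @return a list of class `flyway_config`
#' @export
analysis_config <- function(min_records_per_population = 3,
                            coverage_threshold_pct = 50,
                            equal_area_crs = "cea",
                            random_seed = 1L) {
  stopifnot(min_records_per_population >= 1,
            coverage_threshold_pct > 0, coverage_threshold_pct <= 100)
  equal_area_crs <- match.arg(equal_area_crs, c("cea", "planar"))
  structure(list(
    min_records_per_population = as.integer(min_records_per_population),
    coverage_threshold_pct = as.numeric(coverage_threshold_pct),
    equal_area_crs = equal_area_crs,
    random_seed = as.integer(random_seed)
  ), class = "flyway_config")
}

#' Read an analysis configuration (plus optional subregion map) from YAML
#'
#' Recognised top-level keys: the four [analysis_config()] fields and
#' `subregions`, a mapping `code -> {continent, subregion}`. Unknown keys are
#' an error, so typos fail loudly.
#'
#' @param path YAML file
#' @return list with elements `config` ([analysis_config()]) and
#'   `subregion_map` (named list or `NULL`)
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("min_records_per_population", "coverage_threshold_pct",
             "equal_area_crs", "random_seed", "subregions")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  args <- raw[setdiff(names(raw), "subregions")]
  cfg <- do.call(analysis_config, args)
  list(config = cfg, subregion_map = raw$subregions)
}

#' Default African-Eurasian study-region mapping
#'
#' The packaged country-to-subregion mapping for the real flyway: European
#' breeding countries (Turkey included, Russia excluded) and sub-Saharan
#' African nonbreeding countries, each assigned to one of four subregions per
#' continent. Override by supplying your own mapping of the same shape.
#'
#' @return named list: ISO 3166-1 alpha-3 code -> list(continent, subregion)
#' @export
flyway_subregions <- function() {
  path <- system.file("extdata", "flyway_subregions.yaml",
                      package = "flywaylinks", mustWork = TRUE)
  yaml::read_yaml(path)$subregions
}

validate_subregion_map <- function(map) {
  for (code in names(map)) {
    e <- map[[code]]
    if (is.null(e$continent) || is.null(e$subregion)) {
      stop("subregion map entry for ", code, " lacks continent/subregion")
    }
    if (!e$continent %in% c("Europe", "Africa")) {
      stop("subregion map entry for ", code, ": unknown continent ",
           e$continent)
    }
    ok <- if (e$continent == "Europe") EUROPEAN_SUBREGIONS else
      AFRICAN_SUBREGIONS
    if (!e$subregion %in% ok) {
      stop("subregion map entry for ", code, ": subregion ", e$subregion,
           " not valid for ", e$continent)
    }
  }
  invisible(map)
}
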