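# Desk-scale worked examples built from published national population
# shares, used in the README, the tests and the acceptance checks.

#' Worked example: European turtle dove in western Europe
#'
#' The published national shares of the western-European breeding population
#' of the European turtle dove (*Streptopelia turtur*) — Spain 73.8%, France
#' 24.9%, Portugal 0.9%, United Kingdom 0.2%, Belgium 0.2%, Netherlands and
#' Luxembourg below 0.1% — reconstructed as raw population sizes (per 100
#' 000) whose shares round to those values. Tracking data existed for the
#' French and British populations, so the coverage rule starts from 25.1%
#' of the subregional population and must add Spain.
#'
#' @return list with `populations` (population-table tibble),
#'   `tracked_countries` (`FRA`, `GBR`) and `subregion_countries`
#' @export
example_turtle_dove <- function() {
  populations <- tibble::tibble(
    species_id = "turtle_dove",
    country = c("ESP", "FRA", "PRT", "GBR", "BEL", "NLD", "LUX"),
    pop_size = c(73790, 24860, 880, 230, 180, 40, 20),
    trend = "decreasing",
    species_group = "landbird")
  list(populations = populations,
       tracked_countries = c("FRA", "GBR"),
       subregion_countries = populations$country)
}

#' Worked example: link strengths from simple record splits
#'
#' Builds a one-population link table from a named vector of per-country
#' record counts and computes strengths; e.g. a 3-record population split
#' 2:1 yields strengths 66.7% and 33.3%, and any 9-link population has mean
#' strength 100/9 = 11.1%.
#'
#' @param counts named numeric vector: nonbreeding country -> record count
#' @param species,breeding_country labels for the population
#' @return link tibble with strengths
#' @export
example_population_links <- function(counts, species = "SP001",
                                     breeding_country = "E01") {
  links <- tibble::tibble(
    species_id = species, species_group = "landbird",
    breeding_country = breeding_country,
    nonbreeding_country = names(counts),
    status = "observed",
    record_count = as.numeric(counts),
    strength_pct = NA_real_)
  compute_strengths(links)
}
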