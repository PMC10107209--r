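# Knowledge gaps and priorities for future tracking.
#
# A gap species for a country is a long-distance migrant present there (by
# the population table in Europe, by positive nonbreeding-range overlap in
# Africa) with no migratory link — observed or inferred — touching the
# country. Priorities are the species-country combinations needed to bring
# tracking coverage of each decreasing species up to the configured share of
# every subregional population it has.

#' Species of a group present in a country
#'
#' European countries list species with a positive population-table entry;
#' African countries list species whose nonbreeding range overlaps the
#' country with positive area in the equal-area projection (boundary-point
#' contact does not count as presence).
#'
#' @param country country code
#' @param group `"landbird"` or `"raptor"`
#' @param populations population table (carries the species group)
#' @param ranges seasonal range tibble
#' @param countries country layer
#' @param crs equal-area projection identifier
#' @return character vector of species ids, sorted
#' @export
species_presence <- function(country, group, populations, ranges, countries,
                             crs = "cea") {
  continent <- countries$continent[match(country, countries$code)]
  if (is.na(continent)) stop("unknown country code: ", country)
  if (continent == "Europe") {
    sp <- populations |>
      dplyr::filter(.data$species_group == group, .data$country == !!country,
                    .data$pop_size > 0) |>
      dplyr::pull(.data$species_id)
    return(sort(unique(sp)))
  }
  group_of <- unique(populations[c("species_id", "species_group")])
  cg <- geom_project(country_geometry(countries, country), crs)
  cand <- ranges |>
    dplyr::filter(.data$season == "nonbreeding") |>
    dplyr::semi_join(dplyr::filter(group_of, .data$species_group == group),
                     by = "species_id")
  c_area <- geom_area(cg)
  present <- vapply(seq_len(nrow(cand)), function(i) {
    pr <- geom_project(cand$geometry[[i]], crs)
    a <- geom_area(geom_intersection(pr, cg))
    area_positive(a, min(c_area, geom_area(pr)))
  }, logical(1))
  sort(unique(cand$species_id[present]))
}

tracked_species_in_country <- function(links, country, countries) {
  sort(unique(links_touching_country(links, country, countries)$species_id))
}

#' Knowledge-gap percentages per country and species group
#'
#' For every country of the layer and both groups, the percentage of present
#' species without any link touching the country:
#' `gap_pct = 100 * (present - tracked) / present`. Countries where no
#' species of the group is present are omitted with a warning.
#'
#' @param links link tibble
#' @param populations population table
#' @param ranges seasonal range tibble
#' @param countries country layer
#' @param crs equal-area projection identifier
#' @return tibble `country, continent, species_group, n_species_present,
#'   n_species_tracked, gap_pct`
#' @export
knowledge_gaps <- function(links, populations, ranges, countries,
                           crs = "cea") {
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(countries))) {
    code <- countries$code[i]
    tracked_all <- tracked_species_in_country(links, code, countries)
    for (group in SPECIES_GROUPS) {
      present <- species_presence(code, group, populations, ranges,
                                  countries, crs)
      if (length(present) == 0) { skipped <- skipped + 1L; next }
      tracked <- intersect(tracked_all, present)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        country = code, continent = countries$continent[i],
        species_group = group,
        n_species_present = length(present),
        n_species_tracked = length(tracked),
        gap_pct = 100 * (length(present) - length(tracked)) /
          length(present))
    }
  }
  if (skipped > 0) {
    warning(skipped, " country-group combinations had no species present ",
            "and were omitted")
  }
  dplyr::bind_rows(rows)
}

#' Greedily select priority countries to reach coverage of a subregional
#' population
#'
#' Starting from the coverage already afforded by tracked countries (the sum
#' of their shares), untracked countries are added in order of decreasing
#' share (ties broken by country code) until cumulative coverage reaches
#' `threshold_pct` or the subregion is exhausted. An empty selection means
#' existing tracking already covers the threshold.
#'
#' @param shares tibble with `country` and `share_pct` for every country of
#'   the subregion holding the species
#' @param tracked_countries codes of countries already holding a link for
#'   the species
#' @param threshold_pct coverage target (default 50)
#' @return tibble `country, share_pct, coverage_before, coverage_after`,
#'   one row per selected country in selection order
#' @export
select_priority_countries <- function(shares, tracked_countries,
                                      threshold_pct = 50) {
  coverage0 <- sum(shares$share_pct[shares$country %in% tracked_countries])
  empty <- tibble::tibble(country = character(), share_pct = numeric(),
                          coverage_before = numeric(),
                          coverage_after = numeric())
  if (coverage0 >= threshold_pct) return(empty)
  # ties (including floating-noise near-ties from polygon arithmetic) break
  # by country code, so ordering shares to 1e-9 of a point keeps the
  # selection deterministic
  todo <- shares |>
    dplyr::filter(!.data$country %in% tracked_countries) |>
    dplyr::arrange(dplyr::desc(round(.data$share_pct, 9)), .data$country)
  picked <- list()
  cov <- coverage0
  for (i in seq_len(nrow(todo))) {
    picked[[i]] <- tibble::tibble(country = todo$country[i],
                                  share_pct = todo$share_pct[i],
                                  coverage_before = cov,
                                  coverage_after = cov + todo$share_pct[i])
    cov <- cov + todo$share_pct[i]
    if (cov >= threshold_pct) break
  }
  dplyr::bind_rows(picked)
}

#' Priority species-country combinations across the flyway
#'
#' Runs [select_priority_countries()] for every species with a decreasing
#' European population, in every European subregion where it breeds (shares
#' from national population sizes) and every African subregion its
#' nonbreeding range reaches (shares from range areas, since no African
#' national population sizes exist). A country counts as tracked for a
#' species when any link of any of its populations touches it, regardless
#' of link status. Combinations are deduplicated across subregional runs (a
#' country appears once per species).
#'
#' @param links link tibble
#' @param populations population table
#' @param ranges seasonal range tibble
#' @param countries country layer
#' @param config [analysis_config()]
#' @return list with `combos` (tibble `species_id, species_group, continent,
#'   subregion, country, share_pct, coverage_before, coverage_after`) and
#'   `counts` (per-country number of priority species)
#' @export
priority_atlas <- function(links, populations, ranges, countries,
                           config = analysis_config()) {
  thr <- config$coverage_threshold_pct
  crs <- config$equal_area_crs
  decreasing <- populations |>
    dplyr::filter(.data$trend == "decreasing") |>
    dplyr::distinct(.data$species_id, .data$species_group)
  combos <- list()
  for (k in seq_len(nrow(decreasing))) {
    sp <- decreasing$species_id[k]
    sp_links <- dplyr::filter(links, .data$species_id == sp)
    tracked_eur <- unique(sp_links$breeding_country)
    tracked_afr <- unique(sp_links$nonbreeding_country)
    # European subregions where the species breeds
    eur_subs <- countries |>
      dplyr::filter(.data$continent == "Europe") |>
      dplyr::semi_join(dplyr::filter(populations, .data$species_id == sp,
                                     .data$pop_size > 0),
                       by = c(code = "country")) |>
      dplyr::distinct(.data$subregion) |>
      dplyr::pull(.data$subregion)
    for (sub in eur_subs) {
      shares <- population_shares(populations, sp, "subregional",
                                  countries, sub)
      sel <- select_priority_countries(shares, tracked_eur, thr)
      if (nrow(sel) > 0) {
        combos[[length(combos) + 1L]] <- dplyr::mutate(
          sel, species_id = sp,
          species_group = decreasing$species_group[k],
          continent = "Europe", subregion = sub, .before = 1)
      }
    }
    # African subregions the nonbreeding range reaches
    rg <- range_geometry(ranges, sp, "nonbreeding")
    if (length(rg) == 0) next
    afr_subs <- unique(countries$subregion[countries$continent == "Africa"])
    for (sub in afr_subs) {
      shares <- tryCatch(
        range_shares(ranges, countries, sp, "subregional", sub, crs),
        error = function(e) NULL)
      if (is.null(shares)) next
      sel <- select_priority_countries(
        shares[c("country", "share_pct")], tracked_afr, thr)
      if (nrow(sel) > 0) {
        combos[[length(combos) + 1L]] <- dplyr::mutate(
          sel, species_id = sp,
          species_group = decreasing$species_group[k],
          continent = "Africa", subregion = sub, .before = 1)
      }
    }
  }
  combos <- dplyr::bind_rows(combos)
  if (nrow(combos) == 0) {
    combos <- tibble::tibble(species_id = character(),
                             species_group = character(),
                             continent = character(), subregion = character(),
                             country = character(), share_pct = numeric(),
                             coverage_before = numeric(),
                             coverage_after = numeric())
  } else {
    combos <- dplyr::distinct(combos, .data$species_id, .data$country,
                              .keep_all = TRUE)
  }
  counts <- combos |>
    dplyr::count(.data$country, .data$species_group,
                 name = "n_priority_species")
  list(combos = combos, counts = counts)
}
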