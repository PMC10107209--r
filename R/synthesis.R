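# Country-, species- and flyway-level syntheses of the link table.

#' National shares of a species' European or subregional population
#'
#' For each European country holding the species, the percentage of the
#' scope's total breeding population it hosts:
#' `100 * pop_size(country) / sum(pop_size over scope)`. Scope is either the
#' whole European population or one subregional population.
#'
#' @param populations population table ([read_population_table()])
#' @param species species id
#' @param scope `"european"` or `"subregional"`
#' @param countries country layer (required for subregional scope)
#' @param subregion subregion name (required for subregional scope)
#' @return tibble `country, pop_size, share_pct` ordered by descending share
#' @export
population_shares <- function(populations, species,
                              scope = c("european", "subregional"),
                              countries = NULL, subregion = NULL) {
  scope <- match.arg(scope)
  tab <- dplyr::filter(populations, .data$species_id == species,
                       .data$pop_size > 0)
  if (nrow(tab) == 0) stop("no population entries for species ", species)
  if (scope == "subregional") {
    if (is.null(countries) || is.null(subregion)) {
      stop("subregional scope needs a country layer and a subregion")
    }
    members <- countries$code[countries$subregion == subregion]
    tab <- dplyr::filter(tab, .data$country %in% members)
    if (nrow(tab) == 0) {
      stop("species ", species, " has no population in ", subregion)
    }
  }
  total <- sum(tab$pop_size)
  if (total <= 0) stop("zero total population for species ", species)
  tab |>
    dplyr::transmute(.data$country, .data$pop_size,
                     share_pct = 100 * .data$pop_size / total) |>
    dplyr::arrange(dplyr::desc(.data$share_pct), .data$country)
}

#' National shares of a species' sub-Saharan nonbreeding range
#'
#' The African-side analogue of [population_shares()], used where no
#' national population sizes exist: the percentage of the species'
#' nonbreeding-range area (equal-area projection) falling in each country of
#' the scope, relative to the range area within the whole scope region.
#'
#' @param ranges seasonal range tibble
#' @param countries country layer
#' @param species species id
#' @param scope `"sub_saharan"` (all African countries of the layer) or
#'   `"subregional"`
#' @param subregion subregion name for subregional scope
#' @param crs equal-area projection identifier
#' @return tibble `country, area, share_pct` ordered by descending share
#' @export
range_shares <- function(ranges, countries, species,
                         scope = c("sub_saharan", "subregional"),
                         subregion = NULL, crs = "cea") {
  scope <- match.arg(scope)
  rg <- range_geometry(ranges, species, "nonbreeding")
  if (length(rg) == 0) stop("species ", species, " has no nonbreeding range")
  members <- dplyr::filter(countries, .data$continent == "Africa")
  if (scope == "subregional") {
    if (is.null(subregion)) stop("subregional scope needs a subregion")
    members <- dplyr::filter(members, .data$subregion == !!subregion)
  }
  pr <- geom_project(rg, crs)
  range_area <- geom_area(pr)
  areas <- vapply(members$geometry, function(cg) {
    cgp <- geom_project(cg, crs)
    a <- geom_area(geom_intersection(pr, cgp))
    if (area_positive(a, min(range_area, geom_area(cgp)))) a else 0
  }, numeric(1))
  total <- sum(areas)
  if (total <= 0) {
    stop("nonbreeding range of ", species, " does not reach the scope region")
  }
  tibble::tibble(country = members$code, area = areas,
                 share_pct = 100 * areas / total) |>
    dplyr::filter(.data$area > 0) |>
    dplyr::arrange(dplyr::desc(.data$share_pct), .data$country)
}

links_touching_country <- function(links, country, countries) {
  continent <- countries$continent[match(country, countries$code)]
  if (is.na(continent)) stop("unknown country code: ", country)
  side <- if (continent == "Europe") "breeding_country" else
    "nonbreeding_country"
  dplyr::filter(links, .data[[side]] == country)
}

#' Connectivity summary for one country
#'
#' All links touching the country (breeding side for European countries,
#' nonbreeding side for African ones), ordered by descending strength with
#' ties broken by partner country code, plus per-group counts of links,
#' species tracked and partner countries.
#'
#' @param links link tibble
#' @param country country code
#' @param countries country layer
#' @return list with `country`, `links` (ordered tibble) and `summary`
#'   (tibble `species_group, n_links, n_species_tracked,
#'   n_partner_countries`)
#' @export
country_connectivity <- function(links, country, countries) {
  continent <- countries$continent[match(country, countries$code)]
  sel <- links_touching_country(links, country, countries)
  partner <- if (identical(continent, "Europe")) "nonbreeding_country" else
    "breeding_country"
  sel <- dplyr::arrange(sel, dplyr::desc(.data$strength_pct),
                        .data[[partner]], .data$species_id)
  summary <- sel |>
    dplyr::group_by(.data$species_group) |>
    dplyr::summarise(
      n_links = dplyr::n(),
      n_species_tracked = dplyr::n_distinct(.data$species_id),
      n_partner_countries = dplyr::n_distinct(.data[[partner]]),
      .groups = "drop")
  list(country = country, links = sel, summary = summary)
}

#' Importance of each African country for a species' European population
#'
#' Each tracked population's link strengths are weighted by the share of the
#' species' total European population breeding in that country, and the
#' weighted values are summed per African country. The summed importances
#' equal the total European-population share of the tracked populations: the
#' tracked mass is redistributed, never created.
#'
#' @param links link tibble
#' @param populations population table
#' @param species species id
#' @return tibble `species_id, african_country, importance_pct` ordered by
#'   descending importance
#' @export
species_importance <- function(links, populations, species) {
  sl <- dplyr::filter(links, .data$species_id == species)
  if (nrow(sl) == 0) {
    return(tibble::tibble(species_id = character(),
                          african_country = character(),
                          importance_pct = numeric()))
  }
  shares <- population_shares(populations, species, scope = "european")
  sl |>
    dplyr::inner_join(shares, by = c(breeding_country = "country")) |>
    dplyr::group_by(african_country = .data$nonbreeding_country) |>
    dplyr::summarise(
      importance_pct = sum(.data$strength_pct / 100 * .data$share_pct),
      .groups = "drop") |>
    dplyr::mutate(species_id = species, .before = 1) |>
    dplyr::arrange(dplyr::desc(.data$importance_pct), .data$african_country)
}

#' Per-country link and tracked-species counts for mapping
#'
#' @param links link tibble
#' @param countries country layer
#' @return tibble `country, continent, n_links, n_species_tracked`, zeros
#'   for countries without links
#' @export
flyway_counts <- function(links, countries) {
  rows <- lapply(seq_len(nrow(countries)), function(i) {
    sel <- links_touching_country(links, countries$code[i], countries)
    tibble::tibble(country = countries$code[i],
                   continent = countries$continent[i],
                   n_links = nrow(sel),
                   n_species_tracked = dplyr::n_distinct(sel$species_id))
  })
  dplyr::bind_rows(rows)
}

#' Cumulative numbers of studies and links over time
#'
#' Studies are dated by publication year; a link is dated by the earliest
#' study contributing a record to its triple, and an inferred link by the
#' earliest study of its population. Studies without a year are excluded
#' with a warning (their links date from other studies, if any).
#'
#' @param records record tibble
#' @param links link tibble
#' @return tibble `year, cumulative_studies, cumulative_links`, one row per
#'   year with activity, both series non-decreasing
#' @export
cumulative_trends <- function(records, links) {
  studies <- unique(records[c("study_id", "year_published")])
  undated <- unique(studies$study_id[is.na(studies$year_published)])
  if (length(undated) > 0) {
    warning(length(undated), " study(ies) without publication year excluded ",
            "from trends: ", paste(undated, collapse = ", "))
  }
  studies <- studies[!is.na(studies$year_published), ]
  study_year <- studies |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(year = min(.data$year_published), .groups = "drop")
  dated <- dplyr::inner_join(records, study_year, by = "study_id")
  obs_year <- dated |>
    dplyr::group_by(.data$species_id, .data$breeding_country,
                    .data$nonbreeding_country) |>
    dplyr::summarise(year = min(.data$year), .groups = "drop")
  pop_year <- dated |>
    dplyr::group_by(.data$species_id, .data$breeding_country) |>
    dplyr::summarise(pop_first_year = min(.data$year), .groups = "drop")
  link_years <- links |>
    dplyr::left_join(obs_year, by = c("species_id", "breeding_country",
                                      "nonbreeding_country")) |>
    dplyr::left_join(pop_year, by = c("species_id", "breeding_country")) |>
    dplyr::mutate(year = dplyr::if_else(.data$status == "observed",
                                        .data$year, .data$pop_first_year))
  link_years <- link_years$year[!is.na(link_years$year)]
  years <- sort(unique(c(study_year$year, link_years)))
  tibble::tibble(
    year = as.integer(years),
    cumulative_studies = vapply(years, function(y)
      sum(study_year$year <= y), integer(1)),
    cumulative_links = vapply(years, function(y)
      sum(link_years <= y), integer(1)))
}

#' Fit a saturating tracking-effort curve
#'
#' Least-squares fit of a Michaelis-Menten-type curve
#' `links = a * n / (b + n)` to per-population (records, links) pairs —
#' links accumulate with records but saturate once every true nonbreeding
#' country has been sampled. Reports whether the curve reaches 95% of its
#' asymptote `a` within the observed record range (it does iff
#' `max(n) >= 19 b`).
#'
#' @param effort tibble/data.frame with columns `n_records`, `n_links`
#' @return list with `a`, `b`, `residual_se`, `reaches_95pct_asymptote`,
#'   `n_at_95pct` and the `nls` fit object
#' @export
fit_effort_curve <- function(effort) {
  stopifnot(all(c("n_records", "n_links") %in% names(effort)))
  effort <- effort[stats::complete.cases(effort[c("n_records", "n_links")]), ]
  if (nrow(effort) < 3) stop("need at least 3 populations to fit")
  if (stats::var(effort$n_records) == 0 || stats::var(effort$n_links) == 0) {
    if (stats::var(effort$n_links) == 0) {
      # flat response: the curve degenerates to its asymptote
      return(list(a = effort$n_links[1], b = 0, residual_se = 0,
                  reaches_95pct_asymptote = TRUE, n_at_95pct = 0,
                  fit = NULL, degenerate = TRUE))
    }
    stop("degenerate effort data: no variation in n_records")
  }
  # Levenberg-Marquardt on the residual function directly: with noisy or
  # nearly flat data the (a, b) pair can drift along a ridge, which is fine
  # for the ridge minimum but breaks model-object construction in nls-style
  # wrappers.
  resid_fun <- function(p) {
    effort$n_links - p["a"] * effort$n_records / (p["b"] + effort$n_records)
  }
  fit <- minpack.lm::nls.lm(
    par = c(a = max(effort$n_links) * 1.2,
            b = stats::median(effort$n_records)),
    fn = resid_fun,
    lower = c(a = 1e-9, b = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  a <- unname(fit$par["a"]); b <- unname(fit$par["b"])
  list(a = a, b = b,
       residual_se = sqrt(mean(resid_fun(fit$par)^2)),
       reaches_95pct_asymptote = max(effort$n_records) >= 19 * b,
       n_at_95pct = 19 * b,
       fit = fit, degenerate = FALSE)
}

#' Per-population tracking effort (records vs links)
#'
#' @param records retained record tibble
#' @param links link tibble
#' @return tibble `species_id, species_group, breeding_country, n_records,
#'   n_links`
#' @export
population_effort <- function(records, links) {
  nr <- records |>
    dplyr::count(.data$species_id, .data$species_group,
                 .data$breeding_country, name = "n_records")
  nl <- links |>
    dplyr::count(.data$species_id, .data$breeding_country, name = "n_links")
  dplyr::inner_join(nr, nl, by = c("species_id", "breeding_country"))
}
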