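# The link engine: migration records -> migratory links with strengths.
#
# A migratory link is a (species, European breeding country, sub-Saharan
# nonbreeding country) edge. Populations (species x breeding country) with
# fewer than the configured minimum of records are excluded; each retained
# population contributes one *observed* link per distinct nonbreeding
# country, weighted by its record count. Links likely missed by sampling are
# *inferred*: the minimum convex polygon of the nonbreeding-range centroids
# of the observed countries is intersected with the species' nonbreeding
# range in every other country, and each intersected country gains an
# inferred link whose record count is interpolated from the record density
# of neighbouring observed countries. Link strength is the percentage of the
# population's (observed + interpolated) records per nonbreeding country.

LINK_COLUMNS <- c("species_id", "species_group", "breeding_country",
                  "nonbreeding_country", "status", "record_count",
                  "strength_pct")

#' Split records into retained populations and excluded ones
#'
#' Populations (species x breeding country) with fewer than `min_n`
#' migration records are excluded from all further analysis; the cut guards
#' against single-bird populations dominating link-strength estimates.
#'
#' @param records validated record tibble
#' @param min_n minimum records per population (default 3)
#' @return list with `retained` (records of retained populations, input
#'   order preserved) and `excluded` (tibble of excluded populations with
#'   their record counts)
#' @export
filter_populations <- function(records, min_n = 3) {
  stopifnot(min_n >= 1)
  if (nrow(records) == 0) {
    return(list(retained = records,
                excluded = tibble::tibble(species_id = character(),
                                          breeding_country = character(),
                                          n_records = integer())))
  }
  counts <- records |>
    dplyr::count(.data$species_id, .data$breeding_country, name = "n_records")
  excluded <- dplyr::filter(counts, .data$n_records < min_n)
  retained <- records |>
    dplyr::anti_join(excluded, by = c("species_id", "breeding_country"))
  message("population filter (min ", min_n, " records): retained ",
          nrow(retained), "/", nrow(records), " records in ",
          nrow(counts) - nrow(excluded), " populations; excluded ",
          nrow(excluded), " populations")
  list(retained = retained, excluded = excluded)
}

#' Derive observed migratory links from retained records
#'
#' One observed link per distinct (species, breeding country, nonbreeding
#' country) triple; `record_count` is the number of individuals on the
#' triple. Strengths are left unset.
#'
#' @param records retained records (see [filter_populations()])
#' @return link tibble with `status = "observed"` and `strength_pct = NA`
#' @export
derive_observed_links <- function(records) {
  links <- records |>
    dplyr::count(.data$species_id, .data$species_group,
                 .data$breeding_country, .data$nonbreeding_country,
                 name = "record_count") |>
    dplyr::mutate(status = "observed",
                  record_count = as.numeric(.data$record_count),
                  strength_pct = NA_real_) |>
    dplyr::select(dplyr::all_of(LINK_COLUMNS))
  links
}

#' Centroid of a species' nonbreeding range within one country
#'
#' The anchor point of a migratory link on the African side: the
#' area-weighted centroid, computed in the equal-area projection, of the
#' intersection between the species' nonbreeding range and the country.
#'
#' @param range_geom nonbreeding-range geometry
#' @param country_geom country geometry
#' @param crs projection for the computation (`"cea"` or `"planar"`)
#' @return `c(x, y)` in projected coordinates, or `NULL` when the range does
#'   not reach the country
#' @export
nonbreeding_centroid <- function(range_geom, country_geom, crs = "cea") {
  inter <- geom_intersection(geom_project(range_geom, crs),
                             geom_project(country_geom, crs))
  if (geom_area(inter) == 0) return(NULL)
  geom_centroid(inter)
}

# Range-within-country geometries and centroids for a species over a country
# layer, in projected coordinates. Returns a list keyed by country code.
range_by_country <- function(range_geom, countries, crs = "cea") {
  pr <- geom_project(range_geom, crs)
  range_area <- geom_area(pr)
  out <- list()
  for (i in seq_len(nrow(countries))) {
    if (countries$continent[i] != "Africa") next
    cg <- geom_project(countries$geometry[[i]], crs)
    inter <- geom_intersection(pr, cg)
    if (area_positive(geom_area(inter), min(range_area, geom_area(cg)))) {
      out[[countries$code[i]]] <- inter
    }
  }
  out
}

#' Infer missing links for one population from the centroid hull
#'
#' Builds the minimum convex polygon of the nonbreeding centroids of the
#' population's observed countries. Every African country that (a) is not
#' already observed, (b) holds a positive-area share of the species'
#' nonbreeding range, and (c) whose within-country range geometry intersects
#' the hull (boundary contact counts) gains one inferred link. With a single
#' observed country there is nothing to interpolate between and no link is
#' inferred; with two, the hull degenerates to the segment joining the two
#' centroids.
#'
#' @param pop_links observed links of one population
#' @param range_geom the species' nonbreeding-range geometry
#' @param countries country layer
#' @param crs equal-area projection identifier
#' @return tibble of inferred links (`record_count = NA`), possibly empty
#' @export
infer_links <- function(pop_links, range_geom, countries, crs = "cea") {
  stopifnot(nrow(pop_links) >= 1, all(pop_links$status == "observed"))
  empty <- pop_links[0, ]
  observed <- pop_links$nonbreeding_country
  if (length(observed) < 2) return(empty)
  rbc <- range_by_country(range_geom, countries, crs)
  cents <- list()
  for (code in observed) {
    g <- rbc[[code]]
    cents[[code]] <- if (!is.null(g)) geom_centroid(g) else
      geom_centroid(geom_project(country_geometry(countries, code), crs))
  }
  cm <- do.call(rbind, cents)
  if (nrow(unique(cm)) < 2) return(empty)
  hull <- convex_hull(cm[, 1], cm[, 2])
  candidates <- setdiff(names(rbc), observed)
  hit <- vapply(candidates, function(code) {
    hull_intersects(hull, rbc[[code]])
  }, logical(1))
  if (!any(hit)) return(empty)
  tibble::tibble(
    species_id = pop_links$species_id[1],
    species_group = pop_links$species_group[1],
    breeding_country = pop_links$breeding_country[1],
    nonbreeding_country = sort(candidates[hit]),
    status = "inferred",
    record_count = NA_real_,
    strength_pct = NA_real_
  )
}

#' Interpolate the record count of an inferred link
#'
#' Record counts for inferred links are transferred from the record density
#' of neighbouring observed countries: for each observed country i sharing a
#' boundary with the inferred country D, `density_i = records_i / area_i`
#' where `area_i` is the species' nonbreeding-range area within i, and the
#' interpolated count is `mean(density_i) * area_D`. When no observed
#' country borders D, the two observed countries whose within-country range
#' centroids are nearest to D's serve as neighbours. Counts are kept
#' fractional.
#'
#' @param inferred_country code of the inferred country
#' @param pop_links observed links of the population
#' @param range_geom the species' nonbreeding-range geometry
#' @param countries country layer
#' @param crs equal-area projection identifier
#' @return non-negative numeric record count
#' @export
interpolate_record_count <- function(inferred_country, pop_links, range_geom,
                                     countries, crs = "cea") {
  observed <- pop_links$nonbreeding_country[pop_links$status == "observed"]
  counts <- pop_links$record_count[pop_links$status == "observed"]
  rbc <- range_by_country(range_geom, countries, crs)
  gD <- rbc[[inferred_country]]
  if (is.null(gD)) {
    stop("country ", inferred_country,
         " holds no part of the species' nonbreeding range")
  }
  target_raw <- country_geometry(countries, inferred_country)
  neigh <- observed[vapply(observed, function(code) {
    geom_adjacent(target_raw, country_geometry(countries, code))
  }, logical(1))]
  if (length(neigh) == 0) {
    cD <- geom_centroid(gD)
    dists <- vapply(observed, function(code) {
      g <- rbc[[code]]
      cc <- if (!is.null(g)) geom_centroid(g) else
        geom_centroid(geom_project(country_geometry(countries, code), crs))
      sqrt(sum((cc - cD)^2))
    }, numeric(1))
    neigh <- observed[order(dists)][seq_len(min(2, length(observed)))]
  }
  dens <- vapply(neigh, function(code) {
    g <- rbc[[code]]
    a <- if (!is.null(g)) geom_area(g) else
      geom_area(geom_project(country_geometry(countries, code), crs))
    counts[match(code, observed)] / a
  }, numeric(1))
  mean(dens) * geom_area(gD)
}

#' Turn record counts into link strengths
#'
#' Strength is the percentage of a population's records (observed or
#' interpolated) assigned to each nonbreeding country:
#' `100 * record_count / sum(record_count)`. Strengths over a population sum
#' to 100.
#'
#' @param pop_links links of one population, all with record counts
#' @return the links with `strength_pct` filled in
#' @export
compute_strengths <- function(pop_links) {
  stopifnot(!anyNA(pop_links$record_count))
  total <- sum(pop_links$record_count)
  if (total <= 0) stop("population has zero total record count")
  dplyr::mutate(pop_links,
                strength_pct = 100 * .data$record_count / total)
}

#' Run the full link engine
#'
#' Filters populations, derives observed links, infers missing links and
#' interpolates their record counts, and computes strengths, for every
#' population in the record table.
#'
#' @param records validated record tibble
#' @param countries country layer
#' @param ranges seasonal range tibble (nonbreeding season used)
#' @param config [analysis_config()]
#' @return list with `links` (full link tibble), `excluded` (populations cut
#'   by the record filter) and `n_records_retained`
#' @export
derive_links <- function(records, countries, ranges,
                         config = analysis_config()) {
  flt <- filter_populations(records, config$min_records_per_population)
  observed <- derive_observed_links(flt$retained)
  pops <- unique(observed[c("species_id", "breeding_country")])
  out <- vector("list", nrow(pops))
  for (k in seq_len(nrow(pops))) {
    pl <- observed |>
      dplyr::filter(.data$species_id == pops$species_id[k],
                    .data$breeding_country == pops$breeding_country[k])
    rg <- range_geometry(ranges, pops$species_id[k], "nonbreeding")
    inf <- if (length(rg) > 0) {
      infer_links(pl, rg, countries, config$equal_area_crs)
    } else pl[0, ]
    if (nrow(inf) > 0) {
      inf$record_count <- unname(vapply(
        inf$nonbreeding_country, function(code) {
          interpolate_record_count(code, pl, rg, countries,
                                   config$equal_area_crs)
        }, numeric(1)))
    }
    out[[k]] <- compute_strengths(dplyr::bind_rows(pl, inf))
  }
  links <- dplyr::bind_rows(out)
  if (nrow(links) == 0) links <- observed
  message("derived ", sum(links$status == "observed"), " observed and ",
          sum(links$status == "inferred"), " inferred links for ",
          nrow(pops), " populations")
  list(links = links, excluded = flt$excluded,
       n_records_retained = nrow(flt$retained))
}

#' @rdname derive_links
#' @param links link tibble
#' @param path output CSV
#' @param round_digits optional decimal places for percentages at report
#'   time (strengths are stored at full precision)
#' @export
write_links <- function(links, path, round_digits = NULL) {
  out <- links[LINK_COLUMNS]
  if (!is.null(round_digits)) {
    out$strength_pct <- round(out$strength_pct, round_digits)
    out$record_count <- round(out$record_count, round_digits)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a previously written link table
#' @param path links CSV
#' @return link tibble
#' @export
read_links <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    species_id = "character", species_group = "character",
    breeding_country = "character", nonbreeding_country = "character",
    status = "character", record_count = "numeric",
    strength_pct = "numeric"))
  tibble::as_tibble(df[LINK_COLUMNS])
}
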