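# Readers and writers for the four inputs (migration records, country layer,
# seasonal ranges, national population table) and for GeoJSON geometries.
#
# Validation is total: any row or feature violating a type invariant stops
# with an error naming the offender. Every repair/filter decision is reported
# via message() so a pipeline log records it.

# ---- GeoJSON <-> ring-list conversion ---------------------------------------

coords_to_rings <- function(poly_coords) {
  # poly_coords: list of rings, ring = list of [x, y]
  lapply(poly_coords, function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    list(x = as.numeric(m[, 1]), y = as.numeric(m[, 2]))
  })
}

geojson_geometry_to_rings <- function(geom) {
  if (is.null(geom)) return(list())
  switch(geom$type,
    Polygon = coords_to_rings(geom$coordinates),
    MultiPolygon = do.call(c, lapply(geom$coordinates, coords_to_rings)),
    stop("unsupported GeoJSON geometry type: ", geom$type)
  )
}

close_ring_coords <- function(ring) {
  xs <- c(ring$x, ring$x[1]); ys <- c(ring$y, ring$y[1])
  lapply(seq_along(xs), function(i) c(xs[i], ys[i]))
}

# Group rings into polygons-with-holes for valid GeoJSON output: rings with
# negative signed area are holes, attached to the outer ring containing their
# first vertex.
rings_to_geojson_geometry <- function(g) {
  if (length(g) == 0) {
    return(list(type = "MultiPolygon", coordinates = list()))
  }
  areas <- vapply(g, ring_signed_area, numeric(1))
  outers <- which(areas >= 0); holes <- which(areas < 0)
  polys <- lapply(outers, function(i) list(g[[i]]))
  for (h in holes) {
    p <- c(g[[h]]$x[1], g[[h]]$y[1])
    owner <- NULL
    for (k in seq_along(outers)) {
      if (point_in_geom(p, list(g[[outers[k]]]))) { owner <- k; break }
    }
    if (is.null(owner)) owner <- 1L  # orphan hole: keep with first polygon
    polys[[owner]] <- c(polys[[owner]], list(g[[h]]))
  }
  list(type = "MultiPolygon",
       coordinates = lapply(polys, function(rings)
         lapply(rings, close_ring_coords)))
}

read_feature_collection <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  fc$features
}

write_feature_collection <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

ingest_geometry <- function(geom, label) {
  g <- geojson_geometry_to_rings(geom)
  repaired <- geom_repair(g)
  if (length(repaired) != length(g)) {
    message("repaired geometry of ", label, " (", length(g), " -> ",
            length(repaired), " rings after resolving self-intersections)")
  }
  repaired
}

# ---- Migration records ------------------------------------------------------

RECORD_COLUMNS <- c("record_id", "species_id", "species_group",
                    "breeding_country", "nonbreeding_country", "device",
                    "study_id", "year_published")

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read and validate a migration-record table
#'
#' One row per tracked individual: the species, its breeding country in
#' Europe and the sub-Saharan country where it spent the nonbreeding season,
#' plus device class and source study. Each row is validated against the
#' country layer: the breeding country must be a European country of the
#' layer and the nonbreeding country an African one.
#'
#' @param path CSV or TSV file with header columns
#'   `record_id, species_id, species_group, breeding_country,
#'   nonbreeding_country, device, study_id, year_published`
#' @param countries country layer from [read_country_layer()]
#' @return tibble of validated records, input order preserved
#' @export
read_migration_records <- function(path, countries) {
  df <- utils::read.csv(path, sep = detect_sep(path),
                        colClasses = "character", strip.white = TRUE)
  missing <- setdiff(RECORD_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("record table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[RECORD_COLUMNS]
  if (nrow(df) == 0) {
    return(tibble::as_tibble(df)[0, ] |>
             dplyr::mutate(year_published = integer(0)))
  }
  dup <- duplicated(df$record_id)
  if (any(dup)) {
    stop("row ", which(dup)[1], ": duplicate record_id '",
         df$record_id[which(dup)[1]], "'")
  }
  eur <- countries$code[countries$continent == "Europe"]
  afr <- countries$code[countries$continent == "Africa"]
  for (i in seq_len(nrow(df))) {
    if (!df$species_group[i] %in% SPECIES_GROUPS) {
      stop("row ", i, ": unknown species_group '", df$species_group[i], "'")
    }
    if (!df$device[i] %in% DEVICES) {
      stop("row ", i, ": unknown device '", df$device[i], "'")
    }
    if (!df$breeding_country[i] %in% eur) {
      stop("row ", i, ": breeding_country '", df$breeding_country[i],
           "' is not a European country of the layer")
    }
    if (!df$nonbreeding_country[i] %in% afr) {
      stop("row ", i, ": nonbreeding_country '", df$nonbreeding_country[i],
           "' is not a sub-Saharan country of the layer")
    }
  }
  grp <- tapply(df$species_group, df$species_id,
                function(v) length(unique(v)))
  if (any(grp > 1)) {
    stop("species ", names(grp)[grp > 1][1],
         " appears with more than one species_group")
  }
  df$year_published <- suppressWarnings(as.integer(df$year_published))
  message("read ", nrow(df), " migration records from ", path)
  tibble::as_tibble(df)
}

#' @rdname read_migration_records
#' @param records record tibble
#' @export
write_migration_records <- function(records, path) {
  utils::write.csv(records[RECORD_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

# ---- Country layer ----------------------------------------------------------

#' Read a country boundary layer from GeoJSON
#'
#' Features must carry a `code` property (ISO 3166-1 alpha-3 in real data).
#' Continent and subregion come from `subregion_map` when supplied (a named
#' list `code -> {continent, subregion}`, e.g. [flyway_subregions()]) and
#' otherwise from the feature properties. Invalid geometries are repaired by
#' resolving self-intersections, with a message.
#'
#' @param path GeoJSON FeatureCollection (WGS84 lon/lat)
#' @param subregion_map optional mapping; a feature whose code is missing
#'   from it is an error
#' @return tibble with columns `code`, `name`, `continent`, `subregion` and a
#'   `geometry` list-column of ring lists
#' @export
read_country_layer <- function(path, subregion_map = NULL) {
  if (!is.null(subregion_map)) validate_subregion_map(subregion_map)
  feats <- read_feature_collection(path)
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    code <- f$properties$code
    if (is.null(code)) stop("feature ", i, " lacks a 'code' property")
    if (!is.null(subregion_map)) {
      if (is.null(subregion_map[[code]])) {
        stop("country code '", code, "' (feature ", i,
             ") is absent from the subregion map")
      }
      continent <- subregion_map[[code]]$continent
      subregion <- subregion_map[[code]]$subregion
    } else {
      continent <- f$properties$continent
      subregion <- f$properties$subregion
      if (is.null(continent) || is.null(subregion)) {
        stop("feature ", i, " (", code, ") lacks continent/subregion and no ",
             "subregion map was supplied")
      }
    }
    list(code = code,
         name = if (is.null(f$properties$name)) code else f$properties$name,
         continent = continent, subregion = subregion,
         geometry = list(ingest_geometry(f$geometry, paste0("country ", code))))
  })
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  if (anyDuplicated(out$code)) {
    stop("duplicate country code: ", out$code[duplicated(out$code)][1])
  }
  message("read country layer of ", nrow(out), " countries from ", path)
  out
}

country_feature <- function(code, name, continent, subregion, geometry) {
  list(type = "Feature",
       properties = list(code = code, name = name, continent = continent,
                         subregion = subregion),
       geometry = rings_to_geojson_geometry(geometry))
}

#' @rdname read_country_layer
#' @param countries country-layer tibble
#' @export
write_country_layer <- function(countries, path) {
  feats <- lapply(seq_len(nrow(countries)), function(i) {
    country_feature(countries$code[i], countries$name[i],
                    countries$continent[i], countries$subregion[i],
                    countries$geometry[[i]])
  })
  write_feature_collection(feats, path)
}

country_geometry <- function(countries, code) {
  i <- match(code, countries$code)
  if (is.na(i)) stop("unknown country code: ", code)
  countries$geometry[[i]]
}

# ---- Species ranges ---------------------------------------------------------

#' Read per-species seasonal range polygons from GeoJSON
#'
#' Features carry `species_id` and `season` (breeding / nonbreeding /
#' resident) properties; at most one feature per (species, season).
#'
#' @param path GeoJSON FeatureCollection
#' @return tibble with `species_id`, `season` and a `geometry` list-column
#' @export
read_species_ranges <- function(path) {
  feats <- read_feature_collection(path)
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    sp <- f$properties$species_id; season <- f$properties$season
    if (is.null(sp) || is.null(season)) {
      stop("range feature ", i, " lacks species_id/season")
    }
    if (!season %in% SEASONS) {
      stop("range feature ", i, " (", sp, "): unknown season '", season, "'")
    }
    list(species_id = sp, season = season,
         geometry = list(ingest_geometry(
           f$geometry, paste0(sp, " ", season, " range"))))
  })
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  if (nrow(out) > 0 && anyDuplicated(out[c("species_id", "season")])) {
    stop("duplicate (species, season) range feature")
  }
  message("read ", nrow(out), " seasonal range layers from ", path)
  out
}

#' @rdname read_species_ranges
#' @param ranges range tibble
#' @export
write_species_ranges <- function(ranges, path) {
  feats <- lapply(seq_len(nrow(ranges)), function(i) {
    list(type = "Feature",
         properties = list(species_id = ranges$species_id[i],
                           season = ranges$season[i]),
         geometry = rings_to_geojson_geometry(ranges$geometry[[i]]))
  })
  write_feature_collection(feats, path)
}

range_geometry <- function(ranges, species, season = "nonbreeding") {
  i <- which(ranges$species_id == species & ranges$season == season)
  if (length(i) == 0) return(list())
  ranges$geometry[[i]]
}

# ---- Population table -------------------------------------------------------

POPULATION_COLUMNS <- c("species_id", "country", "pop_size", "trend",
                        "species_group")

#' Read and validate the national breeding-population table
#'
#' One row per species x European breeding country with the national
#' population size estimate, the European-level trend flag (`decreasing` or
#' `other`, constant within a species) and the species group (`landbird` or
#' `raptor`, used by the gap and priority analyses where untracked species
#' must still be classified).
#'
#' @param path CSV with columns `species_id, country, pop_size, trend,
#'   species_group`
#' @return tibble, one row per (species, country)
#' @export
read_population_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    species_id = "character", country = "character", pop_size = "numeric",
    trend = "character", species_group = "character"))
  missing <- setdiff(POPULATION_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("population table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[POPULATION_COLUMNS]
  for (i in seq_len(nrow(df))) {
    if (is.na(df$pop_size[i]) || df$pop_size[i] < 0) {
      stop("row ", i, ": pop_size must be a non-negative number")
    }
    if (!df$trend[i] %in% c("decreasing", "other")) {
      stop("row ", i, ": unknown trend '", df$trend[i], "'")
    }
    if (!df$species_group[i] %in% SPECIES_GROUPS) {
      stop("row ", i, ": unknown species_group '", df$species_group[i], "'")
    }
  }
  if (anyDuplicated(df[c("species_id", "country")])) {
    stop("duplicate (species_id, country) population entry")
  }
  tr <- tapply(df$trend, df$species_id, function(v) length(unique(v)))
  if (any(tr > 1)) {
    stop("species ", names(tr)[tr > 1][1],
         " has inconsistent trend flags (trend is a European-level attribute)")
  }
  message("read ", nrow(df), " population entries from ", path)
  tibble::as_tibble(df)
}

#' @rdname read_population_table
#' @param populations population tibble
#' @export
write_population_table <- function(populations, path) {
  utils::write.csv(populations[POPULATION_COLUMNS], path, row.names = FALSE)
  invisible(path)
}
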