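# Synthetic-world generator: abstract continents, Voronoi countries,
# species ranges, national populations, true connectivity and sampled
# tracking records, statistically shaped like the real flyway dataset but
# fully seeded and download-free.
#
# Seeds are split hierarchically (world / species / truth / records) so that
# changing, say, the number of species never perturbs the country layer.

SEED_SPLIT <- c(world = 0L, species = 1000003L, truth = 2000003L,
                records = 3000003L)

split_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) + SEED_SPLIT[[stage]]
}

#' Parameters of the synthetic flyway
#'
#' Defaults emulate the structure of the real compiled dataset at reduced
#' scale: two continents of Voronoi countries, a 3:1 landbird:raptor species
#' ratio, about a third of species with decreasing European trend,
#' log-normal national population sizes, Dirichlet-distributed true
#' nonbreeding proportions, per-population sample sizes with substantial
#' mass below 3 records (so the population filter is exercised), and
#' tracking effort biased toward western/central Europe and toward raptors.
#'
#' @param n_countries_europe,n_countries_africa countries per continent
#'   (at least 4 each, one per subregion quadrant)
#' @param n_landbirds,n_raptors species per group
#' @param breeding_lambda,nonbreeding_lambda Poisson rates; a species'
#'   range is a contiguous union of `1 + rpois(lambda)` countries
#' @param hole_prob probability that a nonbreeding range of 4+ countries
#'   loses one interior country (a geometric gap for inference to fill)
#' @param pop_meanlog,pop_sdlog log-normal national population size
#' @param decreasing_fraction fraction of species flagged decreasing
#' @param dirichlet_alpha concentration of true nonbreeding proportions
#' @param track_prob baseline probability a population is tracked at all
#' @param effort_bias_subregion named multipliers on `track_prob` per
#'   European subregion
#' @param effort_bias_group named multipliers per species group
#' @param sample_mu,sample_size negative-binomial mean and dispersion of the
#'   per-population record count
#' @param europe_bbox,africa_bbox lon/lat rectangles
#'   `c(xmin, xmax, ymin, ymax)` of the two continents
#' @return parameter list
#' @export
simulation_params <- function(n_countries_europe = 14,
                              n_countries_africa = 14,
                              n_landbirds = 18, n_raptors = 6,
                              breeding_lambda = 2.5,
                              nonbreeding_lambda = 3.5,
                              hole_prob = 0.15,
                              pop_meanlog = 10, pop_sdlog = 1.5,
                              decreasing_fraction = 0.32,
                              dirichlet_alpha = 0.8,
                              track_prob = 0.35,
                              effort_bias_subregion = c(
                                "western Europe" = 1.3,
                                "central Europe" = 1.3,
                                "northern Europe" = 1.0,
                                "eastern Europe" = 0.5),
                              effort_bias_group = c(landbird = 0.9,
                                                    raptor = 1.2),
                              sample_mu = 8, sample_size = 1.2,
                              europe_bbox = c(-10, 30, 36, 60),
                              africa_bbox = c(-15, 45, -30, 10)) {
  stopifnot(n_countries_europe >= 4, n_countries_africa >= 4,
            n_landbirds + n_raptors >= 1,
            hole_prob >= 0, hole_prob <= 1,
            decreasing_fraction >= 0, decreasing_fraction <= 1,
            dirichlet_alpha > 0, sample_mu > 0, sample_size > 0)
  as.list(environment())
}

# Voronoi tessellation of a rectangle into n contiguous countries; subregion
# assigned by the quadrant of each seed point.
tessellate_continent <- function(n, bbox, continent, code_prefix,
                                 subregion_names) {
  px <- stats::runif(n, bbox[1], bbox[2])
  py <- stats::runif(n, bbox[3], bbox[4])
  dd <- deldir::deldir(px, py, rw = bbox)
  tiles <- deldir::tile.list(dd)
  midx <- mean(bbox[1:2]); midy <- mean(bbox[3:4])
  quadrant <- function(x, y) {
    if (x < midx) { if (y < midy) 1L else 2L } else {
      if (y < midy) 3L else 4L }
  }
  rows <- lapply(seq_len(n), function(i) {
    ring <- list(x = as.numeric(tiles[[i]]$x), y = as.numeric(tiles[[i]]$y))
    code <- sprintf("%s%02d", code_prefix, i)
    tibble::tibble(
      code = code, name = paste("Country", code), continent = continent,
      subregion = subregion_names[quadrant(px[i], py[i])],
      geometry = list(geom_repair(list(ring))))
  })
  dplyr::bind_rows(rows)
}

#' Generate the synthetic country layer
#'
#' Two disjoint rectangular continents, each tessellated into contiguous
#' Voronoi countries around uniformly seeded points and assigned subregions
#' by quadrant. Deterministic under the seed.
#'
#' @param params [simulation_params()]
#' @param seed integer seed
#' @return list with `countries` (country-layer tibble), the two bboxes and
#'   a country adjacency matrix
#' @export
generate_world <- function(params = simulation_params(), seed = 1L) {
  set.seed(split_seed(seed, "world"))
  # quadrant order: (W,S), (W,N), (E,S), (E,N)
  eur <- tessellate_continent(
    params$n_countries_europe, params$europe_bbox, "Europe", "E",
    c("western Europe", "northern Europe", "central Europe",
      "eastern Europe"))
  afr <- tessellate_continent(
    params$n_countries_africa, params$africa_bbox, "Africa", "A",
    c("western Africa", "central Africa", "southern Africa",
      "eastern Africa"))
  countries <- dplyr::bind_rows(eur, afr)
  n <- nrow(countries)
  adj <- matrix(FALSE, n, n, dimnames = list(countries$code, countries$code))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (countries$continent[i] != countries$continent[j]) next
      ok <- geom_adjacent(countries$geometry[[i]], countries$geometry[[j]])
      adj[i, j] <- ok; adj[j, i] <- ok
    }
  }
  list(countries = countries, europe_bbox = params$europe_bbox,
       africa_bbox = params$africa_bbox, adjacency = adj)
}

# Grow a contiguous set of k countries from a random start on the adjacency
# graph (codes restricted to one continent).
grow_contiguous <- function(codes, adjacency, k) {
  start <- sample(codes, 1)
  members <- start
  while (length(members) < min(k, length(codes))) {
    frontier <- setdiff(
      codes[apply(adjacency[members, codes, drop = FALSE], 2, any)],
      members)
    if (length(frontier) == 0) break
    members <- c(members, sample(frontier, 1))
  }
  members
}

#' Generate species, ranges, populations and trends
#'
#' Each species receives a breeding range (contiguous union of European
#' countries), a nonbreeding range (contiguous union of African countries,
#' optionally with one interior country removed to create a gap),
#' log-normal national population sizes for every breeding country, and a
#' European-level trend flag.
#'
#' @param world output of [generate_world()]
#' @param params [simulation_params()]
#' @param seed integer seed
#' @return list with `ranges` (tibble), `populations` (tibble) and
#'   `species` (tibble `species_id, species_group, breeding_countries,
#'   nonbreeding_countries` list-columns)
#' @export
generate_species <- function(world, params = simulation_params(),
                             seed = 1L) {
  set.seed(split_seed(seed, "species"))
  countries <- world$countries
  eur <- countries$code[countries$continent == "Europe"]
  afr <- countries$code[countries$continent == "Africa"]
  n_sp <- params$n_landbirds + params$n_raptors
  ids <- sprintf("SP%03d", seq_len(n_sp))
  groups <- c(rep("landbird", params$n_landbirds),
              rep("raptor", params$n_raptors))
  geom_of <- function(code) country_geometry(countries, code)
  sp_rows <- list(); range_rows <- list(); pop_rows <- list()
  for (s in seq_len(n_sp)) {
    kb <- 1 + stats::rpois(1, params$breeding_lambda)
    kn <- 1 + stats::rpois(1, params$nonbreeding_lambda)
    bc <- grow_contiguous(eur, world$adjacency, kb)
    nc <- grow_contiguous(afr, world$adjacency, kn)
    if (length(nc) >= 4 && stats::runif(1) < params$hole_prob) {
      # drop an interior member (not the first-grown seed) to carve a gap
      nc <- setdiff(nc, sample(nc[-1], 1))
    }
    trend <- if (stats::runif(1) < params$decreasing_fraction)
      "decreasing" else "other"
    range_rows[[length(range_rows) + 1L]] <- tibble::tibble(
      species_id = ids[s], season = "breeding",
      geometry = list(geom_union_all(lapply(bc, geom_of))))
    range_rows[[length(range_rows) + 1L]] <- tibble::tibble(
      species_id = ids[s], season = "nonbreeding",
      geometry = list(geom_union_all(lapply(nc, geom_of))))
    pop_rows[[length(pop_rows) + 1L]] <- tibble::tibble(
      species_id = ids[s], country = bc,
      pop_size = stats::rlnorm(length(bc), params$pop_meanlog,
                               params$pop_sdlog),
      trend = trend, species_group = groups[s])
    sp_rows[[length(sp_rows) + 1L]] <- tibble::tibble(
      species_id = ids[s], species_group = groups[s],
      breeding_countries = list(bc), nonbreeding_countries = list(nc))
  }
  list(ranges = dplyr::bind_rows(range_rows),
       populations = dplyr::bind_rows(pop_rows),
       species = dplyr::bind_rows(sp_rows))
}

#' Generate true connectivity proportions per population
#'
#' For every population (species x breeding country) the true proportions of
#' individuals wintering in each country of the species' nonbreeding range
#' are drawn from a symmetric Dirichlet; the support never leaves the range,
#' so inferred links can never point outside it.
#'
#' @param species_info output of [generate_species()]
#' @param params [simulation_params()]
#' @param seed integer seed
#' @return tibble `species_id, breeding_country, nonbreeding_country,
#'   proportion` (proportions sum to 1 per population)
#' @export
generate_truth <- function(species_info, params = simulation_params(),
                           seed = 1L) {
  set.seed(split_seed(seed, "truth"))
  rows <- list()
  sp <- species_info$species
  for (s in seq_len(nrow(sp))) {
    nc <- sp$nonbreeding_countries[[s]]
    for (bc in sp$breeding_countries[[s]]) {
      g <- stats::rgamma(length(nc), shape = params$dirichlet_alpha)
      if (sum(g) == 0) g <- rep(1, length(nc))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        species_id = sp$species_id[s], species_group = sp$species_group[s],
        breeding_country = bc, nonbreeding_country = nc,
        proportion = g / sum(g))
    }
  }
  dplyr::bind_rows(rows)
}

#' Sample migration records from true connectivity
#'
#' Each population is tracked with a probability shaped by the effort biases
#' (subregion of the breeding country, species group); a tracked population
#' contributes a negative-binomial number of records (or exactly
#' `n_per_population` when given), each record an i.i.d. multinomial draw of
#' a nonbreeding country from the true proportions. Device class and study
#' year are drawn to mirror the field's history: raptors tracked earlier and
#' with satellite tags, landbirds mostly with geolocators after 2010.
#'
#' @param truth output of [generate_truth()]
#' @param world output of [generate_world()]
#' @param params [simulation_params()]
#' @param seed integer seed
#' @param n_per_population if non-NULL, every population is tracked with
#'   exactly this many records (used by recovery experiments)
#' @return record tibble in the [read_migration_records()] schema
#' @export
sample_records <- function(truth, world, params = simulation_params(),
                           seed = 1L, n_per_population = NULL) {
  set.seed(split_seed(seed, "records"))
  countries <- world$countries
  pops <- truth |>
    dplyr::distinct(.data$species_id, .data$species_group,
                    .data$breeding_country)
  rows <- list()
  rec <- 0L
  for (k in seq_len(nrow(pops))) {
    sub <- countries$subregion[match(pops$breeding_country[k],
                                     countries$code)]
    grp <- pops$species_group[k]
    if (is.null(n_per_population)) {
      p_track <- min(1, params$track_prob *
                       params$effort_bias_subregion[[sub]] *
                       params$effort_bias_group[[grp]])
      if (stats::runif(1) > p_track) next
      n <- stats::rnbinom(1, size = params$sample_size,
                          mu = params$sample_mu)
    } else {
      n <- n_per_population
    }
    if (n == 0) next
    tr <- truth |>
      dplyr::filter(.data$species_id == pops$species_id[k],
                    .data$breeding_country == pops$breeding_country[k])
    draws <- stats::rmultinom(1, n, tr$proportion)[, 1]
    dest <- rep(tr$nonbreeding_country, draws)
    year <- if (grp == "raptor") {
      sample(1996:2021, 1)
    } else {
      sample(c(1996:2009, rep(2010:2021, 4)), 1)
    }
    device <- if (grp == "raptor") {
      sample(c("PTT", "GPS"), 1)
    } else {
      sample(c("GLS", "GLS", "GLS", "GPS"), 1)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      record_id = sprintf("R%06d", rec + seq_len(n)),
      species_id = pops$species_id[k], species_group = grp,
      breeding_country = pops$breeding_country[k],
      nonbreeding_country = dest, device = device,
      study_id = paste0("ST_", pops$species_id[k], "_",
                        pops$breeding_country[k]),
      year_published = as.integer(year))
    rec <- rec + n
  }
  if (length(rows) == 0) {
    return(tibble::tibble(record_id = character(), species_id = character(),
                          species_group = character(),
                          breeding_country = character(),
                          nonbreeding_country = character(),
                          device = character(), study_id = character(),
                          year_published = integer()))
  }
  dplyr::bind_rows(rows)
}

#' Simulate a complete synthetic flyway dataset
#'
#' Chains world, species, truth and record generation, and optionally writes
#' the four input files (plus a config YAML with the generated subregion
#' map) in exactly the formats the readers accept, so the synthetic path is
#' byte-compatible with the real one.
#'
#' @param params [simulation_params()]
#' @param seed integer seed
#' @param out_dir if non-NULL, directory to write `records.csv`,
#'   `countries.geojson`, `ranges.geojson`, `populations.csv`, `config.yaml`
#' @return list with `world`, `species`, `ranges`, `populations`, `truth`,
#'   `records`, `config` and (if written) `paths`
#' @export
simulate_flyway <- function(params = simulation_params(), seed = 1L,
                            out_dir = NULL) {
  world <- generate_world(params, seed)
  spx <- generate_species(world, params, seed)
  truth <- generate_truth(spx, params, seed)
  records <- sample_records(truth, world, params, seed)
  config <- analysis_config(random_seed = seed)
  out <- list(world = world, species = spx$species, ranges = spx$ranges,
              populations = spx$populations, truth = truth,
              records = records, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      records = file.path(out_dir, "records.csv"),
      countries = file.path(out_dir, "countries.geojson"),
      ranges = file.path(out_dir, "ranges.geojson"),
      populations = file.path(out_dir, "populations.csv"),
      config = file.path(out_dir, "config.yaml"))
    write_migration_records(records, paths$records)
    write_country_layer(world$countries, paths$countries)
    write_species_ranges(spx$ranges, paths$ranges)
    write_population_table(spx$populations, paths$populations)
    submap <- stats::setNames(lapply(seq_len(nrow(world$countries)),
      function(i) list(continent = world$countries$continent[i],
                       subregion = world$countries$subregion[i])),
      world$countries$code)
    yaml::write_yaml(list(
      min_records_per_population = config$min_records_per_population,
      coverage_threshold_pct = config$coverage_threshold_pct,
      equal_area_crs = config$equal_area_crs,
      random_seed = config$random_seed,
      subregions = submap), paths$config)
    out$paths <- paths
  }
  out
}

#' True strengths of a population, for comparison with estimates
#' @keywords internal
true_strengths <- function(truth, species, breeding_country) {
  tr <- truth[truth$species_id == species &
                truth$breeding_country == breeding_country, ]
  stats::setNames(100 * tr$proportion, tr$nonbreeding_country)
}

#' End-to-end recovery experiment for the strength estimator
#'
#' Fixes one synthetic world and its true connectivity, then repeatedly
#' re-samples `n_per_population` records per population and runs the full
#' link engine, measuring per population the maximum absolute error between
#' estimated and true strengths (over the union of true-support and linked
#' countries) and the fraction of true-support countries recovered
#' (observed or inferred).
#'
#' @param params [simulation_params()]
#' @param n_reps number of record re-samples
#' @param n_per_population records per population in each replicate
#' @param seed integer seed (world and truth derive from it; replicate r
#'   samples records with seed `seed + r`)
#' @return tibble `rep, species_id, breeding_country, max_abs_error_pct,
#'   support_recovered_frac`
#' @export
recovery_experiment <- function(params = simulation_params(), n_reps = 20,
                                n_per_population = 100, seed = 1L) {
  world <- generate_world(params, seed)
  spx <- generate_species(world, params, seed)
  truth <- generate_truth(spx, params, seed)
  config <- analysis_config(random_seed = seed)
  rows <- list()
  for (r in seq_len(n_reps)) {
    records <- sample_records(truth, world, params, seed = seed + r,
                              n_per_population = n_per_population)
    res <- suppressMessages(
      derive_links(records, world$countries, spx$ranges, config))
    pops <- unique(res$links[c("species_id", "breeding_country")])
    for (k in seq_len(nrow(pops))) {
      est <- res$links |>
        dplyr::filter(.data$species_id == pops$species_id[k],
                      .data$breeding_country == pops$breeding_country[k])
      tru <- true_strengths(truth, pops$species_id[k],
                            pops$breeding_country[k])
      all_c <- union(names(tru), est$nonbreeding_country)
      est_v <- stats::setNames(rep(0, length(all_c)), all_c)
      est_v[est$nonbreeding_country] <- est$strength_pct
      tru_v <- stats::setNames(rep(0, length(all_c)), all_c)
      tru_v[names(tru)] <- tru
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rep = r, species_id = pops$species_id[k],
        breeding_country = pops$breeding_country[k],
        max_abs_error_pct = max(abs(est_v - tru_v)),
        support_recovered_frac =
          mean(names(tru) %in% est$nonbreeding_country))
    }
  }
  dplyr::bind_rows(rows)
}
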