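# Pipeline front end: chains the stages over in-memory objects or files,
# writes deterministic CSV outputs and a run manifest.

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

file_digests <- function(paths) {
  paths <- unlist(paths)
  stats::setNames(as.list(unname(tools::md5sum(paths))), basename(paths))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — link engine, syntheses
#' (flyway counts, country summaries, species importance, cumulative
#' trends), knowledge gaps and priority selection — and writes one CSV per
#' output plus a `manifest.json` recording the configuration digest, input
#' and output file digests and stage timings. Re-running with identical
#' inputs and configuration reproduces byte-identical outputs.
#'
#' @param records record tibble
#' @param countries country layer
#' @param ranges seasonal range tibble
#' @param populations population table
#' @param config [analysis_config()]
#' @param out_dir output directory (created if needed)
#' @param input_paths optional named list of source file paths, digested
#'   into the manifest
#' @param round_digits optional decimal places applied to percentages in the
#'   emitted tables (storage stays full precision in memory)
#' @return invisible list with all stage outputs and the manifest
#' @export
run_pipeline <- function(records, countries, ranges, populations,
                         config = analysis_config(), out_dir,
                         input_paths = NULL, round_digits = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  rnd <- function(x, cols) {
    if (is.null(round_digits)) return(x)
    for (cl in intersect(cols, names(x))) {
      x[[cl]] <- round(x[[cl]], round_digits)
    }
    x
  }
  written <- character()
  emit <- function(df, name, pct_cols = character()) {
    path <- file.path(out_dir, name)
    utils::write.csv(rnd(df, pct_cols), path, row.names = FALSE)
    written <<- c(written, path)
    path
  }

  t0 <- tic()
  linkres <- derive_links(records, countries, ranges, config)
  links <- linkres$links
  timings$links <- tic() - t0
  emit(links, "links.csv", c("strength_pct", "record_count"))
  emit(linkres$excluded, "excluded_populations.csv")

  t0 <- tic()
  emit(flyway_counts(links, countries), "flyway_counts.csv")
  summaries <- lapply(countries$code, function(code) {
    cc <- country_connectivity(links, code, countries)
    if (nrow(cc$summary) == 0) return(NULL)
    dplyr::mutate(cc$summary, country = code, .before = 1)
  })
  emit(dplyr::bind_rows(summaries), "country_summary.csv")
  importance <- dplyr::bind_rows(lapply(unique(links$species_id),
    function(sp) species_importance(links, populations, sp)))
  emit(importance, "species_importance.csv", "importance_pct")
  trends <- suppressWarnings(cumulative_trends(records, links))
  emit(trends, "trend_series.csv")
  timings$synthesize <- tic() - t0

  t0 <- tic()
  flt <- suppressMessages(
    filter_populations(records, config$min_records_per_population))
  gaps <- suppressWarnings(
    knowledge_gaps(links, populations, ranges, countries,
                   config$equal_area_crs))
  emit(gaps, "gaps.csv", "gap_pct")
  timings$gaps <- tic() - t0

  t0 <- tic()
  atlas <- priority_atlas(links, populations, ranges, countries, config)
  emit(atlas$combos, "priorities.csv",
       c("share_pct", "coverage_before", "coverage_after"))
  emit(atlas$counts, "priority_counts.csv")
  timings$priorities <- tic() - t0

  manifest <- list(
    tool = "flywaylinks",
    version = as.character(utils::packageVersion("flywaylinks")),
    config = unclass(config),
    config_digest = config_digest(config),
    input_digests = if (is.null(input_paths)) NULL else
      file_digests(input_paths),
    n_records = nrow(records),
    n_records_retained = linkres$n_records_retained,
    stage_timings_sec = lapply(timings, function(x) round(x, 3)),
    outputs = file_digests(written))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(links = links, excluded = linkres$excluded,
                 n_records_retained = linkres$n_records_retained,
                 importance = importance, trends = trends, gaps = gaps,
                 atlas = atlas, manifest = manifest))
}

#' Run the pipeline from files
#'
#' File-path front end over [run_pipeline()]: reads the four inputs (and
#' optionally a config YAML with a subregion map) and runs every stage.
#'
#' @param records_path,countries_path,ranges_path,populations_path input
#'   files in the formats of the `read_*` functions
#' @param config_path optional YAML ([read_analysis_config()])
#' @param out_dir output directory
#' @param round_digits optional decimal places for emitted percentages
#' @return invisible list as for [run_pipeline()]
#' @export
run_pipeline_files <- function(records_path, countries_path, ranges_path,
                               populations_path, config_path = NULL,
                               out_dir, round_digits = NULL) {
  if (!is.null(config_path)) {
    cfg <- read_analysis_config(config_path)
    config <- cfg$config; submap <- cfg$subregion_map
  } else {
    config <- analysis_config(); submap <- NULL
  }
  countries <- read_country_layer(countries_path, submap)
  records <- read_migration_records(records_path, countries)
  ranges <- read_species_ranges(ranges_path)
  populations <- read_population_table(populations_path)
  run_pipeline(records, countries, ranges, populations, config, out_dir,
               input_paths = list(records_path, countries_path, ranges_path,
                                  populations_path),
               round_digits = round_digits)
}

#' Summarise a deposited migration-record (and link) table
#'
#' Computes the headline counts of the compiled real dataset from its
#' deposited files: total and retained records, retained populations,
#' observed links, records per European subregion, and — when the deposited
#' link table (observed plus inferred links) is supplied — the mean number
#' of links per European country. Works on any files in the package's
#' record/link schemas; the real deposited tables are a separate download
#' and are not shipped here.
#'
#' @param records_path deposited record CSV
#' @param countries country layer covering all referenced codes
#' @param links_path optional deposited link CSV
#' @param min_n population filter threshold
#' @return list of summary numbers
#' @export
deposited_dataset_summary <- function(records_path, countries,
                                      links_path = NULL, min_n = 3) {
  records <- read_migration_records(records_path, countries)
  flt <- filter_populations(records, min_n)
  obs <- derive_observed_links(flt$retained)
  sub_of <- countries$subregion[match(flt$retained$breeding_country,
                                      countries$code)]
  out <- list(
    n_records_total = nrow(records),
    n_records_retained = nrow(flt$retained),
    n_populations = nrow(unique(flt$retained[c("species_id",
                                               "breeding_country")])),
    n_observed_links = nrow(obs),
    records_per_subregion = table(sub_of))
  if (!is.null(links_path)) {
    links <- read_links(links_path)
    per_country <- links |>
      dplyr::count(.data$breeding_country)
    out$n_links_total <- nrow(links)
    out$mean_links_per_european_country <- mean(per_country$n)
  }
  out
}
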