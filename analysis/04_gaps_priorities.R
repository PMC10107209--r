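#!/usr/bin/env Rscript
# Stage 4: knowledge gaps (share of present species without links, per
# country and group) and the priority species-country combinations needed
# to cover at least 50% of each decreasing species' subregional populations.

suppressMessages(library(flywaylinks))
ind <- "results/synthetic_inputs"

cfg <- read_analysis_config(file.path(ind, "config.yaml"))
countries <- read_country_layer(file.path(ind, "countries.geojson"),
                                cfg$subregion_map)
populations <- read_population_table(file.path(ind, "populations.csv"))
ranges <- read_species_ranges(file.path(ind, "ranges.geojson"))
links <- read_links("results/links.csv")

gaps <- knowledge_gaps(links, populations, ranges, countries,
                       cfg$config$equal_area_crs)
utils::write.csv(gaps, "results/gaps.csv", row.names = FALSE)
cat("knowledge gaps (mean % of present species untracked):\n")
for (cont in c("Europe", "Africa")) {
  for (grp in c("landbird", "raptor")) {
    sel <- gaps[gaps$continent == cont & gaps$species_group == grp, ]
    if (nrow(sel) > 0) {
      cat(" ", cont, grp, ":", round(mean(sel$gap_pct), 1), "%\n")
    }
  }
}

atlas <- priority_atlas(links, populations, ranges, countries, cfg$config)
utils::write.csv(atlas$combos, "results/priorities.csv", row.names = FALSE)
utils::write.csv(atlas$counts, "results/priority_counts.csv",
                 row.names = FALSE)
cat("priorities:", nrow(atlas$combos),
    "species-country combinations for future tracking\n")
if (nrow(atlas$counts) > 0) {
  topc <- atlas$counts[order(-atlas$counts$n_priority_species), ][1, ]
  cat("  most-needed country:", topc$country, "(",
      topc$n_priority_species, "priority species )\n")
}
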