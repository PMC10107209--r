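#!/usr/bin/env Rscript
# Stage 2: migration records -> migratory links.
#
# Populations with fewer than 3 records are excluded; observed links are the
# distinct (species, breeding country, nonbreeding country) triples of the
# retained records; missing links are inferred from the convex hull of the
# nonbreeding-range centroids and given record counts interpolated from
# neighbouring-country record densities; strengths are per-population record
# percentages. Reads the files written by stage 1.

suppressMessages(library(flywaylinks))
ind <- "results/synthetic_inputs"

cfg <- read_analysis_config(file.path(ind, "config.yaml"))
countries <- read_country_layer(file.path(ind, "countries.geojson"),
                                cfg$subregion_map)
records <- read_migration_records(file.path(ind, "records.csv"), countries)
ranges <- read_species_ranges(file.path(ind, "ranges.geojson"))

res <- derive_links(records, countries, ranges, cfg$config)
write_links(res$links, "results/links.csv")
utils::write.csv(res$excluded, "results/excluded_populations.csv",
                 row.names = FALSE)

links <- res$links
n_pops <- nrow(unique(links[c("species_id", "breeding_country")]))
cat("\nlink engine summary:\n")
cat("  records retained:", res$n_records_retained, "of", nrow(records),
    "in", n_pops, "populations\n")
cat("  links:", sum(links$status == "observed"), "observed +",
    sum(links$status == "inferred"), "inferred =", nrow(links), "\n")
cat("  mean links per population:",
    round(nrow(links) / n_pops, 1), "\n")
cat("  strengths sum to 100 per population: max deviation",
    format(max(abs(tapply(links$strength_pct,
                          paste(links$species_id, links$breeding_country),
                          sum) - 100)), digits = 3), "\n")
cat("links written to results/links.csv\n")
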