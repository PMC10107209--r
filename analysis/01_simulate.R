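#!/usr/bin/env Rscript
# Stage 1: generate the synthetic flyway used by the downstream stages.
#
# Two rectangular continents are tessellated into Voronoi countries, species
# receive contiguous breeding/nonbreeding ranges and national population
# sizes, true per-population nonbreeding proportions are drawn from a
# Dirichlet, and tracking records are sampled under western/central-Europe
# and raptor effort biases. The four input files land in
# results/synthetic_inputs/ in the same formats real data would use.
#
# Usage: Rscript analysis/01_simulate.R [--seed <int>]

suppressMessages(library(flywaylinks))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args)
  args[which(args == "--seed") + 1] else "1")

params <- simulation_params()
sim <- simulate_flyway(params, seed = seed,
                       out_dir = "results/synthetic_inputs")

cat("synthetic flyway (seed ", seed, "):\n", sep = "")
cat("  countries:   ", nrow(sim$world$countries), " (",
    sum(sim$world$countries$continent == "Europe"), " European, ",
    sum(sim$world$countries$continent == "Africa"), " African)\n", sep = "")
cat("  species:     ", nrow(sim$species), " (",
    sum(sim$species$species_group == "landbird"), " landbirds, ",
    sum(sim$species$species_group == "raptor"), " raptors)\n", sep = "")
cat("  populations: ", nrow(unique(sim$truth[c("species_id",
                                               "breeding_country")])),
    " candidate, of which ",
    nrow(unique(sim$records[c("species_id", "breeding_country")])),
    " tracked\n", sep = "")
cat("  records:     ", nrow(sim$records), "\n", sep = "")
cat("inputs written to results/synthetic_inputs/\n")
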