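#!/usr/bin/env Rscript
# Stage 5: validation of the strength estimator end to end. One synthetic
# world and its true connectivity are fixed; records are re-sampled at
# several per-population sample sizes and the maximum absolute error of
# estimated vs true strengths is measured across replicates, together with
# the fraction of true nonbreeding countries recovered.
#
# Usage: Rscript analysis/05_recovery.R [--seed <int>]

suppressMessages(library(flywaylinks))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args)
  args[which(args == "--seed") + 1] else "1")

params <- simulation_params(n_countries_europe = 6, n_countries_africa = 8,
                            n_landbirds = 2, n_raptors = 1, track_prob = 1)

cat("strength recovery vs per-population sample size",
    "(median over replicates):\n")
rows <- list()
for (n in c(3, 10, 50, 500)) {
  reps <- if (n == 500) 200 else 50
  rec <- recovery_experiment(params, n_reps = reps, n_per_population = n,
                             seed = seed)
  rows[[length(rows) + 1]] <- data.frame(
    n_per_population = n, n_reps = reps,
    median_max_abs_error_pct = stats::median(rec$max_abs_error_pct),
    median_support_recovered = stats::median(rec$support_recovered_frac))
  cat(sprintf("  n = %4d: max |error| = %5.1f points, support recovered = %4.0f%%\n",
              n, stats::median(rec$max_abs_error_pct),
              100 * stats::median(rec$support_recovered_frac)))
}
out <- do.call(rbind, rows)
utils::write.csv(out, "results/recovery_summary.csv", row.names = FALSE)
cat("small samples (n = 3) carry errors of tens of points;",
    "n = 500 estimates are within a few points of the truth\n")
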