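#!/usr/bin/env Rscript
# Windowed heterozygosity and maximum-likelihood theta/epsilon on a
# simulated individual genome.
#
# A 5-Mb diploid pileup genome is generated with known per-site
# heterozygosity (theta = 0.002, the order observed in taurine cattle) and
# sequencing error rate (epsilon = 0.002), depth-filtered to well-covered
# sites (4-30x), summarised in 10-kb windows, and handed to the theta/
# epsilon co-estimator. Outputs: per-window table, per-sample estimate.

suppressMessages(library(herdscan))
dir.create("results", showWarnings = FALSE)
seed <- 101
theta_true <- 0.002; eps_true <- 0.002

sim <- simulate_pileup_genome(5e6, theta = theta_true, epsilon = eps_true,
                              mean_depth = 10, seed = seed)
fs <- filter_sites(sim$sites)                 # well-covered sites, 4-30x
message(sprintf("retained %d of %d sites after depth filtering",
                nrow(fs), nrow(sim$sites)))

win <- window_heterozygosity(fs, window = 10000, genome_length = 5e6)
write_tsv(win, "results/01_window_heterozygosity.tsv")
usable <- !win$flagged
message(sprintf("mean 10-kb window het rate: %.5f (%d/%d windows usable)",
                sum(win$n_het[usable]) / sum(win$n_covered[usable]),
                sum(usable), nrow(win)))

est <- estimate_theta_epsilon(fs)
print(est)
message(sprintf("relative error: theta %.1f%%, epsilon %.1f%%",
                100 * abs(est$theta - theta_true) / theta_true,
                100 * abs(est$epsilon - eps_true) / eps_true))
jsonlite::write_json(unclass(est), "results/01_theta_estimate.json",
                     auto_unbox = TRUE, digits = NA)
write_manifest(list(stage = "heterozygosity", seed = seed,
                    genome_length = 5e6, theta_true = theta_true,
                    epsilon_true = eps_true, window = 10000,
                    min_depth = 4, max_depth = 30),
               path = "results/01_manifest.json")
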