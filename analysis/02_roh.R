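#!/usr/bin/env Rscript
# Runs-of-homozygosity calling with planted truth, and diversity inside
# vs outside the called runs (pi_in / pi_out).
#
# A 10-Mb genome carries 10 planted autozygous tracts (25-50 bins of
# 10 kb, residual heterozygosity 0). The bin-based caller (seed < 0.25x
# genome average, bin ceiling 2x, run mean <= 2/3x, >= 20 consecutive
# bins) is scored against the planted coordinates at bin level.
# Outputs: BED of called runs, TSV of per-run stats, JSON summary.

suppressMessages(library(herdscan))
dir.create("results", showWarnings = FALSE)
seed <- 202

spec <- plant_roh_tracts(1e7, n_tracts = 10, len_bins = c(25, 50),
                         seed = seed)
sim <- simulate_pileup_genome(1e7, theta = 0.002, epsilon = 0.002,
                              mean_depth = 10, roh_spec = spec,
                              seed = seed + 1)
fs <- filter_sites(sim$sites)
het <- call_het(fs)
bins <- bin_counts(fs, genome_length = 1e7, het = het)
avg <- genome_avg_snp(bins)
message(sprintf("genome average: %.2f het SNPs per 10-kb bin", avg))

called <- call_roh(bins, avg)
write_bed(called, "results/02_roh_calls.bed")
write_bed(cbind(chrom = "chr1", sim$truth$planted_roh[c("start", "end")]),
          "results/02_roh_truth.bed")
write_tsv(called, "results/02_roh_calls.tsv")

bin_set <- function(iv) unlist(mapply(
  function(s, e) (s %/% 1e4):((e %/% 1e4) - 1), iv$start, iv$end,
  SIMPLIFY = FALSE))
tb <- bin_set(spec); cb <- bin_set(called)
message(sprintf("called %d runs vs %d planted; bin sensitivity %.3f, precision %.3f",
                nrow(called), nrow(spec),
                length(intersect(cb, tb)) / length(tb),
                length(intersect(cb, tb)) / length(cb)))

summ <- summarize_roh(called, fs, assayed_length = sum(!bins$no_data) * 1e4,
                      het = het)
print(summ)
jsonlite::write_json(unclass(summ), "results/02_roh_summary.json",
                     auto_unbox = TRUE, digits = NA)
write_manifest(list(stage = "roh", seed = seed, genome_length = 1e7,
                    bin_size = 10000, seed_factor = 0.25,
                    bin_ceiling_factor = 2, run_mean_factor = 2 / 3,
                    min_bins = 20),
               path = "results/02_manifest.json")
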