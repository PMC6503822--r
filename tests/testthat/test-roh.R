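# Bin-based ROH caller: tiling contract, seed/relaxation/length rules,
# brute-force oracle equivalence, parameter monotonicity, summaries.

test_that("bins tile from 0 at exact multiples and flag empty regions", {
  s <- make_sites(matrix(rep(c(10L, 0L, 0L, 0L), each = 4), ncol = 4),
                  pos = c(500, 9999, 10001, 35000))
  b <- bin_counts(s, bin_size = 10000, genome_length = 40000)
  expect_equal(b$start, c(0, 10000, 20000, 30000))
  expect_equal(b$end, c(10000, 20000, 30000, 40000))
  expect_equal(b$covered_sites, c(2L, 1L, 0L, 1L))
  expect_true(all(b$no_data))                     # all far below 0.2 coverage
  expect_equal(b$snp_count, rep(0L, 4))
})

test_that("uniform genome seeds no runs; uniform bins never fire", {
  bins <- data.frame(chrom = "chr1", bin_index = 0:99,
                     start = (0:99) * 1e4, end = (1:100) * 1e4,
                     snp_count = 20L, covered_sites = 9000L, no_data = FALSE)
  expect_equal(nrow(call_roh(bins, 20)), 0L)
  expect_error(call_roh(bins, 0), "genome_avg")
})

test_that("planted zero tract is recovered with bin-accurate boundaries", {
  g <- simulate_pileup_genome(2e6, theta = 0.002, epsilon = 0.002,
                              mean_depth = 10,
                              roh_spec = data.frame(start = 8e5, end = 1.1e6,
                                                    factor = 0),
                              seed = 31)
  fs <- filter_sites(g$sites)
  b <- bin_counts(fs, genome_length = 2e6)
  r <- call_roh(b, genome_avg_snp(b))
  expect_equal(nrow(r), 1L)
  expect_lte(abs(r$start - 8e5), 1e4)             # within one bin of truth
  expect_lte(abs(r$end - 1.1e6), 1e4)
  expect_gte(r$n_bins, 28L)

  # same genome, 10-bin tract: below min_bins, nothing called
  g2 <- simulate_pileup_genome(1e6, theta = 0.002, epsilon = 0.002,
                               mean_depth = 10,
                               roh_spec = data.frame(start = 5e5, end = 6e5,
                                                     factor = 0),
                               seed = 32)
  b2 <- bin_counts(filter_sites(g2$sites), genome_length = 1e6)
  r2 <- call_roh(b2, genome_avg_snp(b2),
                 roh_params(min_bins = 20, min_length = 2e5))
  expect_equal(nrow(r2), 0L)
})

test_that("short no-data gaps are bridged, long gaps break the run", {
  base <- data.frame(chrom = "chr1", bin_index = 0:49,
                     start = (0:49) * 1e4, end = (1:50) * 1e4,
                     snp_count = 20L, covered_sites = 9000L, no_data = FALSE)
  low <- 5:36                                      # 32 low bins
  mk <- function(nd_at) {
    b <- base
    b$snp_count[low] <- 0L
    b$no_data[nd_at] <- TRUE
    b$snp_count[nd_at] <- 0L
    b$covered_sites[nd_at] <- 0L
    b
  }
  bridged <- call_roh(mk(20:21), 20)               # 2 consecutive no-data
  expect_equal(nrow(bridged), 1L)
  expect_equal(bridged$n_bins, 32L)
  broken <- call_roh(mk(20:22), 20)                # 3 consecutive no-data
  expect_equal(nrow(broken), 0L)                   # both halves < 20 bins
})

test_that("caller matches the brute-force enumeration oracle", {
  for (seed in 1:10) {
    bins <- random_bins(seed)
    avg <- genome_avg_snp(bins)
    expect_equal(call_roh(bins, avg), oracle_roh(bins, avg),
                 info = paste("seed", seed))
  }
})

test_that("threshold monotonicity: stricter seeds/lengths call less", {
  bins <- random_bins(99)
  avg <- genome_avg_snp(bins)
  n_prev <- Inf
  for (sf in c(0.25, 0.15, 0.05)) {
    n <- nrow(call_roh(bins, avg, roh_params(seed_factor = sf)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  len_prev <- Inf
  for (mb in c(5, 10, 20, 40)) {
    r <- call_roh(bins, avg, roh_params(min_bins = mb))
    cum <- if (nrow(r)) sum(r$end - r$start) else 0
    expect_lte(cum, len_prev)
    len_prev <- cum
  }
})

test_that("summaries: empty call set, planted tract, and locality", {
  g <- simulate_pileup_genome(5e5, theta = 0.002, epsilon = 0.002,
                              mean_depth = 10,
                              roh_spec = data.frame(start = 1e5, end = 3.5e5,
                                                    factor = 0),
                              seed = 41)
  fs <- filter_sites(g$sites)
  het <- call_het(fs)
  none <- data.frame(chrom = character(), start = integer(), end = integer())
  s0 <- summarize_roh(none, fs, assayed_length = 5e5, het = het)
  expect_equal(s0$n_roh, 0L)
  expect_equal(s0$f_roh, 0)
  expect_equal(s0$pi_out, mean(het))

  iv <- data.frame(chrom = "chr1", start = 1e5, end = 3.5e5)
  s1 <- summarize_roh(iv, fs, assayed_length = 5e5, het = het)
  expect_equal(s1$f_roh, 0.5)
  expect_lt(s1$pi_in, 1e-4)
  expect_gt(s1$pi_out, s1$pi_in)
  expect_error(summarize_roh(iv, fs, assayed_length = 0), "assayed_length")

  # locality: altering sites outside the interval leaves pi_in unchanged
  fs2 <- fs
  out_rows <- which(!(fs2$pos > 1e5 & fs2$pos <= 3.5e5))
  flip <- out_rows[seq_len(200)]
  fs2[flip, c("nA", "nC", "nG", "nT")] <- rep(c(5L, 5L, 0L, 0L), each = 200)
  fs2$depth[flip] <- 10L
  s2 <- summarize_roh(iv, fs2, assayed_length = 5e5)
  expect_equal(s2$pi_in, s1$pi_in)
})
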