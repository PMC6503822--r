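# Generators: determinism, degenerate parameters, and agreement of the
# generated marginals with their generative laws.

test_that("generators are deterministic given the seed", {
  a <- simulate_pileup_genome(2e4, seed = 11)
  b <- simulate_pileup_genome(2e4, seed = 11)
  expect_identical(a$sites, b$sites)
  expect_identical(a$truth$het_sites, b$truth$het_sites)
  expect_false(identical(a$sites, simulate_pileup_genome(2e4, seed = 12)$sites))

  p1 <- simulate_admixed_panel(500, seed = 3)
  p2 <- simulate_admixed_panel(500, seed = 3)
  expect_identical(p1$C$calls, p2$C$calls)

  w1 <- simulate_twolocus_wf(50, 0.01, 40, 20, generations = 50, seed = 5)
  w2 <- simulate_twolocus_wf(50, 0.01, 40, 20, generations = 50, seed = 5)
  expect_identical(w1$genotypes$calls, w2$genotypes$calls)
})

test_that("theta = 0 yields no heterozygous sites", {
  g <- simulate_pileup_genome(1e5, theta = 0, epsilon = 0.002, seed = 1)
  expect_length(g$truth$het_sites, 0)
})

test_that("zero-residual tracts carry no planted hets; errors only", {
  g <- simulate_pileup_genome(2e5, theta = 0.002, epsilon = 0.002,
                              roh_spec = data.frame(start = 5e4, end = 1.5e5,
                                                    factor = 0),
                              seed = 2)
  expect_false(any(g$truth$het_sites > 5e4 & g$truth$het_sites <= 1.5e5))
  # inside the tract every non-major read is a sequencing error: the
  # empirical minor-read rate matches epsilon to within 3 binomial SDs
  tract <- g$sites[g$sites$pos > 5e4 & g$sites$pos <= 1.5e5, ]
  minor <- sum(tract$depth) - sum(pmax(tract$nA, tract$nC, tract$nG, tract$nT))
  n_reads <- sum(tract$depth)
  expect_lt(abs(minor / n_reads - 0.002), 3 * sqrt(0.002 * 0.998 / n_reads) + 1e-5)
})

test_that("generated marginals track their generative laws within 3 SD", {
  L <- 5e5
  g <- simulate_pileup_genome(L, theta = 0.002, epsilon = 0.002,
                              mean_depth = 10, seed = 7)
  het_frac <- length(g$truth$het_sites) / L
  expect_lt(abs(het_frac - 0.002), 3 * sqrt(0.002 * 0.998 / L))
  expect_lt(abs(mean(g$sites$depth) - 10), 3 * sqrt(10 / L))
})

test_that("pileup generator rejects invalid specs", {
  expect_error(simulate_pileup_genome(0, seed = 1), "genome_length")
  expect_error(simulate_pileup_genome(1e4, theta = 0.5, seed = 1), "theta")
  expect_error(simulate_pileup_genome(1e4, epsilon = 0.1, seed = 1), "epsilon")
  expect_error(simulate_pileup_genome(
    1e5, roh_spec = data.frame(start = c(0, 5e3), end = c(1e4, 2e4),
                               factor = 0), seed = 1),
    "overlap")
  expect_error(simulate_pileup_genome(
    1e4, roh_spec = data.frame(start = 5e3, end = 2e4, factor = 0), seed = 1),
    "within the genome")
})

test_that("admixed panel boundary: alpha = 1 with tiny target drift copies A", {
  sim <- simulate_admixed_panel(2000, f_a = 0.05, f_b = 0.05, f_c = 1e-6,
                                alpha = 1, n_per_pop = 5, seed = 4)
  expect_lt(max(abs(sim$truth$freq_c - sim$truth$freq_a)), 0.01)
  expect_true(all(sim$C$calls %in% 0:2))
  expect_error(simulate_admixed_panel(100, n_per_pop = 1, seed = 1),
               "n_per_pop")
  expect_error(simulate_admixed_panel(100, f_a = 0, seed = 1), "drift")
})

test_that("stored true frequencies predict the f3 sign (brute force)", {
  adm <- simulate_admixed_panel(20000, f_a = 0.05, f_b = 0.05, f_c = 0.001,
                                alpha = 0.5, n_per_pop = 5, seed = 8)
  expect_lt(f3_population(adm$truth$freq_a, adm$truth$freq_b,
                          adm$truth$freq_c), 0)
  for (a in c(0, 1)) {
    una <- simulate_admixed_panel(20000, f_a = 0.05, f_b = 0.05, f_c = 0.05,
                                  alpha = a, n_per_pop = 5, seed = 9 + a)
    expect_gt(f3_population(una$truth$freq_a, una$truth$freq_b,
                            una$truth$freq_c), 0)
  }
})

test_that("unlinked Wright-Fisher loci sit near the r2 sampling floor", {
  sim <- simulate_twolocus_wf(200, 0.5, 400, 50, generations = 200, seed = 6)
  ld <- ld_decay(sim$genotypes, min_dist = 1, max_dist = 1e8, n_bins = 1)
  # Sved floor at c = 0.5 is 1/(1 + 2 ne) = 0.0025; the adjustment has
  # already removed the 1/n sampling term
  expect_lt(abs(ld$mean_r2_adj), 0.02)
  expect_error(simulate_twolocus_wf(1, 0.1, 10, 5, seed = 1), "ne")
  expect_error(simulate_twolocus_wf(50, 0.6, 10, 5, seed = 1), "c_rec")
})
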