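# Site filtering, het calling, windowed heterozygosity and theta/epsilon
# maximum likelihood.

test_that("depth filter bounds are inclusive and order-preserving", {
  s <- make_sites(rbind(c(3, 0, 0, 0), c(4, 0, 0, 0), c(30, 0, 0, 0),
                        c(31, 0, 0, 0)))
  kept <- filter_sites(s)
  expect_equal(kept$depth, c(4L, 30L))
  expect_equal(filter_sites(kept), kept)          # idempotent
  expect_equal(nrow(filter_sites(s[0, ])), 0L)
  unsorted <- s[c(2, 1, 3, 4), ]
  expect_error(filter_sites(unsorted), "sorted")
})

test_that("het call needs both 2 supporting reads and 0.2 fraction", {
  s <- make_sites(rbind(c(8, 2, 0, 0),      # 2 reads, fraction 0.2: het
                        c(10, 0, 0, 0),     # no minor allele
                        c(9, 1, 0, 0),      # 1 read < 2
                        c(0, 16, 2, 0),     # 2 reads but fraction 1/9 < 0.2
                        c(0, 3, 2, 0)))     # 2 reads, fraction 0.4: het
  expect_equal(call_het(s), c(TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("window statistics do the arithmetic and conserve totals", {
  hom <- matrix(rep(c(10L, 0L, 0L, 0L), each = 9000), ncol = 4)
  hom[sample(9000, 18), ] <- rep(c(5L, 5L, 0L, 0L), each = 18)
  s <- make_sites(hom, pos = sample(10000, 9000))
  s <- s[order(s$pos), ]
  w <- window_heterozygosity(s, window = 10000)
  expect_equal(nrow(w), 1L)
  expect_equal(w$n_covered, 9000L)
  expect_equal(w$n_het, 18L)
  expect_equal(w$het_rate, 2.0e-3)
  expect_false(w$flagged)

  # conservation across a multi-window genome
  g <- simulate_pileup_genome(2e5, theta = 0.005, epsilon = 0.002, seed = 3)
  fs <- filter_sites(g$sites)
  w <- window_heterozygosity(fs)
  expect_equal(sum(w$n_het) / sum(w$n_covered),
               mean(call_het(fs)))
})

test_that("all-homozygous error-free genome gives zero het everywhere", {
  g <- simulate_pileup_genome(1e5, theta = 0, epsilon = 0, seed = 5)
  w <- window_heterozygosity(filter_sites(g$sites))
  expect_true(all(w$n_het == 0L))
  expect_true(all(w$het_rate[!w$flagged] == 0))
})

test_that("windowed het rate recovers theta at high depth (binomial oracle)", {
  L <- 1e6
  g <- simulate_pileup_genome(L, theta = 0.002, epsilon = 0.002,
                              mean_depth = 20, seed = 9)
  fs <- filter_sites(g$sites)
  w <- window_heterozygosity(fs, genome_length = L)
  rate <- sum(w$n_het[!w$flagged]) / sum(w$n_covered[!w$flagged])
  expect_lt(abs(rate - 0.002), 3 * sqrt(0.002 * 0.998 / sum(w$n_covered)))
})

test_that("mixture log-likelihood equals per-site enumeration", {
  g <- simulate_pileup_genome(50, theta = 0.05, epsilon = 0.01,
                              mean_depth = 12, seed = 21)
  s <- g$sites[g$sites$depth > 0, ]
  pat <- herdscan:::.ml_patterns(s)
  for (par in list(c(0.002, 0.002), c(0.05, 0.01), c(1e-4, 0.03))) {
    expect_equal(herdscan:::.ml_loglik(par[1], par[2], pat),
                 oracle_loglik(s, par[1], par[2]), tolerance = 1e-11)
  }
})

test_that("theta MLE responds monotonically to added het-like sites", {
  hom <- matrix(rep(c(12L, 0L, 0L, 0L), each = 3000), ncol = 4)
  prev <- -Inf
  for (k in c(0, 6, 30, 90)) {
    m <- hom
    if (k > 0) m[seq_len(k), ] <- rep(c(6L, 6L, 0L, 0L), each = k)
    est <- estimate_theta_epsilon(make_sites(m))
    expect_gte(est$theta, prev - 1e-10)
    prev <- est$theta
  }
})

test_that("on error-free data theta matches the plain het fraction", {
  g <- simulate_pileup_genome(2e5, theta = 0.01, epsilon = 0,
                              mean_depth = 15, seed = 13)
  fs <- filter_sites(g$sites)
  est <- estimate_theta_epsilon(fs)
  t2 <- herdscan:::.top2(fs)
  plain <- mean(t2[, 2] >= 1)                      # any second allele read
  expect_lt(abs(est$theta - plain) / plain, 0.02)
})

test_that("monoallelic input drives both estimates to the zero boundary", {
  s <- make_sites(matrix(rep(c(15L, 0L, 0L, 0L), each = 2000), ncol = 4))
  est <- estimate_theta_epsilon(s)
  expect_lt(est$theta, 1e-6)
  expect_lt(est$epsilon, 1e-6)
  expect_true(est$at_boundary)
  expect_error(estimate_theta_epsilon(make_sites(matrix(0L, 5, 4))),
               "zero-depth")
})

test_that("theta/epsilon recovery on a medium synthetic genome", {
  g <- simulate_pileup_genome(2e6, theta = 0.002, epsilon = 0.002,
                              mean_depth = 10, seed = 17)
  est <- estimate_theta_epsilon(filter_sites(g$sites))
  expect_lt(abs(est$theta - 0.002) / 0.002, 0.10)
  expect_lt(abs(est$epsilon - 0.002) / 0.002, 0.25)
  expect_false(est$low_confidence)
})
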