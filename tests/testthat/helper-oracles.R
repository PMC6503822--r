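# Independent brute-force oracles and fixture builders shared by the tests.
# These re-derive expected results naively (O(n^2) scans, per-site
# enumeration) and must stay independent of the package's optimised paths.

# naive ROH enumeration: for every possible seed bin, re-extend by explicit
# recomputation (mean() over the accepted vector each step), trim to the
# last sub-seed bin, emit if long enough, resume after an emitted run
oracle_roh <- function(bins, genome_avg, params = roh_params()) {
  seed_thr <- params$seed_factor * genome_avg
  ceil_thr <- params$bin_ceiling_factor * genome_avg
  mean_thr <- params$run_mean_factor * genome_avg
  res <- list()
  for (chr in unique(bins$chrom)) {
    b <- bins[bins$chrom == chr, , drop = FALSE]
    n <- nrow(b)
    i <- 1L
    while (i <= n) {
      if (!b$no_data[i] && b$snp_count[i] < seed_thr) {
        acc <- i; k <- i + 1L; gap <- 0L
        while (k <= n) {
          if (b$no_data[k]) {
            gap <- gap + 1L
            if (gap > params$max_gap_bins) break
          } else {
            if (b$snp_count[k] > ceil_thr) break
            if (mean(b$snp_count[c(acc, k)]) > mean_thr) break
            if (b$snp_count[k] >= seed_thr) {
              # consecutive exception bins since the last sub-seed bin
              since <- acc[acc > max(acc[b$snp_count[acc] < seed_thr])]
              if (length(since) + 1L > params$max_exception_bins) break
            }
            gap <- 0L
            acc <- c(acc, k)
          }
          k <- k + 1L
        }
        last <- max(acc[b$snp_count[acc] < seed_thr])
        n_bins <- last - i + 1L
        if (n_bins >= params$min_bins &&
            (b$end[last] - b$start[i]) >= params$min_length) {
          res[[length(res) + 1L]] <- data.frame(
            chrom = chr, start = b$start[i], end = b$end[last],
            n_bins = n_bins,
            mean_snp_per_bin = mean(b$snp_count[acc[acc <= last]]))
          i <- last + 1L
          next
        }
      }
      i <- i + 1L
    }
  }
  if (length(res) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_bins = integer(),
                      mean_snp_per_bin = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# random bin tables exercising seeds, exceptions, gaps and chromosome breaks
random_bins <- function(seed, max_bins = 2000L) {
  set.seed(seed)
  n_chrom <- sample(1:3, 1L)
  out <- lapply(seq_len(n_chrom), function(ci) {
    n <- sample(50:floor(max_bins / n_chrom), 1L)
    snp <- rpois(n, 20)
    for (k in seq_len(sample(0:6, 1L))) {          # planted low stretches
      len <- sample(5:min(60L, n - 10L), 1L)
      at <- sample(n - len, 1L)
      snp[at:(at + len - 1L)] <- rpois(len, runif(1, 0, 4))
    }
    snp[sample(n, round(0.02 * n))] <- rpois(round(0.02 * n), 60)  # spikes
    nd <- runif(n) < 0.04                           # no-data bins
    data.frame(chrom = paste0("chr", ci), bin_index = seq_len(n) - 1L,
               start = (seq_len(n) - 1L) * 10000L, end = seq_len(n) * 10000L,
               snp_count = snp, covered_sites = ifelse(nd, 0L, 9000L),
               no_data = nd)
  })
  do.call(rbind, out)
}

# direct per-site summation of the hom/het mixture likelihood (dmultinom)
oracle_loglik <- function(sites, theta, eps) {
  h <- theta / (1 + theta)
  sum(vapply(seq_len(nrow(sites)), function(i) {
    cnt <- as.numeric(sites[i, c("nA", "nC", "nG", "nT")])
    ord <- order(cnt, decreasing = TRUE)
    p_hom <- rep(eps / 3, 4); p_hom[ord[1L]] <- 1 - eps
    p_het <- rep(eps / 3, 4); p_het[ord[1:2]] <- (1 - eps) / 2 + eps / 6
    log((1 - h) * dmultinom(cnt, prob = p_hom) +
          h * dmultinom(cnt, prob = p_het))
  }, numeric(1)))
}

# hand-built pileup rows from a base-count matrix
make_sites <- function(counts, chrom = "chr1", pos = NULL) {
  counts <- matrix(as.integer(counts), ncol = 4L)
  n <- nrow(counts)
  if (is.null(pos)) pos <- seq_len(n)
  data.frame(chrom = chrom, pos = as.integer(pos),
             depth = as.integer(rowSums(counts)),
             nA = counts[, 1L], nC = counts[, 2L],
             nG = counts[, 3L], nT = counts[, 4L])
}

# allele-frequency table built directly from given frequencies (population
# level: huge n_hap makes the sampling correction negligible)
make_af_table <- function(freq_list, n_hap = 1e9) {
  freq <- do.call(cbind, freq_list)
  nh <- matrix(n_hap, nrow(freq), ncol(freq), dimnames = dimnames(freq))
  structure(list(freq = freq, n_hap = nh,
                 variants = data.frame(chrom = "1",
                                       pos = seq_len(nrow(freq)),
                                       ref = "A", alt = "G")),
            class = "allele_freq_table")
}

# genotype matrix from a plain dosage matrix (samples x variants)
make_geno <- function(calls, chrom = NULL, pos = NULL) {
  m <- ncol(calls)
  ids <- if (is.null(rownames(calls))) sprintf("s%03d", seq_len(nrow(calls)))
         else rownames(calls)
  geno_matrix(calls,
              chrom = if (is.null(chrom)) rep("1", m) else chrom,
              pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
              ref = rep("A", m), alt = rep("G", m),
              samples = ids)
}
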