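# Three-population f3 admixture test. f3(C; A, B) is the average over SNPs
# of (c - a)(c - b) minus the finite-sample correction for the target
# population; a Z-score below -3 (block-jackknife SE over 1,000-SNP blocks)
# is taken as significant evidence that C is admixed between populations
# related to A and B.

#' Per-population allele frequencies from a genotype matrix
#'
#' Computes, per variant and population, the alternate-allele frequency and
#' the number of non-missing allele copies. Variants with no genotyped
#' sample in some population are dropped (count recorded in attribute
#' `n_dropped`).
#'
#' @param g a [geno_matrix()].
#' @param groups named character vector mapping sample id to population.
#' @return list of class `allele_freq_table`: `freq` and `n_hap` (variant x
#'   population matrices) and `variants` (records, genome order).
#' @export
allele_freqs <- function(g, groups) {
  stopifnot(inherits(g, "geno_matrix"))
  ids <- rownames(g$calls)
  if (!all(ids %in% names(groups))) stop("every sample needs a population")
  pop <- factor(groups[ids])
  if (any(table(pop) == 0L)) stop("empty population")
  freq <- sapply(levels(pop), function(p) {
    m <- g$calls[pop == p, , drop = FALSE]
    colSums(m, na.rm = TRUE) / (2 * colSums(!is.na(m)))
  })
  n_hap <- sapply(levels(pop), function(p)
    2 * colSums(!is.na(g$calls[pop == p, , drop = FALSE])))
  ok <- rowSums(n_hap == 0L) == 0L
  structure(list(freq = freq[ok, , drop = FALSE],
                 n_hap = n_hap[ok, , drop = FALSE],
                 variants = g$variants[ok, , drop = FALSE]),
            class = "allele_freq_table", n_dropped = sum(!ok))
}

# weighted delete-one-block jackknife for a mean statistic; returns the SE
# (Busing-style weights, reducing to the classical formula for equal blocks)
.block_jackknife_se <- function(u, block) {
  n <- length(u)
  g <- length(unique(block))
  if (g < 2L) stop("need at least 2 jackknife blocks")
  m_j <- tabulate(factor(block))
  sum_j <- rowsum(u, block)[, 1L]
  theta <- mean(u)
  theta_del <- (sum(u) - sum_j) / (n - m_j)
  h_j <- n / m_j
  tau <- h_j * theta - (h_j - 1) * theta_del
  theta_jack <- g * theta - sum((1 - m_j / n) * theta_del)
  sqrt(sum((tau - theta_jack)^2 / (h_j - 1)) / g)
}

#' Three-population f3 test with block-jackknife standard error
#'
#' Per SNP the statistic is `(c - a)(c - b) - c(1 - c)/(n_hap_C - 1)`,
#' where a, b, c are the allele frequencies of the two reference
#' populations and the target, and the subtracted term corrects for
#' sampling noise in the target frequency. The f3 estimate is the
#' unweighted mean over SNPs; its standard error comes from a
#' delete-one-block jackknife over contiguous blocks of `block_snps` SNPs
#' in genome order. A Z-score below -3 is flagged significant (evidence of
#' admixture in the target).
#'
#' Variants monomorphic across all three populations are excluded.
#'
#' @param freqs an [allele_freqs()] table.
#' @param target,ref_a,ref_b population names (columns of `freqs$freq`).
#' @param block_snps jackknife block size in SNPs (default 1000).
#' @return list of class `f3_result`: f3, se, z, n_snps, n_blocks,
#'   significant.
#' @export
f3_test <- function(freqs, target, ref_a, ref_b, block_snps = 1000L) {
  stopifnot(inherits(freqs, "allele_freq_table"))
  pops <- colnames(freqs$freq)
  if (!all(c(target, ref_a, ref_b) %in% pops)) stop("unknown population")
  a <- freqs$freq[, ref_a]; b <- freqs$freq[, ref_b]
  cc <- freqs$freq[, target]; nc <- freqs$n_hap[, target]
  if (any(nc < 2L)) stop("target needs n_hap >= 2 at every variant")
  poly <- !((a == 0 & b == 0 & cc == 0) | (a == 1 & b == 1 & cc == 1))
  a <- a[poly]; b <- b[poly]; cc <- cc[poly]; nc <- nc[poly]
  n <- length(a)
  if (n < 2L * block_snps && n < 2L) stop("too few SNPs")
  u <- (cc - a) * (cc - b) - cc * (1 - cc) / (nc - 1)
  block <- (seq_len(n) - 1L) %/% block_snps
  if (length(unique(block)) < 2L) stop("need at least 2 blocks of block_snps SNPs")
  f3 <- mean(u)
  se <- .block_jackknife_se(u, block)
  z <- f3 / se
  structure(list(f3 = f3, se = se, z = z, n_snps = n,
                 n_blocks = length(unique(block)),
                 significant = z < -3.0,
                 target = target, ref_a = ref_a, ref_b = ref_b),
            class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3(%s; %s, %s) = %.6f  SE %.6f  Z = %.2f  (%d SNPs, %d blocks)%s\n",
              x$target, x$ref_a, x$ref_b, x$f3, x$se, x$z, x$n_snps,
              x$n_blocks, if (x$significant) "  [significant: admixed]" else ""))
  invisible(x)
}

#' Population-level f3 from true allele frequencies
#'
#' Brute-force oracle for simulations: the plain mean of
#' `(c - a)(c - b)` over loci computed from known (noise-free) population
#' frequencies, with no sampling correction.
#'
#' @param p_a,p_b,p_c numeric vectors of true frequencies.
#' @return a single number.
#' @export
f3_population <- function(p_a, p_b, p_c) mean((p_c - p_a) * (p_c - p_b))
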