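# Genotype QC and LD pruning. Thresholds default to the PLINK-style values
# used for the array data: --mind 0.1, --geno 0.05, --maf 0.01; LD pruning
# targets overall pairwise r^2 < 0.10.

#' Missingness and allele-frequency QC of a genotype matrix
#'
#' Applies the three filters in fixed order: (1) drop samples whose missing
#' fraction exceeds `max_sample_missing`; (2) on the retained samples, drop
#' variants whose missing fraction exceeds `max_variant_missing`; (3) on the
#' retained samples, drop variants with minor allele frequency below
#' `min_maf`. Re-running on its own output is a no-op.
#'
#' @param g a [geno_matrix()].
#' @param max_sample_missing sample-level missingness ceiling (default 0.10).
#' @param max_variant_missing variant-level missingness ceiling (default 0.05).
#' @param min_maf minimum minor allele frequency retained (default 0.01).
#' @return filtered [geno_matrix()] with attribute `qc_log`, a data.frame of
#'   items dropped at each step.
#' @export
qc_filter <- function(g, max_sample_missing = 0.10,
                      max_variant_missing = 0.05, min_maf = 0.01) {
  stopifnot(inherits(g, "geno_matrix"))
  miss_s <- rowMeans(is.na(g$calls))
  keep_s <- miss_s <= max_sample_missing
  if (!any(keep_s)) stop("qc_filter dropped all samples")
  g1 <- subset_geno(g, samples = which(keep_s))

  miss_v <- colMeans(is.na(g1$calls))
  keep_v1 <- miss_v <= max_variant_missing
  g2 <- subset_geno(g1, variants = which(keep_v1))

  maf <- .maf(g2$calls)
  keep_v2 <- !is.na(maf) & maf >= min_maf
  out <- subset_geno(g2, variants = which(keep_v2))

  attr(out, "qc_log") <- data.frame(
    step = c("sample_missingness", "variant_missingness", "maf"),
    dropped = c(sum(!keep_s), sum(!keep_v1), sum(!keep_v2)),
    retained = c(sum(keep_s), sum(keep_v1), sum(keep_v2)))
  out
}

# squared dosage correlation for one pair of dosage vectors, complete-case
.r2_pair <- function(x, y, min_pairs = 5L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_pairs) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Pairwise composite LD (r-squared) between two variants
#'
#' Squared Pearson correlation of unphased genotype dosages (Rogers-Huff
#' composite LD) over the samples non-missing at both variants.
#'
#' @param g a [geno_matrix()].
#' @param i,j variant column indices.
#' @param min_pairs minimum complete pairs required (default 5); below it
#'   the value is flagged undefined (`NA`).
#' @return r^2 in \[0, 1\], or `NA` if undefined.
#' @export
pairwise_r2 <- function(g, i, j, min_pairs = 5L) {
  stopifnot(inherits(g, "geno_matrix"))
  .r2_pair(g$calls[, i], g$calls[, j], min_pairs)
}

# r^2 matrix among a set of variant columns (complete-case per pair)
.r2_matrix <- function(calls, idx) {
  m <- length(idx)
  r2 <- matrix(NA_real_, m, m)
  for (a in seq_len(m - 1L))
    for (b in (a + 1L):m)
      r2[a, b] <- r2[b, a] <- .r2_pair(calls[, idx[a]], calls[, idx[b]])
  r2
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window_snps` variants (step `step_snps`) along each
#' chromosome; within a window, while any retained pair has r^2 above
#' `r2_max`, the member of the worst offending pair with the lower minor
#' allele frequency is dropped (ties drop the later position). After
#' pruning, no retained within-window pair exceeds `r2_max`.
#'
#' @param g a QC-filtered [geno_matrix()].
#' @param r2_max maximum tolerated pairwise r^2 (default 0.10).
#' @param window_snps window size in SNPs (default 50).
#' @param step_snps window step in SNPs (default 5).
#' @return pruned [geno_matrix()] with attribute `n_pruned`.
#' @export
ld_prune <- function(g, r2_max = 0.10, window_snps = 50L, step_snps = 5L) {
  stopifnot(inherits(g, "geno_matrix"))
  maf <- .maf(g$calls)
  keep <- rep(TRUE, ncol(g$calls))
  for (chr in unique(g$variants$chrom)) {
    cols <- which(g$variants$chrom == chr)
    start <- 1L
    repeat {
      win <- cols[start:min(start + window_snps - 1L, length(cols))]
      act <- win[keep[win]]
      if (length(act) >= 2L) {
        r2 <- .r2_matrix(g$calls, act)
        repeat {
          worst <- suppressWarnings(max(r2, na.rm = TRUE))
          if (!is.finite(worst) || worst <= r2_max) break
          hit <- which(r2 == worst, arr.ind = TRUE)[1L, ]
          a <- act[hit[1L]]; b <- act[hit[2L]]
          drop <- if (maf[a] < maf[b]) a
                  else if (maf[b] < maf[a]) b
                  else max(a, b)                     # tie: later position
          di <- match(drop, act)
          act <- act[-di]; r2 <- r2[-di, -di, drop = FALSE]
          keep[drop] <- FALSE
        }
      }
      if (start + window_snps - 1L >= length(cols)) break
      start <- start + step_snps
    }
  }
  out <- subset_geno(g, variants = which(keep))
  attr(out, "n_pruned") <- sum(!keep)
  out
}
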