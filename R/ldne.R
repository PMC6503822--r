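# LD decay in physical-distance bins and Sved-type effective-population-
# size trajectory. Defaults mirror the standard LD-decay tool run: pair distances
# 5 kb to 2 Mb, 50 equal-width bins, MAF 0.05.

#' Binned LD decay over physical distance
#'
#' Filters variants at `min_maf`, enumerates all intra-chromosome variant
#' pairs separated by `min_dist` to `max_dist` bp (inclusive), computes
#' each pair's composite r^2 ([pairwise_r2()]) and the sample-size-adjusted
#' `r2_adj = r2 - 1/n_eff` (n_eff = complete-case sample count), and
#' averages within `n_bins` equal-width distance bins.
#'
#' @param g a [geno_matrix()].
#' @param min_dist,max_dist inclusive pair-distance bounds in bp
#'   (defaults 5000 and 2000000).
#' @param n_bins number of equal-width distance bins (default 50).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param cm_per_mb physical-to-genetic scaling for `mean_c` (default 1).
#' @return data.frame (bins with >= 1 pair): d_min, d_max, mean_dist,
#'   mean_c, mean_r2_adj, n_pairs.
#' @export
ld_decay <- function(g, min_dist = 5000L, max_dist = 2000000L,
                     n_bins = 50L, min_maf = 0.05, cm_per_mb = 1) {
  stopifnot(inherits(g, "geno_matrix"), min_dist < max_dist, n_bins >= 1L)
  maf <- .maf(g$calls)
  g <- subset_geno(g, variants = which(!is.na(maf) & maf >= min_maf))

  dist <- numeric(0); r2a <- numeric(0)
  for (chr in unique(g$variants$chrom)) {
    cols <- which(g$variants$chrom == chr)
    pos <- g$variants$pos[cols]
    for (ii in seq_along(cols)) {
      jj <- which(pos - pos[ii] >= min_dist & pos - pos[ii] <= max_dist)
      for (j in jj) {
        x <- g$calls[, cols[ii]]; y <- g$calls[, cols[j]]
        ok <- !is.na(x) & !is.na(y)
        r2 <- .r2_pair(x, y)
        if (is.na(r2)) next
        dist <- c(dist, pos[j] - pos[ii])
        r2a <- c(r2a, r2 - 1 / sum(ok))
      }
    }
  }
  if (length(dist) == 0L) {
    warning("no qualifying variant pairs")
    return(data.frame(d_min = numeric(), d_max = numeric(),
                      mean_dist = numeric(), mean_c = numeric(),
                      mean_r2_adj = numeric(), n_pairs = integer()))
  }
  width <- (max_dist - min_dist) / n_bins
  bin <- pmin(floor((dist - min_dist) / width), n_bins - 1)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(k) {
    sel <- bin == k
    data.frame(d_min = min_dist + k * width, d_max = min_dist + (k + 1) * width,
               mean_dist = mean(dist[sel]),
               mean_c = mean(dist[sel]) * cm_per_mb * 1e-8,
               mean_r2_adj = mean(r2a[sel]), n_pairs = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

#' Effective-population-size trajectory from binned LD decay
#'
#' Inverts Sved's expectation `E[r2_adj] = 1 / (alpha + 4 Ne c)` per
#' distance bin: `Ne = (1/(4c)) * (1/mean_r2_adj - alpha_const)` with
#' `c = mean_dist * cm_per_mb * 1e-8`, dated `t = 1/(2c)` generations
#' before present. `alpha_const` encodes the mutation model (1: no
#' mutation; 2 or 2.2: with mutation).
#'
#' @param bins output of [ld_decay()].
#' @param alpha_const mutation-correction constant, one of 1, 2, 2.2
#'   (default 2).
#' @param min_pairs bins with fewer pairs are dropped (default 100).
#' @return data.frame: t (generations before present), ne, c, n_pairs.
#'   Bins whose mean r^2 makes Ne non-positive are skipped with a warning.
#' @export
estimate_ne <- function(bins, alpha_const = 2, min_pairs = 100L) {
  stopifnot(alpha_const %in% c(1, 2, 2.2))
  bins <- bins[bins$n_pairs >= min_pairs, , drop = FALSE]
  if (nrow(bins) == 0L) stop("no bins with enough pairs")
  c_rec <- bins$mean_c
  ne <- (1 / (4 * c_rec)) * (1 / bins$mean_r2_adj - alpha_const)
  ok <- is.finite(ne) & ne > 0 & bins$mean_r2_adj > 0
  if (any(!ok))
    warning(sprintf("%d bin(s) outside the estimator's domain skipped", sum(!ok)))
  data.frame(t = 1 / (2 * c_rec[ok]), ne = ne[ok], c = c_rec[ok],
             n_pairs = bins$n_pairs[ok])
}
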