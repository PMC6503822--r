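# Pileup-based diversity: depth filtering, per-site heterozygote calls,
# windowed heterozygosity, and maximum-likelihood co-estimation of the
# population mutation rate theta and the sequencing error rate epsilon.

.count_cols <- c("nA", "nC", "nG", "nT")

.check_pileup <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "depth", .count_cols) %in% names(sites)))
  n <- nrow(sites)
  if (n > 1L) {
    r <- rle(as.character(sites$chrom))
    if (anyDuplicated(r$values)) stop("pileup sites must be sorted by (chrom, pos)")
    d <- diff(sites$pos)
    block_end <- cumsum(r$lengths)                  # position jumps allowed
    d[block_end[-length(block_end)]] <- 1L          # across chromosome ends
    if (!all(d > 0L)) stop("pileup sites must be sorted by (chrom, pos)")
  }
  invisible(sites)
}

# fast subset of a pileup data.frame by integer/logical index
.pileup_rows <- function(sites, i) {
  out <- lapply(sites, `[`, i)
  attr(out, "row.names") <- .set_row_names(length(out[[1L]]))
  class(out) <- "data.frame"
  out
}

#' Depth-filter pileup sites
#'
#' Retains exactly the sites with depth between `min_depth` and `max_depth`
#' inclusive (defaults 4 and 30, the well-covered-site definition used for
#' all diversity statistics), preserving order.
#'
#' @param sites pileup data.frame (chrom, pos, depth, nA, nC, nG, nT),
#'   sorted by (chrom, pos).
#' @param min_depth,max_depth inclusive depth bounds.
#' @return the retained sites.
#' @export
filter_sites <- function(sites, min_depth = 4L, max_depth = 30L) {
  stopifnot(min_depth > 0, min_depth <= max_depth)
  .check_pileup(sites)
  .pileup_rows(sites, sites$depth >= min_depth & sites$depth <= max_depth)
}

# top-two base counts per site: L x 2 matrix (major, second);
# tournament of pmin/pmax, no row-wise sorting
.top2 <- function(sites) {
  hi1 <- pmax(sites$nA, sites$nC); lo1 <- pmin(sites$nA, sites$nC)
  hi2 <- pmax(sites$nG, sites$nT); lo2 <- pmin(sites$nG, sites$nT)
  cbind(pmax(hi1, hi2), pmax(pmin(hi1, hi2), lo1, lo2))
}

#' Call heterozygous sites from base counts
#'
#' A site is heterozygous when its second-most-frequent base is supported
#' by at least `min_alt_reads` reads and by at least `min_alt_fraction` of
#' the total reads (defaults 2 reads and 0.2, the minor-allele evidence
#' thresholds used at variant calling).
#'
#' @param sites depth-filtered pileup data.frame.
#' @param min_alt_reads minimum reads supporting the second base.
#' @param min_alt_fraction minimum fraction of total reads for the second base.
#' @return logical vector, one element per site.
#' @export
call_het <- function(sites, min_alt_reads = 2L, min_alt_fraction = 0.2) {
  if (nrow(sites) == 0L) return(logical(0))
  t2 <- .top2(sites)
  t2[, 2L] >= min_alt_reads & t2[, 2L] >= min_alt_fraction * sites$depth
}

# shared tiling machinery: aggregate covered/het counts into fixed bins
# tiled from coordinate 0 (0-based half-open internally)
.tile_counts <- function(sites, bin_size, het, end_bp = NULL) {
  r <- rle(as.character(sites$chrom))
  ix_all <- if (length(r$values) == 1L) list(seq_len(nrow(sites))) else
    split(seq_len(nrow(sites)),
          factor(rep.int(seq_along(r$values), r$lengths)))
  names(ix_all) <- NULL
  out <- lapply(ix_all, function(ix) {
    pos0 <- sites$pos[ix] - 1L
    bin <- pos0 %/% bin_size
    n_last <- if (is.null(end_bp)) max(bin) else (end_bp - 1L) %/% bin_size
    data.frame(chrom = sites$chrom[ix][1L],
               bin_index = 0:n_last,
               start = (0:n_last) * bin_size,
               end = if (is.null(end_bp)) (0:n_last + 1L) * bin_size
                     else pmin((0:n_last + 1L) * bin_size, end_bp),
               covered = tabulate(bin + 1L, nbins = n_last + 1L),
               het = tabulate(bin[het[ix]] + 1L, nbins = n_last + 1L))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Windowed heterozygosity along the genome
#'
#' Tiles each chromosome with non-overlapping windows of `window` bp from
#' coordinate 0 and reports, per window, the number of covered (filtered)
#' sites, the number of heterozygous sites, and their ratio. Windows whose
#' covered fraction falls below `min_covered_fraction` are flagged
#' (`flagged = TRUE`) and should be excluded from genome-wide averages;
#' their `het_rate` is `NA` when no site is covered.
#'
#' @param sites depth-filtered pileup sites.
#' @param window window size in bp (default 10000).
#' @param min_covered_fraction minimum covered fraction for an unflagged
#'   window (default 0.2).
#' @param genome_length optional genome length in bp, to emit trailing
#'   empty windows.
#' @param het optional precomputed [call_het()] vector for `sites`.
#' @param ... passed to [call_het()].
#' @return data.frame: chrom, start, end (0-based half-open), n_covered,
#'   n_het, het_rate, flagged.
#' @export
window_heterozygosity <- function(sites, window = 10000L,
                                  min_covered_fraction = 0.2,
                                  genome_length = NULL, het = NULL, ...) {
  stopifnot(window > 0)
  .check_pileup(sites)
  if (is.null(het)) het <- call_het(sites, ...)
  w <- .tile_counts(sites, window, het, end_bp = genome_length)
  data.frame(chrom = w$chrom, start = w$start, end = w$end,
             n_covered = w$covered, n_het = w$het,
             het_rate = ifelse(w$covered > 0, w$het / w$covered, NA_real_),
             flagged = w$covered < min_covered_fraction * (w$end - w$start))
}

# --- theta / epsilon maximum likelihood ------------------------------------

# collapse sites into unique (depth, n1, n2) likelihood patterns;
# the multinomial coefficient is constant in (theta, epsilon) and kept as
# an additive constant so the reported log-likelihood is the full one
.ml_patterns <- function(sites) {
  t2 <- .top2(sites)
  logcoef <- lgamma(sites$depth + 1) -
    rowSums(lgamma(as.matrix(sites[, .count_cols]) + 1))
  key <- (sites$depth * 64L + t2[, 1L]) * 64L + t2[, 2L]
  agg <- rowsum(cbind(w = 1, lc = logcoef), key)
  k <- as.numeric(rownames(agg))
  list(d = k %/% (64 * 64), n1 = (k %/% 64) %% 64, n2 = k %% 64,
       w = agg[, "w"], const = sum(agg[, "lc"]))
}

# full log-likelihood of the two-component (hom/het) mixture at (theta, eps)
.ml_loglik <- function(theta, eps, pat) {
  h <- theta / (1 + theta)
  # hom: major base true; P = (1-eps)^n1 * (eps/3)^(d - n1)
  lhom <- pat$n1 * log1p(-eps) + (pat$d - pat$n1) * log(eps / 3)
  # het: two top bases true; each read hits either allele with prob
  # (1-eps)/2 + eps/6, any other base with prob eps/3
  pa <- (1 - eps) / 2 + eps / 6
  lhet <- (pat$n1 + pat$n2) * log(pa) + (pat$d - pat$n1 - pat$n2) * log(eps / 3)
  # eps = 0 limits: 0 * log(0) terms are 0
  if (eps == 0) {
    lhom <- ifelse(pat$d == pat$n1, 0, -Inf)
    lhet <- ifelse(pat$d == pat$n1 + pat$n2, (pat$n1 + pat$n2) * log(0.5), -Inf)
  }
  mx <- pmax(lhom, lhet)
  site <- mx + log((1 - h) * exp(lhom - mx) + h * exp(lhet - mx))
  sum(pat$w * site) + pat$const
}

#' Co-estimate theta and the sequencing error rate from a pileup
#'
#' Maximises, over the per-site heterozygosity parameter theta and the
#' per-read error rate epsilon, the likelihood of the observed base counts
#' under a two-component mixture: each site is heterozygous with
#' probability `theta / (1 + theta)` (infinite-allele form; for small theta
#' this is the expected heterozygosity). Homozygous sites read the major
#' base, heterozygous sites draw either of the top-two bases with equal
#' probability; every read errs with probability epsilon, uniformly to the
#' three other bases. Optimisation is a bounded quasi-Newton search from a
#' small multistart grid (theta in {1e-4, 1e-3, 1e-2} crossed with epsilon
#' in {1e-3, 1e-2}), in log-parameter space, converged to 1e-8 in
#' log-likelihood.
#'
#' @param sites depth-filtered pileup sites with depth > 0.
#' @param min_sites below this many sites the estimate is flagged
#'   low-confidence (default 1000).
#' @return list of class `theta_estimate`: theta, epsilon, loglik, n_sites,
#'   low_confidence, at_boundary.
#' @export
estimate_theta_epsilon <- function(sites, min_sites = 1000L) {
  .check_pileup(sites)
  if (nrow(sites) == 0L || all(sites$depth == 0L))
    stop("no reads: cannot estimate theta/epsilon from zero-depth input")
  sites <- sites[sites$depth > 0L, , drop = FALSE]
  pat <- .ml_patterns(sites)

  lo <- log(c(1e-8, 1e-8)); hi <- log(c(0.5, 0.45))
  nll <- function(par) -.ml_loglik(exp(par[1L]), exp(par[2L]), pat)
  starts <- expand.grid(theta = c(1e-4, 1e-3, 1e-2), eps = c(1e-3, 1e-2))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- optim(log(as.numeric(starts[k, ])), nll, method = "L-BFGS-B",
                 lower = lo, upper = hi,
                 control = list(factr = 1e-8 / .Machine$double.eps))
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  theta <- exp(best$par[1L]); eps <- exp(best$par[2L])
  at_bound <- any(abs(best$par - lo) < 1e-6) || any(abs(best$par - hi) < 1e-6)
  structure(list(theta = theta, epsilon = eps, loglik = -best$value,
                 n_sites = nrow(sites),
                 low_confidence = nrow(sites) < min_sites,
                 at_boundary = at_bound),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("theta = %.6g, epsilon = %.6g (loglik %.3f, %d sites%s)\n",
              x$theta, x$epsilon, x$loglik, x$n_sites,
              if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}
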