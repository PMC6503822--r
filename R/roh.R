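# Bin-based runs-of-homozygosity caller. The genome is tiled in 10-kb bins;
# a run seeds at a bin whose heterozygous-SNP count is below 0.25x the
# genome average, extends while individual bins stay below 2x the average
# and the run mean stays below 2/3 of the average, and is reported when at
# least 20 consecutive bins (200 kb) qualify. Diversity is then summarised
# inside (pi_in) and outside (pi_out) the called runs.

#' ROH caller parameters
#'
#' @param bin_size bin width in bp (default 10000).
#' @param seed_factor a run may open at a bin with SNP count below
#'   `seed_factor` times the genome average (default 0.25).
#' @param bin_ceiling_factor individual bins inside a run may hold at most
#'   this multiple of the genome average (default 2).
#' @param run_mean_factor the running mean SNP count of a run may not
#'   exceed this multiple of the genome average (default 2/3).
#' @param min_bins minimum consecutive bins per reported run (default 20).
#' @param min_length minimum run length in bp (default `min_bins * bin_size`).
#' @param max_gap_bins no-data bins tolerated inside a run without breaking
#'   it (default 2; a longer gap ends the run).
#' @param max_exception_bins consecutive bins at or above the seed
#'   threshold tolerated inside a run (default 3). The relaxation exists to
#'   absorb isolated noisy bins (local assembly or alignment artifacts);
#'   bounding the exception stretch keeps a run from coasting across
#'   ordinary-diversity sequence between two nearby homozygous tracts.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(bin_size = 10000L, seed_factor = 0.25,
                       bin_ceiling_factor = 2, run_mean_factor = 2 / 3,
                       min_bins = 20L, min_length = min_bins * bin_size,
                       max_gap_bins = 2L, max_exception_bins = 3L) {
  stopifnot(seed_factor > 0, seed_factor < run_mean_factor,
            run_mean_factor < bin_ceiling_factor, min_bins >= 1L,
            max_exception_bins >= 0L)
  structure(list(bin_size = as.integer(bin_size), seed_factor = seed_factor,
                 bin_ceiling_factor = bin_ceiling_factor,
                 run_mean_factor = run_mean_factor,
                 min_bins = as.integer(min_bins),
                 min_length = as.integer(min_length),
                 max_gap_bins = as.integer(max_gap_bins),
                 max_exception_bins = as.integer(max_exception_bins)),
            class = "roh_params")
}

#' Heterozygous-SNP counts in consecutive genome bins
#'
#' Tiles each chromosome with consecutive non-overlapping bins of
#' `bin_size` bp from coordinate 0 and counts covered sites and
#' heterozygous sites (per [call_het()]) per bin. Bins with fewer covered
#' sites than `min_covered_fraction` of the bin width are flagged
#' `no_data` and excluded from the genome-average SNP count.
#'
#' @param sites depth-filtered pileup sites.
#' @param bin_size bin width in bp (default 10000).
#' @param min_covered_fraction no-data threshold on the covered fraction
#'   (default 0.2).
#' @param genome_length optional length in bp to emit trailing empty bins.
#' @param het optional precomputed [call_het()] vector for `sites`.
#' @param ... passed to [call_het()].
#' @return data.frame: chrom, bin_index, start, end, snp_count,
#'   covered_sites, no_data.
#' @export
bin_counts <- function(sites, bin_size = 10000L, min_covered_fraction = 0.2,
                       genome_length = NULL, het = NULL, ...) {
  .check_pileup(sites)
  if (is.null(het)) het <- call_het(sites, ...)
  w <- .tile_counts(sites, bin_size, het, end_bp = genome_length)
  data.frame(chrom = w$chrom, bin_index = w$bin_index,
             start = w$start, end = w$end,
             snp_count = w$het, covered_sites = w$covered,
             no_data = w$covered < min_covered_fraction * (w$end - w$start))
}

#' Genome-average SNP count per bin
#'
#' Mean heterozygous-SNP count over non-flagged bins; the reference level
#' for all ROH thresholds.
#'
#' @param bins output of [bin_counts()].
#' @return a single number.
#' @export
genome_avg_snp <- function(bins) {
  ok <- !bins$no_data
  if (!any(ok)) stop("no covered bins")
  mean(bins$snp_count[ok])
}

#' Call runs of homozygosity from binned SNP counts
#'
#' Scans each chromosome left to right. A candidate run opens at a
#' non-flagged bin with `snp_count < seed_factor * genome_avg` and extends
#' over subsequent bins while each bin's count stays at or below
#' `bin_ceiling_factor * genome_avg` and the running mean count of the run
#' stays at or below `run_mean_factor * genome_avg`; bins at or above the
#' seed threshold are tolerated exceptions under those two rules (at most
#' `max_exception_bins` consecutively), but a run must end at a sub-seed
#' bin, so when extension fails the candidate is trimmed back to its last
#' sub-seed bin. Up to `max_gap_bins`
#' consecutive no-data bins inside a run neither extend nor break it; a
#' longer gap ends the run. The trimmed candidate is reported iff it spans
#' at least `min_bins` bins and `min_length` bp. Scanning resumes after a
#' reported run (reported runs are disjoint), or at the next bin otherwise.
#'
#' @param bins output of [bin_counts()] (bins consecutive per chromosome).
#' @param genome_avg genome-average SNP count per bin (> 0); see
#'   [genome_avg_snp()].
#' @param params a [roh_params()].
#' @return data.frame: chrom, start, end (0-based half-open bp), n_bins,
#'   mean_snp_per_bin.
#' @export
call_roh <- function(bins, genome_avg, params = roh_params()) {
  if (genome_avg <= 0) stop("genome_avg must be positive")
  stopifnot(inherits(params, "roh_params"))
  seed_thr <- params$seed_factor * genome_avg
  ceil_thr <- params$bin_ceiling_factor * genome_avg
  mean_thr <- params$run_mean_factor * genome_avg

  res <- list()
  for (chr in unique(bins$chrom)) {
    b <- bins[bins$chrom == chr, , drop = FALSE]
    if (any(diff(b$bin_index) != 1L)) stop("bins must be consecutive")
    n <- nrow(b)
    i <- 1L
    while (i <= n) {
      if (b$no_data[i] || b$snp_count[i] >= seed_thr) { i <- i + 1L; next }
      run_sum <- b$snp_count[i]; run_cnt <- 1L
      last_seed <- i                      # run must end at a sub-seed bin
      seed_sum <- run_sum; seed_cnt <- run_cnt
      gap <- 0L; exc <- 0L
      k <- i + 1L
      while (k <= n) {
        if (b$no_data[k]) {
          gap <- gap + 1L
          if (gap > params$max_gap_bins) break
        } else {
          if (b$snp_count[k] > ceil_thr) break
          if ((run_sum + b$snp_count[k]) / (run_cnt + 1L) > mean_thr) break
          if (b$snp_count[k] >= seed_thr) {
            exc <- exc + 1L
            if (exc > params$max_exception_bins) break
          }
          gap <- 0L
          run_sum <- run_sum + b$snp_count[k]; run_cnt <- run_cnt + 1L
          if (b$snp_count[k] < seed_thr) {
            exc <- 0L
            last_seed <- k; seed_sum <- run_sum; seed_cnt <- run_cnt
          }
        }
        k <- k + 1L
      }
      last_good <- last_seed
      run_sum <- seed_sum; run_cnt <- seed_cnt
      n_bins <- last_good - i + 1L
      len <- b$end[last_good] - b$start[i]
      if (n_bins >= params$min_bins && len >= params$min_length) {
        res[[length(res) + 1L]] <-
          data.frame(chrom = chr, start = b$start[i], end = b$end[last_good],
                     n_bins = n_bins, mean_snp_per_bin = run_sum / run_cnt)
        i <- last_good + 1L
      } else i <- i + 1L
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

# membership of positions (1-based) in a union of disjoint intervals
# (0-based half-open), per chromosome
.in_intervals <- function(chrom, pos, intervals) {
  inside <- logical(length(pos))
  for (chr in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == chr, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    sel <- chrom == chr
    if (!any(sel)) next
    p0 <- pos[sel] - 1L
    hit <- findInterval(p0, iv$start)
    inside[sel] <- hit > 0L & p0 < iv$end[pmax(hit, 1L)]
  }
  inside
}

#' Summarise ROH burden and diversity inside/outside ROH
#'
#' Computes the number of runs, their cumulative length, the fraction of
#' the assayed genome inside runs (F_ROH), and the heterozygous-site
#' fraction over covered sites inside (pi_in) and outside (pi_out) the run
#' union.
#'
#' @param intervals output of [call_roh()] (disjoint intervals).
#' @param sites depth-filtered pileup sites.
#' @param assayed_length assayed genome length in bp (> 0), e.g. total
#'   covered-bin length.
#' @param het optional precomputed [call_het()] vector for `sites`.
#' @param ... passed to [call_het()].
#' @return list of class `roh_summary`: n_roh, cum_length, f_roh, pi_in,
#'   pi_out.
#' @export
summarize_roh <- function(intervals, sites, assayed_length, het = NULL, ...) {
  if (assayed_length <= 0) stop("assayed_length must be positive")
  .check_pileup(sites)
  if (is.null(het)) het <- call_het(sites, ...)
  inside <- if (nrow(intervals) > 0L)
    .in_intervals(sites$chrom, sites$pos, intervals) else
    logical(nrow(sites))
  pi_of <- function(sel)
    if (any(sel)) sum(het[sel]) / sum(sel) else NA_real_
  cum_len <- if (nrow(intervals) > 0L)
    sum(intervals$end - intervals$start) else 0L
  structure(list(n_roh = nrow(intervals), cum_length = cum_len,
                 f_roh = cum_len / assayed_length,
                 pi_in = pi_of(inside), pi_out = pi_of(!inside)),
            class = "roh_summary")
}

#' @export
print.roh_summary <- function(x, ...) {
  cat(sprintf("ROH: n = %d, cumulative %.2f Mb (F_ROH = %.3f); pi_in = %s, pi_out = %s\n",
              x$n_roh, x$cum_length / 1e6, x$f_roh,
              format(x$pi_in, digits = 3), format(x$pi_out, digits = 3)))
  invisible(x)
}
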