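# Synthetic-data generators with known ground truth. All generators are
# deterministic given `seed` and return a `sim_truth` record sufficient to
# score the downstream estimators.

#' Ground-truth record for a simulation
#'
#' Container holding the generative parameters of a synthetic data set:
#' planted ROH coordinates, the true per-site heterozygosity theta, the
#' sequencing-error rate epsilon, the admixture proportion alpha, the
#' effective population size Ne, and the seed. Downstream recovery tests
#' score estimators against this record only.
#'
#' @param planted_roh data.frame with columns chrom, start, end
#'   (0-based half-open bp) or NULL.
#' @param theta_true,epsilon_true,alpha_true,ne_true generative parameters
#'   (NA where not applicable).
#' @param seed integer seed used.
#' @param ... extra named truth fields (e.g. stored true allele frequencies).
#' @return An object of class `sim_truth` (a named list).
#' @export
sim_truth <- function(planted_roh = NULL, theta_true = NA_real_,
                      epsilon_true = NA_real_, alpha_true = NA_real_,
                      ne_true = NA_real_, seed = NA_integer_, ...) {
  if (!is.null(planted_roh)) {
    stopifnot(is.data.frame(planted_roh),
              all(c("chrom", "start", "end") %in% names(planted_roh)))
    if (nrow(planted_roh) > 1L) {
      o <- order(planted_roh$chrom, planted_roh$start)
      planted_roh <- planted_roh[o, , drop = FALSE]
      same <- planted_roh$chrom[-1L] == planted_roh$chrom[-nrow(planted_roh)]
      if (any(same & planted_roh$start[-1L] < planted_roh$end[-nrow(planted_roh)]))
        stop("planted ROH intervals overlap")
    }
  }
  for (p in c(theta_true, epsilon_true, alpha_true))
    if (!is.na(p) && (p < 0 || p > 1)) stop("probabilities must lie in [0,1]")
  if (!is.na(ne_true) && ne_true < 2) stop("ne_true must be >= 2")
  structure(list(planted_roh = planted_roh, theta_true = theta_true,
                 epsilon_true = epsilon_true, alpha_true = alpha_true,
                 ne_true = ne_true, seed = seed, ...),
            class = "sim_truth")
}

# split `n_err` error reads uniformly over the 3 non-true bases; returns an
# L x 3 integer matrix (counts for the other bases in a fixed rotation order)
.split_errors <- function(n_err) {
  e1 <- rbinom(length(n_err), n_err, 1 / 3)
  e2 <- rbinom(length(n_err), n_err - e1, 1 / 2)
  cbind(e1, e2, n_err - e1 - e2)
}

#' Simulate a pileup genome with planted low-diversity tracts
#'
#' Generates one diploid genome as a per-site pileup table. Each site is
#' heterozygous with probability `theta` (multiplied by a residual factor
#' inside planted ROH tracts), read depth is Poisson(`mean_depth`), and each
#' read reports the true base except with probability `epsilon` it reports
#' one of the other three bases uniformly. At heterozygous sites each read
#' draws either allele with probability 1/2 before the error process.
#'
#' @param genome_length genome length in bp.
#' @param theta per-site heterozygosity, in [0, 0.1).
#' @param epsilon per-read error probability, in [0, 0.05).
#' @param mean_depth mean sequencing depth (reads).
#' @param roh_spec planted tracts: data.frame with columns start, end
#'   (0-based half-open bp) and factor (residual heterozygosity multiplier
#'   in [0,1]), or NULL for none.
#' @param seed integer seed (required; same seed gives identical output).
#' @param chrom chromosome name for the single simulated chromosome.
#' @return list with `sites` (data.frame: chrom, pos, depth, nA, nC, nG, nT;
#'   pos is 1-based) and `truth` (a [sim_truth()]).
#' @examples
#' g <- simulate_pileup_genome(5e4, theta = 0.002, epsilon = 0.002,
#'                             mean_depth = 10, seed = 1)
#' head(g$sites)
#' @export
simulate_pileup_genome <- function(genome_length, theta = 0.002,
                                   epsilon = 0.002, mean_depth = 10,
                                   roh_spec = NULL, seed, chrom = "chr1") {
  if (genome_length < 1) stop("genome_length must be >= 1")
  if (theta < 0 || theta >= 0.1) stop("theta must lie in [0, 0.1)")
  if (epsilon < 0 || epsilon >= 0.05) stop("epsilon must lie in [0, 0.05)")
  if (missing(seed)) stop("seed is required")
  L <- as.integer(genome_length)

  p_het <- rep(theta, L)
  if (!is.null(roh_spec)) {
    roh_spec <- as.data.frame(roh_spec)
    stopifnot(all(c("start", "end", "factor") %in% names(roh_spec)))
    if (any(roh_spec$factor < 0 | roh_spec$factor > 1))
      stop("residual het factors must lie in [0,1]")
    if (any(roh_spec$start < 0 | roh_spec$end > L | roh_spec$start >= roh_spec$end))
      stop("roh_spec intervals must lie within the genome")
    o <- order(roh_spec$start)
    roh_spec <- roh_spec[o, , drop = FALSE]
    if (nrow(roh_spec) > 1L &&
        any(roh_spec$start[-1L] < roh_spec$end[-nrow(roh_spec)]))
      stop("roh_spec intervals overlap")
    for (k in seq_len(nrow(roh_spec)))
      p_het[(roh_spec$start[k] + 1L):roh_spec$end[k]] <-
        theta * roh_spec$factor[k]
  }

  set.seed(seed)
  depth <- rpois(L, mean_depth)
  het <- runif(L) < p_het
  base1 <- 1L + as.integer(floor(runif(L) * 4))       # true (major) allele
  ih <- which(het)
  # second allele at het sites: uniform over the other 3 (rotation offset)
  base2 <- 1L + (base1[ih] - 1L + 1L + floor(runif(length(ih)) * 3)) %% 4L

  n1 <- depth                                          # reads from allele 1
  n1[ih] <- rbinom(length(ih), depth[ih], 0.5)
  n2 <- integer(L)                                     # reads from allele 2
  n2[ih] <- depth[ih] - n1[ih]
  err1 <- rbinom(L, n1, epsilon)
  err2 <- integer(L)
  err2[ih] <- rbinom(length(ih), n2[ih], epsilon)

  counts <- matrix(0L, nrow = L, ncol = 4L)
  idx <- seq_len(L)
  add <- function(rows, col, val) {                   # linear-index scatter
    k <- rows + (col - 1L) * L
    counts[k] <<- counts[k] + as.integer(val)
  }
  counts[idx + (base1 - 1L) * L] <- as.integer(n1 - err1)
  add(ih, base2, n2[ih] - err2[ih])
  # errors land uniformly on the 3 bases != the read's true base (rotation)
  ie1 <- which(err1 > 0L)
  if (length(ie1)) {
    s1 <- .split_errors(err1[ie1])
    for (r in 1:3) add(ie1, 1L + (base1[ie1] - 1L + r) %% 4L, s1[, r])
  }
  ie2 <- ih[err2[ih] > 0L]
  if (length(ie2)) {
    s2 <- .split_errors(err2[ie2])
    b2 <- base2[match(ie2, ih)]
    for (r in 1:3) add(ie2, 1L + (b2 - 1L + r) %% 4L, s2[, r])
  }

  sites <- list(chrom = rep(chrom, L), pos = idx, depth = depth,
                nA = counts[, 1L], nC = counts[, 2L],
                nG = counts[, 3L], nT = counts[, 4L])
  attr(sites, "row.names") <- .set_row_names(L)
  class(sites) <- "data.frame"
  planted <- if (is.null(roh_spec) || nrow(roh_spec) == 0L) NULL else
    data.frame(chrom = chrom, start = roh_spec$start, end = roh_spec$end)
  truth <- sim_truth(planted_roh = planted, theta_true = theta,
                     epsilon_true = epsilon, seed = seed,
                     het_sites = which(het), roh_factors = roh_spec$factor)
  list(sites = sites, truth = truth)
}

#' Random non-overlapping ROH tract layout
#'
#' Places `n_tracts` low-diversity tracts, one per equal genome slot, with
#' uniformly drawn offset and length (in bins). Slot placement guarantees
#' a gap of at least `2 * margin_bins` bins between consecutive tracts so
#' tracts stay separable by the caller.
#'
#' @param genome_length genome length in bp.
#' @param bin_size bin width in bp the tracts are aligned to.
#' @param n_tracts number of tracts.
#' @param len_bins integer range (min, max) of tract lengths in bins.
#' @param margin_bins minimum distance (bins) between a tract and its slot
#'   boundary.
#' @param factor residual heterozygosity multiplier of the tracts.
#' @param seed integer seed.
#' @return data.frame with start, end (0-based half-open bp) and factor,
#'   usable as `roh_spec` in [simulate_pileup_genome()].
#' @export
plant_roh_tracts <- function(genome_length, bin_size = 10000L, n_tracts = 10L,
                             len_bins = c(25L, 50L), margin_bins = 5L,
                             factor = 0, seed) {
  if (missing(seed)) stop("seed is required")
  n_bins <- genome_length %/% bin_size
  slot <- n_bins %/% n_tracts
  if (slot < max(len_bins) + 2L * margin_bins)
    stop("genome too short for the requested tract layout")
  set.seed(seed)
  len <- sample(len_bins[1L]:len_bins[2L], n_tracts, replace = TRUE)
  off <- vapply(slot - len - 2L * margin_bins, function(m)
    sample.int(m + 1L, 1L) - 1L, integer(1)) + margin_bins
  start <- ((seq_len(n_tracts) - 1L) * slot + off) * bin_size
  data.frame(start = start, end = start + len * bin_size, factor = factor)
}

# Balding-Nichols draw: descendant frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F)
.bn_drift <- function(p, f) {
  if (f <= 0 || f >= 1) stop("drift parameters must lie in (0,1)")
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

.geno_from_freq <- function(p, n_ind, prefix) {
  n_snps <- length(p)
  calls <- matrix(rbinom(n_ind * n_snps, 2L, rep(p, each = n_ind)),
                  nrow = n_ind)
  geno_matrix(calls,
              chrom = rep("1", n_snps), pos = seq_len(n_snps) * 3000L,
              ref = rep("A", n_snps), alt = rep("G", n_snps),
              samples = sprintf("%s%03d", prefix, seq_len(n_ind)))
}

#' Simulate three drift-related populations with an admixed target
#'
#' Ancestral allele frequencies are drawn uniformly on \[0.05, 0.95\].
#' Source populations A and B drift from the ancestor under the
#' Balding-Nichols model with coefficients `f_a` and `f_b`. The target C
#' mixes the two source frequencies as `alpha * p_A + (1 - alpha) * p_B`
#' and then drifts with coefficient `f_c`. Diploid genotypes are binomial
#' draws from each population's frequencies.
#'
#' @param n_snps number of independent SNPs.
#' @param f_a,f_b,f_c Balding-Nichols drift coefficients in (0,1).
#' @param alpha admixture proportion of A in the target, in \[0,1\].
#' @param n_per_pop diploid samples per population (>= 2).
#' @param seed integer seed.
#' @return list with geno_matrix elements `A`, `B`, `C` and `truth`, a
#'   [sim_truth()] carrying `freq_a`, `freq_b`, `freq_c` (realized true
#'   population frequencies, the oracle for population-level f3).
#' @export
simulate_admixed_panel <- function(n_snps, f_a = 0.05, f_b = 0.05,
                                   f_c = 0.001, alpha = 0.5,
                                   n_per_pop = 30, seed) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0,1]")
  if (n_per_pop < 2) stop("n_per_pop must be >= 2 (f3 bias correction undefined)")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  p_anc <- runif(n_snps, 0.05, 0.95)
  p_a <- .bn_drift(p_anc, f_a)
  p_b <- .bn_drift(p_anc, f_b)
  p_c <- .bn_drift(alpha * p_a + (1 - alpha) * p_b, f_c)
  panels <- list(A = .geno_from_freq(p_a, n_per_pop, "A"),
                 B = .geno_from_freq(p_b, n_per_pop, "B"),
                 C = .geno_from_freq(p_c, n_per_pop, "C"))
  truth <- sim_truth(alpha_true = alpha, seed = seed,
                     freq_a = p_a, freq_b = p_b, freq_c = p_c,
                     f_a = f_a, f_b = f_b, f_c = f_c)
  c(panels, list(truth = truth))
}

# multinomial sampling vectorised across systems by sequential binomials
.rmultinom_rows <- function(size, prob) {
  n <- nrow(prob)
  out <- matrix(0L, n, 4L)
  rem <- rep(as.integer(size), length.out = n)
  ptot <- rowSums(prob)
  for (k in 1:3) {
    pk <- ifelse(ptot > 0, pmin(1, pmax(0, prob[, k] / ptot)), 0)
    out[, k] <- rbinom(n, rem, pk)
    rem <- rem - out[, k]
    ptot <- ptot - prob[, k]
  }
  out[, 4L] <- rem
  out
}

# multivariate hypergeometric sampling (without replacement) per row
.rmvhyper_rows <- function(counts, k) {
  n <- nrow(counts)
  out <- matrix(0L, n, 4L)
  rem <- rep(as.integer(k), length.out = n)
  left <- rowSums(counts)
  for (j in 1:3) {
    out[, j] <- rhyper(n, counts[, j], left - counts[, j], rem)
    rem <- rem - out[, j]
    left <- left - counts[, j]
  }
  out[, 4L] <- rem
  out
}

#' Simulate independent two-locus Wright-Fisher systems
#'
#' Each system is a population of `2 * ne` haplotypes at two biallelic loci
#' separated by recombination fraction `c_rec`, evolved by Wright-Fisher
#' resampling with recombination from an initial state of linkage
#' equilibrium at allele frequency 0.5. After `generations` generations,
#' `n_sample` diploids are drawn without replacement and their genotypes
#' returned. At drift-recombination equilibrium the expected adjusted r^2
#' between the two loci is approximately Sved's 1 / (1 + 4 * ne * c_rec).
#'
#' @param ne diploid effective population size (>= 2). May be a vector of
#'   per-generation sizes of length `generations` (most ancient first) to
#'   simulate size changes such as a recent bottleneck.
#' @param c_rec recombination fraction between the loci, in (0, 0.5].
#' @param n_systems number of independent systems (locus pairs).
#' @param n_sample diploid individuals sampled per system.
#' @param generations generations to evolve; the default,
#'   `max(500, 3 / (2 * c_rec + 1 / max(ne)))`, is at least three LD
#'   relaxation time constants (LD equilibrates at rate about
#'   `2c + 1/(2 ne)` per generation), long enough for
#'   drift-recombination equilibrium of r^2 while most initial-frequency-
#'   0.5 loci still segregate.
#' @param seed integer seed.
#' @param cm_per_mb physical-to-genetic scaling used to place the pair on
#'   the physical map (default 1 cM/Mb), so that downstream distance
#'   binning recovers `c_rec` from positions.
#' @return list with `genotypes` (a [geno_matrix()]: `n_sample` samples by
#'   `2 * n_systems` loci, one chromosome per system) and `truth`.
#' @export
simulate_twolocus_wf <- function(ne, c_rec, n_systems, n_sample,
                                 generations = NULL, seed, cm_per_mb = 1) {
  if (any(ne < 2)) stop("ne must be >= 2")
  if (c_rec <= 0 || c_rec > 0.5) stop("c_rec must lie in (0, 0.5]")
  if (missing(seed)) stop("seed is required")
  if (is.null(generations))
    generations <- max(500L, as.integer(ceiling(3 / (2 * c_rec + 1 / max(ne)))))
  ne_t <- rep(ne, length.out = generations)
  if (n_sample > min(ne_t)) stop("n_sample cannot exceed the smallest ne")
  set.seed(seed)

  # haplotype counts per system: columns AB, Ab, aB, ab
  x <- t(stats::rmultinom(n_systems, 2L * ne_t[1L], rep(0.25, 4)))
  for (g in seq_len(generations)) {
    p <- x / rowSums(x)
    d <- p[, 1L] * p[, 4L] - p[, 2L] * p[, 3L]
    p1 <- cbind(p[, 1L] - c_rec * d, p[, 2L] + c_rec * d,
                p[, 3L] + c_rec * d, p[, 4L] - c_rec * d)
    p1[p1 < 0] <- 0
    x <- .rmultinom_rows(2L * ne_t[g], p1)
  }

  samp <- .rmvhyper_rows(x, 2L * n_sample)             # sampled haplotypes
  # random pairing into diploids: expand, shuffle within system, pair
  sys_id <- rep(seq_len(n_systems), each = 2L * n_sample)
  hap_type <- unlist(lapply(seq_len(n_systems),
                            function(i) rep.int(1:4, samp[i, ])))
  hap_type <- hap_type[order(sys_id, runif(length(hap_type)))]
  hap <- matrix(hap_type, nrow = 2L)                   # 2 x (n_sample*n_systems)
  al1 <- matrix(c(1L, 1L, 0L, 0L)[hap], nrow = 2L)     # allele at locus 1
  al2 <- matrix(c(1L, 0L, 1L, 0L)[hap], nrow = 2L)
  dose1 <- matrix(colSums(al1), nrow = n_sample)       # n_sample x n_systems
  dose2 <- matrix(colSums(al2), nrow = n_sample)

  calls <- matrix(0L, n_sample, 2L * n_systems)
  calls[, seq(1L, 2L * n_systems, by = 2L)] <- dose1
  calls[, seq(2L, 2L * n_systems, by = 2L)] <- dose2
  gap_bp <- max(1L, as.integer(round(c_rec * 1e8 / cm_per_mb)))
  gm <- geno_matrix(calls,
                    chrom = rep(sprintf("sys%05d", seq_len(n_systems)), each = 2L),
                    pos = rep(c(1L, 1L + gap_bp), n_systems),
                    ref = rep("A", 2L * n_systems),
                    alt = rep("G", 2L * n_systems),
                    samples = sprintf("ind%03d", seq_len(n_sample)))
  truth <- sim_truth(ne_true = ne_t[length(ne_t)], seed = seed,
                     c_rec = c_rec, ne_trajectory = ne_t,
                     generations = generations)
  list(genotypes = gm, truth = truth)
}
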