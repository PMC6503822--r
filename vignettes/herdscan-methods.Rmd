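---
title: "Methods: diversity, ROH, f3 and LD-based Ne in herdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, ROH, f3 and LD-based Ne in herdscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

herdscan implements the computational core of an individual-genome
population-genomics workflow for livestock: per-sample diversity from
sequencing pileups, runs of homozygosity (ROH), three-population f3
admixture tests from array-style genotypes, and LD-decay-based
effective-population-size (Ne) trajectories. Every estimator is paired
with a synthetic-data generator whose ground truth makes parameter
recovery directly checkable; the test suite and the acceptance script do
exactly that.

## Input model and coordinates

The sequencing stages consume per-site pileup tables (chromosome, 1-based
position, depth, and A/C/G/T read counts), assumed to come from an
upstream aligner and to have mapping- and base-quality filters already
applied. The genotype stages consume diploid dosage matrices (0/1/2,
missing allowed), e.g. parsed from VCF. Internally every interval is
0-based half-open; pileup and VCF positions are 1-based and BED output is
0-based half-open, with conversions confined to the I/O layer so no
off-by-one can drift through the statistics.

## Site filtering and the heterozygote call

Diversity statistics use only "well-covered" sites, depth 4-30 inclusive
(`filter_sites()`); below 4 reads a heterozygote is barely detectable and
above 30 the site is likely a collapsed repeat or CNV. A site is called
heterozygous when its second-most-frequent base has at least 2 reads
**and** at least 0.2 of the total (`call_het()`, both knobs
configurable). These are the minor-allele-evidence thresholds variant
callers use by default; we adopt them as the per-site rule because the
windowed statistic needs one.

A consequence worth stating plainly: at Poisson-distributed depth with
mean 10, this read-threshold rule detects only about 92-93% of true
heterozygous sites (at depth 4-9 both alleles must appear twice; at depth
11+ the 0.2 fraction rule demands 3+ reads), so window heterozygosity and
pi estimates sit a few percent below the generative per-site rate. This
is a property of all read-count het calls at modest coverage, not a bug;
the likelihood-based estimator below models the full count distribution
and does not share the bias.

## Maximum-likelihood theta and epsilon

`estimate_theta_epsilon()` co-estimates the population mutation rate
theta and the per-read error rate epsilon from the filtered pileup by
maximising

    sum_sites log[ (1 - h) P(counts | hom, eps) + h P(counts | het, eps) ],

with h = theta/(1 + theta), the infinite-allele form (for small theta, h
is simply the expected heterozygosity). Under homozygosity the true base
is the site's major base and each read errs with probability epsilon,
uniformly onto the three other bases; under heterozygosity the two true
alleles are the two most frequent bases and each read picks either with
probability 1/2 before the same error process. Both component
probabilities depend only on the depth and the top-two counts, so sites
are collapsed to unique (depth, n1, n2) patterns before optimisation —
a 5-Mb genome reduces to a few hundred patterns, and the multinomial
coefficients are carried as an additive constant so the reported
log-likelihood is the full one (the tests verify it against a per-site
enumeration to 1e-9).

Optimisation is L-BFGS-B in log-parameter space from a small multistart
grid (theta in 1e-4/1e-3/1e-2 crossed with epsilon in 1e-3/1e-2),
converged to 1e-8 in log-likelihood; mixture likelihoods can be flat and
the multistart is cheap. Estimates at the box boundary are flagged, as
are inputs under 1,000 sites.

## The ROH caller

`bin_counts()` tiles each chromosome with consecutive 10-kb bins from
coordinate 0 and counts covered sites and called heterozygotes per bin;
bins covered below 20% of their width are flagged no-data and excluded
from the genome average. `call_roh()` then scans each chromosome:

* a candidate run opens at a bin with SNP count below 0.25x the genome
  average;
* it extends while each bin stays at or below 2x the average and the
  running mean stays at or below 2/3 of the average;
* bins at or above the seed threshold are tolerated exceptions — at most
  3 consecutively — and a run must end at a sub-seed bin: when extension
  stops, the candidate is trimmed back to its last sub-seed bin;
* at most 2 consecutive no-data bins are bridged; a longer gap breaks
  the run;
* the trimmed candidate is reported iff it spans at least 20 bins and
  200 kb.

Two of these rules deserve their rationale. First, the exception bound:
the 2x/2-3 relaxation exists to absorb isolated bins inflated by local
assembly or alignment artifacts. Without a bound, the running-mean rule
alone would let a run coast across up to twice its own length of
ordinary-diversity sequence after a genuine tract (the mean budget of a
mostly-zero run is large), silently fusing nearby tracts; bounding
consecutive exceptions keeps the relaxation local, which is what it is
for. Second, ending at a sub-seed bin pins both boundaries to genuinely
homozygous bins, which is why planted-tract boundaries are recovered to
within one bin. The 20-bin minimum (200 kb at 10-kb bins) is the operative
length rule; a separate `min_length` override exists for other bin sizes.

The seed threshold compares bin SNP *counts* to 0.25x the genome-average
count per bin rather than per-bp diversity; with uniform coverage the two
are proportional, and a count-based rule is robust to the no-data
flagging. `summarize_roh()` reports N_ROH, cumulative length, F_ROH
(cumulative length over assayed length) and the het-site fraction over
covered sites inside (pi_in) and outside (pi_out) the run union.

The caller is verified two ways: bin-identical agreement with an
independent brute-force enumeration of the same rules on random bin
tables, and sensitivity/precision >= 0.95 at bin level on genomes with
planted zero-heterozygosity tracts.

## Genotype QC and LD pruning

`qc_filter()` applies, in fixed order: drop samples with more than 10%
missing genotypes, then variants missing in more than 5% of the retained
samples, then variants with minor allele frequency below 1% — the
standard PLINK-style thresholds for array data (`--mind 0.1`,
`--geno 0.05`, `--maf 0.01`). The order matters and re-running is a
no-op.

LD is measured as the squared Pearson correlation of unphased dosages
(Rogers-Huff composite r2) over samples complete at both variants, with
pairs below 5 complete observations flagged undefined. Phasing is out of
scope, and composite r2 is the accepted array-data practice.
`ld_prune()` does greedy windowed pruning (50 SNPs, step 5 — PLINK-style
defaults, since only the target r2 < 0.10 is dictated by the analysis):
within a window, while any retained pair exceeds the ceiling, the member
of the worst pair with the lower MAF is dropped (ties drop the later
position). An exhaustive post-check in the tests confirms no surviving
within-window pair exceeds 0.10.

## The f3 admixture test

For a target C and references A and B, the per-SNP statistic is

    (c - a)(c - b) - c(1 - c) / (n_hap_C - 1),

averaged over SNPs (`f3_test()`). The subtracted term is the
finite-sample correction for sampling noise in the target frequency
(Reich-style); reference-population noise inflates the variance but not
the bias of the product, so only the target term is corrected. Variants
monomorphic across all three populations are excluded as zero-information.
Standard errors come from a delete-one-block jackknife over contiguous
blocks of 1,000 SNPs in genome order (the block length quoted for the
graph-fitting analysis this mirrors; the weighted form handles the ragged
last block, and with equal blocks it reduces exactly to the classical SE
of block means). Z = f3/SE, and Z < -3 is flagged significant — proof of
admixture in the target.

With light target drift and an alpha/(1-alpha) mixture, the population-
level expectation is f3 -> -alpha(1-alpha) mean((p_A - p_B)^2), which the
tests verify in closed form; simulated panels are scored against the
brute-force f3 computed from the generator's stored true frequencies.

## LD decay and Ne

`ld_decay()` enumerates intra-chromosome variant pairs separated by
5 kb - 2 Mb (inclusive), after a MAF >= 0.05 filter — the run parameters
of the LD-decay tool this stage mirrors (50 equal-width distance bins).
Each pair's r2 is adjusted for sample size as r2 - 1/n (n = complete-case
sample count) and bin means are reported. `estimate_ne()` inverts Sved's
expectation E[r2] = 1/(alpha + 4 Ne c) per bin:

    Ne = (1 / 4c) (1 / r2_adj - alpha),   t = 1 / (2c) generations,

with the physical-to-genetic map fixed at 1 cM/Mb (configurable
constant) and alpha in {1, 2, 2.2} encoding the mutation model (default
2; the recovery analyses on mutation-free Wright-Fisher simulations use
alpha = 1, the matching model). Bins whose mean r2 puts Ne outside its
domain are skipped with a warning. The estimator round-trips exact Sved
curves with zero error.

Two honest caveats. The 1/n adjustment slightly over-corrects dosage r2
(the actual sampling inflation is close to (1 - r2)^2/n), which biases
recovered Ne upward by roughly 10% at n = 50 — inside the recovery
tolerance, and kept because the plain 1/n form is what the mirrored tool
uses. And Sved's formula is itself an approximation to the equilibrium
r2 of segregating loci; the two-locus simulations sit a few percent
below it.

## The synthetic-data generators

`simulate_pileup_genome()` draws per-site heterozygosity directly as
P(het) = theta (valid for theta << 1; no coalescent machinery, so every
recovery target stays analytic), Poisson depth, and a uniform
substitution error model — the simplest model consistent with a single
epsilon. Planted tracts multiply theta by a residual factor, emulating
autozygous segments. It does **not** emulate mapping error, CNV-driven
depth, indels, or base-quality variation; passing tests say the
estimators recover their own generative model, not that real alignments
are artifact-free.

`simulate_admixed_panel()` uses the Balding-Nichols model (descendant
frequency Beta-distributed around the ancestor, drift coefficient F) —
standard, closed-form, and it makes the f3 sign analytically predictable.
Ancestral frequencies are uniform on [0.05, 0.95], mimicking an
ascertained SNP panel.

`simulate_twolocus_wf()` evolves independent two-locus haplotype
populations by Wright-Fisher resampling with recombination from linkage
equilibrium at frequency 0.5, then samples diploids without replacement.
The burn-in default, max(500, three LD relaxation time constants
3/(2c + 1/Ne)), was fixed once after checking drift-recombination
equilibrium against Sved's expectation: long enough for r2 to
equilibrate, short enough that most loci still segregate (fixation, not
equilibration, is the binding constraint at large generation counts).
`ne` may be a per-generation vector, which is how the bottleneck
contrasts are generated. Mutation is not modelled; downstream analyses
use the MAF filter to condition on segregation, as the mirrored tools do.

All generators are bit-reproducible from their seed, and their `SimTruth`
record (planted tract coordinates, true theta/epsilon/alpha/Ne, realized
population frequencies) is sufficient to score every downstream
estimator.

## Problem sizes and numerical conventions

The acceptance-grade checks run at: 20 seeds x 10-Mb genomes for ROH
recovery (10 planted tracts of 25-50 bins each); 20 seeds x 5-Mb genomes
for theta/epsilon (tolerances 10% and 25%); 20 seeds x 50,000-SNP panels
with 30 diploids per population for f3 (Z < -3 in >= 18/20 admixed runs);
2,000 two-locus systems with 50 sampled diploids for Ne recovery (within
25%); 20 replicate pairs for each demographic contrast, compared by
one-sided paired Wilcoxon tests. These sizes keep every recovery target
well inside its tolerance at desk scale. Ties in the ROH caller are
impossible by construction (deterministic scan order); ties in LD pruning
drop the later position; windows tile from coordinate 0; degenerate
inputs (all-monomorphic sites, zero-depth pileups, empty populations,
all-dropped samples) raise immediate errors or flagged boundary
estimates rather than silent numbers.

## Known limitations

* pi-type statistics inherit the het-call detection shortfall described
  above (about -7% at 10x Poisson coverage with the 4-30x filter); use
  the likelihood estimator when an unbiased theta is the goal.
* The f3 implementation targets the standard use case (one target, two
  references, genome-order SNP blocks); genetic-distance blocking and f4/D
  statistics are out of scope.
* Ne trajectories assume a constant recombination map (1 cM/Mb by
  default) and inherit Sved-approximation bias of order a few percent.
* The VCF reader handles diploid GT (phased or unphased) with optional
  GQ/DP call filtering; multi-allelic records and indels are dropped by
  design, mirroring the upstream variant-filtering recipe.
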