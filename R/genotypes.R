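# Diploid genotype matrix container shared by the QC, f3 and LD stages.

#' Diploid genotype matrix
#'
#' Samples-by-variants matrix of alternate-allele dosages in {0, 1, 2},
#' with `NA` for missing calls, plus variant records (chrom, 1-based pos,
#' ref/alt alleles). Positions must be strictly increasing within each
#' chromosome.
#'
#' @param calls integer matrix, samples x variants, values 0/1/2/NA.
#' @param chrom,pos,ref,alt per-variant records; `pos` is 1-based bp.
#' @param samples character vector of sample identifiers.
#' @return object of class `geno_matrix`: list with `calls` (rownames =
#'   samples) and `variants` (data.frame chrom, pos, ref, alt).
#' @export
geno_matrix <- function(calls, chrom, pos, ref, alt, samples) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c(0L, 1L, 2L, NA)))
    stop("calls must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  if (length(chrom) != ncol(calls) || length(pos) != ncol(calls))
    stop("variant records must match the number of call columns")
  if (length(samples) != nrow(calls))
    stop("samples must match the number of call rows")
  by_chrom <- split(pos, chrom)
  if (any(vapply(by_chrom, function(p) any(diff(p) <= 0), logical(1))))
    stop("positions must be strictly increasing within each chromosome")
  rownames(calls) <- samples
  structure(list(calls = calls,
                 variants = data.frame(chrom = as.character(chrom),
                                       pos = as.integer(pos),
                                       ref = as.character(ref),
                                       alt = as.character(alt))),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d variants (%d chromosome(s)), %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$variants$chrom)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

# subset variants (columns) and/or samples (rows), keeping records in step
subset_geno <- function(g, samples = NULL, variants = NULL) {
  calls <- g$calls
  if (!is.null(samples)) calls <- calls[samples, , drop = FALSE]
  if (!is.null(variants)) calls <- calls[, variants, drop = FALSE]
  v <- g$variants
  if (!is.null(variants)) v <- v[variants, , drop = FALSE]
  rownames(v) <- NULL
  structure(list(calls = calls, variants = v), class = "geno_matrix")
}

#' Combine genotype panels sharing the same variants
#'
#' Stacks the samples of several `geno_matrix` objects that describe the
#' same variant set (e.g. the three populations of a simulated admixture
#' panel) into one matrix, for joint allele-frequency computation.
#'
#' @param ... geno_matrix objects with identical variant records.
#' @return a single [geno_matrix()].
#' @export
bind_genotypes <- function(...) {
  gs <- list(...)
  stopifnot(length(gs) >= 1L,
            all(vapply(gs, inherits, logical(1), "geno_matrix")))
  v0 <- gs[[1L]]$variants
  for (g in gs[-1L])
    if (!identical(g$variants$chrom, v0$chrom) ||
        !identical(g$variants$pos, v0$pos))
      stop("panels must share identical variant records")
  calls <- do.call(rbind, lapply(gs, `[[`, "calls"))
  if (anyDuplicated(rownames(calls))) stop("duplicate sample ids across panels")
  structure(list(calls = calls, variants = v0), class = "geno_matrix")
}

# minor allele frequency per variant, complete-case
.maf <- function(calls) {
  f <- colMeans(calls, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}
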