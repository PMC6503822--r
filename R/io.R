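# Readers and writers for the standard text formats used by the pipeline.
# Pileup and VCF positions are 1-based; BED is 0-based half-open; internal
# intervals are 0-based half-open, so BED writes coordinates unchanged.

#' Read a per-site pileup table
#'
#' Tab-separated columns: chrom, pos (1-based), depth, nA, nC, nG, nT.
#'
#' @param path file path.
#' @return pileup data.frame sorted as stored.
#' @export
read_pileup <- function(path) {
  x <- read.table(path, header = FALSE, sep = "\t",
                  col.names = c("chrom", "pos", "depth", .count_cols),
                  colClasses = c("character", rep("integer", 6L)))
  bad <- which(x$depth != x$nA + x$nC + x$nG + x$nT)
  if (length(bad))
    stop(sprintf("pileup line %d: depth does not equal the base-count sum", bad[1L]))
  x
}

#' Write a per-site pileup table
#' @param sites pileup data.frame.
#' @param path file path.
#' @export
write_pileup <- function(sites, path) {
  write.table(sites[, c("chrom", "pos", "depth", .count_cols)], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses diploid GT calls from a VCF (via vcfR), keeping biallelic SNVs
#' only: indels and multi-allelic records are dropped, with counts in
#' attribute `drop_log`. Missing genotypes (`./.`) become `NA`. When the
#' VCF carries GQ and/or DP per call, calls failing `min_gq` or the
#' `dp_range` are set missing; otherwise those filters are skipped with a
#' notice.
#'
#' @param path VCF file path.
#' @param min_gq minimum genotype quality (default 30); `NULL` disables.
#' @param dp_range inclusive per-call depth range (default `c(4, 30)`);
#'   `NULL` disables.
#' @return a [geno_matrix()] with attribute `drop_log`.
#' @export
read_vcf <- function(path, min_gq = 30, dp_range = c(4, 30)) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)     # single-record VCF drops dims
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snv <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  indel <- !snv & !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  core <- gsub("|", "/", substr(gt, 1L, 3L), fixed = TRUE)
  dose[core == "0/0"] <- 0L
  dose[core %in% c("0/1", "1/0")] <- 1L
  dose[core == "1/1"] <- 2L

  fmt <- v@gt[, 1L]
  apply_call_filter <- function(name, keep_fun) {
    if (all(grepl(name, fmt))) {
      x <- suppressWarnings(
        matrix(as.numeric(vcfR::extract.gt(v, element = name)),
               nrow = nrow(gt)))
      dose[!is.na(x) & !keep_fun(x)] <<- NA_integer_
    } else message(sprintf("read_vcf: no %s field; filter skipped", name))
  }
  if (!is.null(min_gq)) apply_call_filter("GQ", function(x) x >= min_gq)
  if (!is.null(dp_range))
    apply_call_filter("DP", function(x) x >= dp_range[1L] & x <= dp_range[2L])

  keep <- which(snv)
  g <- geno_matrix(t(dose[keep, , drop = FALSE]),
                   chrom = fix[keep, "CHROM"],
                   pos = as.integer(fix[keep, "POS"]),
                   ref = ref[keep], alt = alt[keep],
                   samples = colnames(gt))
  attr(g, "drop_log") <- data.frame(reason = c("indel", "multiallelic"),
                                    dropped = c(sum(indel), sum(multi)))
  g
}

#' Write a genotype matrix as VCF 4.2
#' @param g a [geno_matrix()].
#' @param path file path.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g$calls)), collapse = "\t")),
             con)
  gt_of <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(g$calls)), function(j) {
    d <- g$calls[, j]
    gt <- ifelse(is.na(d), "./.", gt_of[d + 1L])
    paste(c(g$variants$chrom[j], g$variants$pos[j], ".",
            g$variants$ref[j], g$variants$alt[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#' @param intervals data.frame with chrom, start, end (already 0-based
#'   half-open internally, written unchanged).
#' @param path file path.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)),
            all(intervals$start >= 0), all(intervals$end > intervals$start))
  write.table(intervals[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 0-based half-open intervals
#' @param path file path.
#' @return data.frame chrom, start, end.
#' @export
read_bed <- function(path) {
  read.table(path, header = FALSE, sep = "\t",
             col.names = c("chrom", "start", "end"),
             colClasses = c("character", "integer", "integer"))
}

#' Write a table as TSV with header
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records every run parameter, the seed, and an md5 hash of each input
#' file, as JSON; enough to reproduce a run bit-for-bit.
#'
#' @param params named list of parameters (must include any seed used).
#' @param inputs character vector of input file paths (hashed).
#' @param path output JSON path.
#' @export
write_manifest <- function(params, inputs = character(0), path) {
  stopifnot(is.list(params))
  manifest <- list(params = params,
                   inputs = lapply(setNames(as.list(inputs), inputs),
                                   function(f) unname(tools::md5sum(f))),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
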