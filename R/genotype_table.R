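#' Genotype table
#'
#' The common currency of the pipeline: a samples x variants matrix of
#' alternate-allele dosages (0, 1, 2 or `NA` for missing), together with
#' variant coordinates and per-sample line labels.
#'
#' @param dosages numeric or integer matrix, one row per sample, one column
#'   per variant; entries in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `chrom` (character), `pos`
#'   (1-based bp, integer), `ref`, `alt` (single bases). Must be sorted by
#'   (chromosome, position).
#' @param samples data.frame with columns `sample_id` and `line`.
#' @param chrom_lengths optional named vector of chromosome lengths in bp;
#'   used to anchor terminal windows. When absent, the largest observed
#'   position per chromosome is used.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(dosages, variants, samples, chrom_lengths = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  stopifnot(is.data.frame(variants), is.data.frame(samples))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
    stop("variants must have columns chrom, pos, ref, alt")
  if (!all(c("sample_id", "line") %in% names(samples)))
    stop("samples must have columns sample_id, line")
  if (nrow(dosages) != nrow(samples))
    stop("dosage rows (", nrow(dosages), ") != number of samples (",
         nrow(samples), ")")
  if (ncol(dosages) != nrow(variants))
    stop("dosage columns (", ncol(dosages), ") != number of variants (",
         nrow(variants), ")")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  ord <- order(chrom_order(variants$chrom), variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, , drop = FALSE]
    dosages <- dosages[, ord, drop = FALSE]
  }
  if (any(nchar(variants$ref) != 1L) || any(nchar(variants$alt) != 1L))
    stop("only biallelic SNPs (single-base ref and alt) are allowed")
  dimnames(dosages) <- list(samples$sample_id, NULL)
  rownames(variants) <- NULL
  structure(
    list(dosages = dosages, variants = variants, samples = samples,
         chrom_lengths = chrom_lengths),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "variants on", length(unique(x$variants$chrom)), "chromosome(s)\n")
  cat("lines:", paste(sprintf("%s (n=%d)", names(table(x$samples$line)),
                              as.integer(table(x$samples$line))),
                      collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("missing entries: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosages)

n_samples <- function(gt) nrow(gt$dosages)
n_variants <- function(gt) ncol(gt$dosages)

#' Subset a genotype table
#'
#' @param gt a `genotype_table`.
#' @param sites integer or logical index over variants.
#' @param samples integer or logical index over samples.
#' @return A `genotype_table` restricted to the requested sites/samples.
#' @export
gt_subset <- function(gt, sites = NULL, samples = NULL) {
  d <- gt$dosages
  v <- gt$variants
  s <- gt$samples
  if (!is.null(sites)) {
    d <- d[, sites, drop = FALSE]
    v <- v[sites, , drop = FALSE]
  }
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    s <- s[samples, , drop = FALSE]
  }
  rownames(v) <- NULL
  rownames(s) <- NULL
  genotype_table(d, v, s, chrom_lengths = gt$chrom_lengths)
}

# Row indices for one line (or a set of pooled lines).
line_rows <- function(gt, line) {
  idx <- which(gt$samples$line %in% line)
  if (!length(idx))
    stop("unknown line label(s): ", paste(line, collapse = ", "))
  idx
}

#' Read a sample-to-line population map
#'
#' Two-column tab-separated text: sample id, line label. A header row
#' (`sample_id<TAB>line`) is accepted and skipped.
#'
#' @param path file path.
#' @return data.frame with columns `sample_id`, `line`.
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("population map not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("sample_id", "line"))
  if (nrow(tab) && tab$sample_id[1] == "sample_id") tab <- tab[-1, , drop = FALSE]
  if (anyDuplicated(tab$sample_id))
    stop("duplicated sample ids in population map")
  rownames(tab) <- NULL
  tab
}

#' Write a population map
#' @param pops data.frame with `sample_id` and `line`.
#' @param path destination path.
#' @export
write_population_map <- function(pops, path) {
  utils::write.table(pops[, c("sample_id", "line")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Quality-control configuration
#'
#' Thresholds mirroring the standard chip/WGS comparability filter set:
#' sites with missing rate strictly above `max_site_missing` are dropped,
#' then samples strictly above `max_sample_missing`; non-autosomal sites are
#' excluded when `autosomes_only`. LD pruning uses a sliding window of
#' `ld_window_snps` SNPs advanced by `ld_step_snps`, removing the later site
#' of any pair with squared dosage correlation above `ld_r2_max`.
#'
#' The autosome list defaults to chicken (GRCg7b) autosome names "1".."39";
#' chromosome naming dialects vary, so it is a configuration value rather
#' than an inference.
#'
#' @param max_site_missing maximum tolerated per-site missing rate.
#' @param max_sample_missing maximum tolerated per-sample missing rate.
#' @param autosomes_only drop sites not on a listed autosome.
#' @param autosomes character vector of autosome names.
#' @param ld_window_snps window size in SNPs.
#' @param ld_step_snps step size in SNPs.
#' @param ld_r2_max r-squared threshold above which the later site is pruned.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(max_site_missing = 0.01,
                      max_sample_missing = 0.05,
                      autosomes_only = TRUE,
                      autosomes = as.character(1:39),
                      ld_window_snps = 50L,
                      ld_step_snps = 5L,
                      ld_r2_max = 0.2) {
  stopifnot(max_site_missing >= 0, max_site_missing <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1,
            ld_step_snps >= 1, ld_window_snps >= ld_step_snps,
            ld_r2_max >= 0)
  structure(list(max_site_missing = max_site_missing,
                 max_sample_missing = max_sample_missing,
                 autosomes_only = autosomes_only,
                 autosomes = as.character(autosomes),
                 ld_window_snps = as.integer(ld_window_snps),
                 ld_step_snps = as.integer(ld_step_snps),
                 ld_r2_max = ld_r2_max),
            class = "qc_config")
}
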