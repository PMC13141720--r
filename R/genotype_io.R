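#' Read genotypes from a VCF file
#'
#' Decodes diploid GT fields into alternate-allele dosages. Phased (`|`) and
#' unphased (`/`) separators are both accepted; `./.` (or `.`) becomes
#' missing. Multi-allelic records and non-SNP records are dropped, with the
#' counts recorded in the `"dropped_records"` attribute of the result.
#'
#' @param path VCF v4.x file (plain text or bgzipped).
#' @param population_map either a path to a two-column tab-separated map
#'   (sample id, line) or a data.frame with columns `sample_id`, `line`.
#'   Every sample in the VCF must appear in the map.
#' @return A [genotype_table()].
#' @export
read_vcf <- function(path, population_map) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  pops <- if (is.character(population_map)) read_population_map(population_map)
          else as.data.frame(population_map, stringsAsFactors = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  is_snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L
  n_dropped <- sum(!is_snp)
  if (n_dropped)
    message("read_vcf: dropped ", n_dropped, " multi-allelic or non-SNP record(s)")

  gt_str <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_str)))
    gt_str <- matrix(gt_str, nrow = nrow(fix),
                     dimnames = list(NULL, names(gt_str)))
  vcf_samples <- colnames(gt_str)
  absent <- setdiff(vcf_samples, pops$sample_id)
  if (length(absent))
    stop("sample(s) in VCF absent from population map: ",
         paste(absent, collapse = ", "))

  gt_str <- gt_str[is_snp, , drop = FALSE]
  chrom <- chrom[is_snp]; pos <- pos[is_snp]
  ref <- ref[is_snp]; alt <- alt[is_snp]

  d <- decode_gt(gt_str, chrom, pos)
  samples <- data.frame(
    sample_id = vcf_samples,
    line = pops$line[match(vcf_samples, pops$sample_id)],
    stringsAsFactors = FALSE
  )
  out <- genotype_table(t(d), data.frame(chrom = chrom, pos = pos, ref = ref,
                                         alt = alt, stringsAsFactors = FALSE),
                        samples)
  attr(out, "dropped_records") <- n_dropped
  out
}

# GT strings (variants x samples) -> integer dosage matrix, same shape.
decode_gt <- function(gt_str, chrom, pos) {
  lut <- c("0/0" = 0L, "0|0" = 0L,
           "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
           "1/1" = 2L, "1|1" = 2L)
  core <- sub(":.*$", "", as.vector(gt_str))
  d <- lut[core]
  miss <- is.na(core) | core %in% c("./.", ".|.", ".")
  bad <- which(is.na(d) & !miss)
  if (length(bad)) {
    rec <- ((bad[1] - 1L) %% nrow(gt_str)) + 1L
    stop("malformed GT '", core[bad[1]], "' at ", chrom[rec], ":", pos[rec])
  }
  d[miss] <- NA_integer_
  matrix(d, nrow = nrow(gt_str), dimnames = dimnames(gt_str))
}

#' Write a genotype table as VCF v4.2
#'
#' Emits a minimal GT-only VCF (unphased separators, missing as `./.`) that
#' round-trips through [read_vcf()] to an identical table.
#'
#' @param gt a `genotype_table`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  chroms <- unique(gt$variants$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=chipconcord",
    sprintf("##contig=<ID=%s>", chroms),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt$samples$sample_id), collapse = "\t")
  )
  writeLines(header, con)
  if (ncol(gt$dosages) > 0) {
    codes <- c("0/0", "0/1", "1/1")
    gstr <- matrix("./.", nrow = ncol(gt$dosages), ncol = nrow(gt$dosages))
    dt <- t(gt$dosages)
    ok <- !is.na(dt)
    gstr[ok] <- codes[dt[ok] + 1L]
    fix <- paste(gt$variants$chrom, gt$variants$pos, ".", gt$variants$ref,
                 gt$variants$alt, ".", "PASS", ".", "GT", sep = "\t")
    lines <- do.call(paste, c(list(fix), asplit(gstr, 2), list(sep = "\t")))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Apply marker and sample quality control
#'
#' Filtering order is fixed: non-autosomal sites first (when configured),
#' then sites whose missing rate strictly exceeds `max_site_missing`, then
#' samples whose missing rate (over surviving sites) strictly exceeds
#' `max_sample_missing`. Exact-boundary sites and samples are retained.
#'
#' @param gt a `genotype_table`.
#' @param cfg a [qc_config()].
#' @return Filtered `genotype_table` with a `"filter_report"` attribute
#'   (counts removed per rule).
#' @export
apply_qc <- function(gt, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  report <- list(n_sites_in = n_variants(gt), n_samples_in = n_samples(gt))

  keep_auto <- rep(TRUE, n_variants(gt))
  if (isTRUE(cfg$autosomes_only))
    keep_auto <- gt$variants$chrom %in% cfg$autosomes
  report$n_sites_non_autosomal <- sum(!keep_auto)

  d <- gt$dosages[, keep_auto, drop = FALSE]
  site_miss <- colMeans(is.na(d))
  keep_site <- site_miss <= cfg$max_site_missing
  report$n_sites_high_missing <- sum(!keep_site)

  d <- d[, keep_site, drop = FALSE]
  if (ncol(d) == 0) stop("apply_qc removed all sites")
  sample_miss <- rowMeans(is.na(d))
  keep_sample <- sample_miss <= cfg$max_sample_missing
  report$n_samples_high_missing <- sum(!keep_sample)
  if (!any(keep_sample)) stop("apply_qc removed all samples")

  sites <- which(keep_auto)[keep_site]
  out <- gt_subset(gt, sites = sites, samples = which(keep_sample))
  report$n_sites_out <- n_variants(out)
  report$n_samples_out <- n_samples(out)
  attr(out, "filter_report") <- report
  out
}

#' Write a QC filter report as JSON
#' @param gt a table returned by [apply_qc()].
#' @param path destination path.
#' @export
write_filter_report <- function(gt, path) {
  rep <- attr(gt, "filter_report")
  if (is.null(rep)) stop("no filter_report attribute; run apply_qc first")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' LD pruning by sliding window over SNP dosages
#'
#' Greedy within-window pruning per chromosome: pairs in each window are
#' scanned in genomic order and the later site of any pair with squared
#' Pearson dosage correlation above `ld_r2_max` is removed; windows advance
#' by `ld_step_snps` over the surviving sites and passes repeat until a full
#' pass removes nothing. r-squared uses pairwise-complete observations;
#' zero-variance sites are treated as uncorrelated. The earlier (left-most)
#' site of a correlated pair is always the one kept, so the first site of a
#' chromosome is never removed and the result is deterministic.
#'
#' @param gt a `genotype_table`.
#' @param cfg a [qc_config()]; fields `ld_window_snps`, `ld_step_snps`,
#'   `ld_r2_max` are used.
#' @return Pruned `genotype_table`.
#' @export
ld_prune <- function(gt, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  keep <- rep(TRUE, n_variants(gt))
  for (ch in unique(gt$variants$chrom)) {
    idx <- which(gt$variants$chrom == ch)
    keep[idx] <- prune_chrom(gt$dosages[, idx, drop = FALSE],
                             cfg$ld_window_snps, cfg$ld_step_snps,
                             cfg$ld_r2_max)
  }
  gt_subset(gt, sites = which(keep))
}

# One chromosome of greedy windowed pruning. Each pass enumerates, once, all
# site pairs within `window - 1` positions of each other on the current alive
# list whose pairwise-complete r-squared exceeds the threshold (banded
# correlations via blocked cross-products), then replays the windowed greedy
# scan over those candidate pairs only - pairs at or below the threshold can
# never cause a removal, so this is exactly the per-window pair scan.
prune_chrom <- function(d, window, step, r2_max) {
  m <- ncol(d)
  keep <- rep(TRUE, m)
  if (m < 2L || window < 2L) return(keep)
  repeat {
    alive <- which(keep)
    na <- length(alive)
    if (na < 2L) break
    cand <- banded_high_ld_pairs(d, alive, window - 1L, r2_max)
    removed <- FALSE
    if (nrow(cand)) {
      cand <- cand[order(cand$i, cand$j), , drop = FALSE]
      for (s in seq.int(1L, na, by = step)) {
        e <- min(s + window - 1L, na)
        sel <- which(cand$i >= s & cand$j <= e)
        for (t in sel) {
          a <- alive[cand$i[t]]
          b <- alive[cand$j[t]]
          if (keep[a] && keep[b]) {
            keep[b] <- FALSE   # later site of the pair is removed
            removed <- TRUE
          }
        }
      }
    }
    if (!removed) break
  }
  keep
}

# All pairs (i < j, j - i <= band, indices into `alive`) with
# pairwise-complete squared Pearson dosage correlation above r2_max.
# Zero-variance or non-overlapping pairs count as uncorrelated.
banded_high_ld_pairs <- function(d, alive, band, r2_max, block = 512L) {
  na <- length(alive)
  out_i <- integer(0)
  out_j <- integer(0)
  s <- 1L
  while (s < na) {
    e <- min(s + block + band - 1L, na)
    x <- d[, alive[s:e], drop = FALSE]
    w <- (!is.na(x)) * 1
    x0 <- x
    x0[is.na(x0)] <- 0L
    storage.mode(x0) <- "double"
    n <- crossprod(w)
    sx <- crossprod(x0, w)       # [i,j] = sum of x_i over pairwise-complete samples
    sxx <- crossprod(x0 * x0, w)
    sxy <- crossprod(x0)
    num <- n * sxy - sx * t(sx)
    vi <- n * sxx - sx * sx
    den <- vi * t(vi)
    r2 <- matrix(0, nrow(n), ncol(n))
    pos <- den > 0
    r2[pos] <- num[pos]^2 / den[pos]
    hits <- which(r2 > r2_max, arr.ind = TRUE)
    if (nrow(hits)) {
      ii <- hits[, 1]
      jj <- hits[, 2]
      ok <- ii < jj & (jj - ii) <= band & ii <= block  # core rows only: dedupe overlap
      out_i <- c(out_i, s - 1L + ii[ok])
      out_j <- c(out_j, s - 1L + jj[ok])
    }
    s <- s + block
  }
  data.frame(i = out_i, j = out_j)
}
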