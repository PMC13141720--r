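#' Per-site allele statistics for one line
#'
#' @param gt a `genotype_table`.
#' @param line line label (or character vector of labels to pool).
#' @return data.frame with one row per site: `chrom`, `pos`, `alt_count`,
#'   `called` (called allele count, 2 x called genotypes), `freq`
#'   (alt_count / called, `NA` when no genotype is called) and `het_count`
#'   (heterozygous genotypes, used by the F_ST kernel).
#' @export
allele_stats <- function(gt, line) {
  d <- gt$dosages[line_rows(gt, line), , drop = FALSE]
  called_gt <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  called <- 2L * called_gt
  data.frame(chrom = gt$variants$chrom,
             pos = gt$variants$pos,
             alt_count = alt,
             called = called,
             freq = ifelse(called > 0, alt / called, NA_real_),
             het_count = colSums(d == 1L, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' Per-line heterozygosity and allele-frequency summary
#'
#' Per site within a line (over called genotypes only): Ho is the fraction of
#' heterozygotes, p the alternate-allele frequency, He = 2p(1-p) and
#' MAF = min(p, 1-p). Line-level values are unweighted means over all sites
#' with at least one called genotype, polymorphic or not. An optional
#' small-sample correction (x 2n/(2n-1)) for He can be switched on; it is off
#' by default.
#'
#' @param gt a `genotype_table`.
#' @param pops optional data.frame (`sample_id`, `line`) overriding the
#'   table's own labels.
#' @param he_correction apply the 2n/(2n-1) small-sample factor to He.
#' @return data.frame with one row per line: `line`, `n_samples`, `ho`,
#'   `he`, `maf`.
#' @export
heterozygosity_summary <- function(gt, pops = NULL, he_correction = FALSE) {
  if (!is.null(pops)) {
    gt$samples$line <- pops$line[match(gt$samples$sample_id, pops$sample_id)]
  }
  lines <- sort(unique(gt$samples$line))
  res <- lapply(lines, function(ln) {
    d <- gt$dosages[line_rows(gt, ln), , drop = FALSE]
    called <- colSums(!is.na(d))
    use <- called > 0
    if (!any(use)) stop("line ", ln, " has no called sites")
    p <- colSums(d, na.rm = TRUE)[use] / (2 * called[use])
    ho <- colSums(d == 1L, na.rm = TRUE)[use] / called[use]
    he <- 2 * p * (1 - p)
    if (he_correction) he <- he * (2 * called[use]) / (2 * called[use] - 1)
    data.frame(line = ln, n_samples = nrow(d), ho = mean(ho), he = mean(he),
               maf = mean(pmin(p, 1 - p)), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Sliding-window grid anchored at position 1; terminal partial windows kept.
window_grid <- function(chrom_len, window_bp, step_bp) {
  starts <- seq.int(1L, max(1L, chrom_len), by = step_bp)
  starts <- starts[starts <= chrom_len]
  ends <- pmin(starts + window_bp - 1, chrom_len)
  data.frame(start = starts, end = ends)
}

chrom_len_for <- function(gt, ch) {
  if (!is.null(gt$chrom_lengths) && ch %in% names(gt$chrom_lengths))
    return(as.numeric(gt$chrom_lengths[[ch]]))
  max(gt$variants$pos[gt$variants$chrom == ch])
}

# Sum a per-site vector over every window of a grid via cumulative sums.
window_sums <- function(pos, values, grid) {
  o <- order(pos)
  pos <- pos[o]; values <- values[o]
  cs <- c(0, cumsum(values))
  cn <- c(0, cumsum(rep(1, length(values))))
  lo <- findInterval(grid$start - 0.5, pos)
  hi <- findInterval(grid$end + 0.5, pos)
  list(sum = cs[hi + 1] - cs[lo + 1], n = cn[hi + 1] - cn[lo + 1])
}

#' Windowed nucleotide diversity
#'
#' Per site, the unbiased pairwise-diversity term
#' 2 c (n - c) / (n (n - 1)) with c the alternate-allele count and n the
#' called allele count; per window, the sum of per-site terms divided by the
#' window span in bp (so invariant positions implicitly contribute zero, the
#' convention of windowed-diversity tools operating on variant-only input).
#' Windows are 1-based inclusive, anchored at position 1, advancing by
#' `step_bp`; terminal partial windows are normalized by their actual span.
#' Sites with fewer than two called alleles are skipped (counted in the
#' `"skipped_sites"` attribute). Empty windows are reported with pi = 0.
#'
#' @param gt a `genotype_table`.
#' @param line line label (or labels to pool).
#' @param window_bp window size in bp (default 100 kb).
#' @param step_bp step size in bp (default 30 kb).
#' @return data.frame of windows: `chrom`, `start`, `end`, `n_sites`, `pi`.
#' @export
windowed_pi <- function(gt, line, window_bp = 1e5, step_bp = 3e4) {
  stopifnot(step_bp >= 1, window_bp >= step_bp)
  st <- allele_stats(gt, line)
  ok <- st$called >= 2
  n_skip <- sum(!ok)
  persite <- with(st[ok, ], 2 * alt_count * (called - alt_count) /
                    (called * (called - 1)))
  out <- lapply(unique(gt$variants$chrom), function(ch) {
    grid <- window_grid(chrom_len_for(gt, ch), window_bp, step_bp)
    sel <- st$chrom[ok] == ch
    ws <- window_sums(st$pos[ok][sel], persite[sel], grid)
    data.frame(chrom = ch, start = grid$start, end = grid$end,
               n_sites = ws$n, pi = ws$sum / (grid$end - grid$start + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "skipped_sites") <- n_skip
  out
}

#' Per-line and genome-wide diversity report
#'
#' Composes [heterozygosity_summary()] with windowed diversity. The
#' genome-wide pi per line is the length-weighted mean of non-overlapping
#' 100-kb window values (equivalently, the summed per-site diversity divided
#' by total genome span covered by windows).
#'
#' @param gt a `genotype_table`.
#' @param pops optional sample map override.
#' @param window_bp,step_bp sliding-window parameters for the per-window
#'   tables (defaults 100 kb / 30 kb).
#' @return list with `summary` (line, n_samples, ho, he, maf, pi) and
#'   `windows` (named list of per-line sliding-window tables).
#' @export
diversity_report <- function(gt, pops = NULL, window_bp = 1e5, step_bp = 3e4) {
  summ <- heterozygosity_summary(gt, pops)
  windows <- list()
  pi_gw <- numeric(nrow(summ))
  for (i in seq_len(nrow(summ))) {
    ln <- summ$line[i]
    windows[[ln]] <- windowed_pi(gt, ln, window_bp, step_bp)
    wp <- windowed_pi(gt, ln, window_bp, window_bp)  # partition for genome mean
    span <- wp$end - wp$start + 1
    pi_gw[i] <- sum(wp$pi * span) / sum(span)
  }
  summ$pi <- pi_gw
  list(summary = summ, windows = windows)
}
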