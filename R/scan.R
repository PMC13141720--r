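#' Flag windows in the top fraction of an empirical distribution
#'
#' The threshold is the value of the ceiling(fraction * N)-th largest among
#' the N non-missing window values; every window with value >= threshold is
#' flagged, so ties at the threshold are all included.
#'
#' @param windows data.frame of windows (must contain `chrom`, `start`,
#'   `end` and the statistic column).
#' @param statistic name of the statistic column.
#' @param fraction top fraction to flag, in (0, 1); default 0.05.
#' @return list of class `candidate_regions` with fields `statistic`,
#'   `fraction`, `threshold`, `windows` (flagged rows), `n_total`.
#' @export
empirical_top_fraction <- function(windows, statistic, fraction = 0.05) {
  stopifnot(fraction > 0, fraction < 1, statistic %in% names(windows))
  v <- windows[[statistic]]
  keep <- !is.na(v)
  n <- sum(keep)
  if (n == 0) stop("no non-missing values for statistic ", statistic)
  k <- ceiling(fraction * n)
  threshold <- sort(v[keep], decreasing = TRUE)[k]
  flagged <- keep & v >= threshold
  structure(list(statistic = statistic,
                 fraction = fraction,
                 threshold = threshold,
                 windows = windows[flagged, , drop = FALSE],
                 n_total = n),
            class = "candidate_regions")
}

#' @export
print.candidate_regions <- function(x, ...) {
  cat("candidate_regions:", nrow(x$windows), "of", x$n_total,
      "windows flagged\n")
  cat(sprintf("statistic %s, top %.1f%%, empirical threshold %.4f\n",
              x$statistic, 100 * x$fraction, x$threshold))
  invisible(x)
}

#' Joint F_ST / diversity-ratio selection scan between two lines
#'
#' Windows are matched across the three inputs by coordinates. Per window,
#' `log2_pi_ratio = log2(pi_X / pi_Y)`. Flagged windows are those in the top
#' `fst_fraction` of F_ST AND in either tail (below the `ratio_tail_fraction`
#' quantile or above the 1 - `ratio_tail_fraction` quantile) of the log2
#' ratio. Each flagged window is labeled with the line of reduced diversity
#' (X when the ratio is on the negative side, Y otherwise). Windows with
#' zero diversity in either line have an undefined log ratio; they are
#' excluded from quantile estimation and reported separately in
#' `zero_pi_windows`.
#'
#' Tail thresholds use the same inclusive order-statistic rule as
#' [empirical_top_fraction()].
#'
#' @param fst_windows windowed F_ST table for the X-Y pair.
#' @param pi_windows_x,pi_windows_y windowed diversity tables for X and Y on
#'   the same grid.
#' @param fst_fraction top F_ST fraction (default 0.05).
#' @param ratio_tail_fraction per-tail fraction of the log2 ratio
#'   distribution (default 0.025).
#' @param label_x,label_y line names used in the reduced-diversity label.
#' @return list of class `candidate_regions` with the joint threshold pair
#'   and a `reduced_line` column in `windows`.
#' @export
fst_pi_joint_scan <- function(fst_windows, pi_windows_x, pi_windows_y,
                              fst_fraction = 0.05,
                              ratio_tail_fraction = 0.025,
                              label_x = "X", label_y = "Y") {
  key <- function(w) paste(w$chrom, w$start, w$end, sep = ":")
  kx <- key(pi_windows_x)
  m1 <- match(key(fst_windows), kx)
  m2 <- match(key(fst_windows), key(pi_windows_y))
  ok <- !is.na(m1) & !is.na(m2)
  if (!any(ok)) stop("no coordinate overlap between F_ST and pi windows")
  w <- fst_windows[ok, c("chrom", "start", "end", "n_sites", "fst")]
  w$pi_x <- pi_windows_x$pi[m1[ok]]
  w$pi_y <- pi_windows_y$pi[m2[ok]]
  pos_pi <- w$pi_x > 0 & w$pi_y > 0
  w$log2_pi_ratio <- ifelse(pos_pi, log2(w$pi_x / w$pi_y), NA_real_)

  fst_ok <- !is.na(w$fst)
  n_fst <- sum(fst_ok)
  if (n_fst == 0) stop("no non-missing F_ST values")
  fst_thr <- sort(w$fst[fst_ok], decreasing = TRUE)[ceiling(fst_fraction * n_fst)]

  ratio <- w$log2_pi_ratio[!is.na(w$log2_pi_ratio)]
  n_r <- length(ratio)
  if (n_r == 0) stop("no windows with positive diversity in both lines")
  k <- ceiling(ratio_tail_fraction * n_r)
  lo_thr <- sort(ratio)[k]
  hi_thr <- sort(ratio, decreasing = TRUE)[k]

  flagged <- fst_ok & !is.na(w$log2_pi_ratio) & w$fst >= fst_thr &
    (w$log2_pi_ratio <= lo_thr | w$log2_pi_ratio >= hi_thr)
  wf <- w[flagged, , drop = FALSE]
  wf$reduced_line <- ifelse(wf$log2_pi_ratio <= lo_thr, label_x, label_y)
  structure(list(statistic = "fst_pi_joint",
                 fraction = fst_fraction,
                 ratio_tail_fraction = ratio_tail_fraction,
                 threshold = fst_thr,
                 ratio_thresholds = c(lower = lo_thr, upper = hi_thr),
                 windows = wf,
                 zero_pi_windows = w[!pos_pi, , drop = FALSE],
                 n_total = nrow(w)),
            class = "candidate_regions")
}

#' Write flagged windows as a BED file
#'
#' BED uses 0-based half-open coordinates; window start - 1 and end are
#' written, so a 1-based inclusive window `[1, 100000]` becomes
#' `0 100000`.
#'
#' @param regions a `candidate_regions` object.
#' @param path destination path.
#' @export
write_regions_bed <- function(regions, path) {
  w <- regions$windows
  bed <- data.frame(w$chrom, w$start - 1L, w$end,
                    paste0(regions$statistic, "_", seq_len(nrow(w))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
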