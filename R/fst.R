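#' Weir-Cockerham per-site variance components for two populations
#'
#' The 1984 method-of-moments components for population differentiation:
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals), computed from per-population sample sizes,
#' alternate-allele frequencies and observed heterozygote fractions. The
#' per-site estimator is a/(a+b+c); windowed estimates use the ratio of sums.
#'
#' All arguments are vectorized over sites.
#'
#' @param n1,n2 called diploid sample sizes in each population.
#' @param p1,p2 alternate-allele frequencies.
#' @param h1,h2 observed heterozygote fractions (heterozygotes / called).
#' @return list with numeric vectors `a`, `b`, `c`.
#' @export
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  n_bar <- (n1 + n2) / 2
  nc <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  inner <- p_bar * (1 - p_bar) - (r - 1) / r * s2
  a <- (n_bar / nc) * (s2 - (inner - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (inner - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  list(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham F_ST between two lines
#'
#' Per-site variance components are summed within sliding windows and the
#' window estimate is sum(a) / sum(a+b+c) (the ratio-of-sums, or "weighted",
#' estimator). Sites where either line has fewer than two called genotypes
#' are skipped; windows whose summed denominator is zero (no usable sites,
#' or all sites monomorphic across both lines) are reported with `fst = NA`.
#' Negative values are reported as computed, without clamping.
#'
#' @param gt a `genotype_table`.
#' @param line_x,line_y line labels (or label vectors to pool).
#' @param window_bp window size in bp (default 100 kb).
#' @param step_bp step size in bp (default 30 kb).
#' @return data.frame of windows: `chrom`, `start`, `end`, `n_sites`, `fst`.
#' @export
windowed_fst <- function(gt, line_x, line_y, window_bp = 1e5, step_bp = 3e4) {
  stopifnot(step_bp >= 1, window_bp >= step_bp)
  sx <- allele_stats(gt, line_x)
  sy <- allele_stats(gt, line_y)
  nx <- sx$called / 2; ny <- sy$called / 2
  ok <- nx >= 2 & ny >= 2
  comp <- wc_components(nx[ok], sx$freq[ok], sx$het_count[ok] / nx[ok],
                        ny[ok], sy$freq[ok], sy$het_count[ok] / ny[ok])
  denom <- comp$a + comp$b + comp$c
  out <- lapply(unique(gt$variants$chrom), function(ch) {
    grid <- window_grid(chrom_len_for(gt, ch), window_bp, step_bp)
    sel <- sx$chrom[ok] == ch
    pos <- sx$pos[ok][sel]
    wa <- window_sums(pos, comp$a[sel], grid)
    wd <- window_sums(pos, denom[sel], grid)
    fst <- ifelse(wd$sum != 0, wa$sum / wd$sum, NA_real_)
    data.frame(chrom = ch, start = grid$start, end = grid$end,
               n_sites = wa$n, fst = fst, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Locus-specific branch length
#'
#' LSBL for focal population X against references Y and Z isolates
#' differentiation on the branch leading to X:
#' `(F_ST(X,Y) + F_ST(X,Z) - F_ST(Y,Z)) / 2`. Vectorized; a missing F_ST
#' propagates to a missing LSBL.
#'
#' @param fst_xy,fst_xz,fst_yz window-matched F_ST values.
#' @return numeric vector of LSBL values.
#' @export
lsbl <- function(fst_xy, fst_xz, fst_yz) {
  (fst_xy + fst_xz - fst_yz) / 2
}

#' Genome-wide LSBL scan for a focal population
#'
#' Computes the three pairwise windowed F_ST tables on one shared grid of
#' non-overlapping windows (step = window, the convention for LSBL scans)
#' and combines them per window.
#'
#' @param gt a `genotype_table`.
#' @param focal focal line label(s); pooled when a vector (e.g. both lines
#'   of one breed).
#' @param ref1,ref2 reference line labels.
#' @param window_bp window size in bp (default 100 kb); step equals window.
#' @return data.frame of windows with columns `chrom`, `start`, `end`,
#'   `n_sites`, `fst_xy`, `fst_xz`, `fst_yz`, `lsbl`.
#' @export
lsbl_scan <- function(gt, focal, ref1, ref2, window_bp = 1e5) {
  fxy <- windowed_fst(gt, focal, ref1, window_bp, window_bp)
  fxz <- windowed_fst(gt, focal, ref2, window_bp, window_bp)
  fyz <- windowed_fst(gt, ref1, ref2, window_bp, window_bp)
  stopifnot(identical(fxy[c("chrom", "start", "end")],
                      fxz[c("chrom", "start", "end")]),
            identical(fxy[c("chrom", "start", "end")],
                      fyz[c("chrom", "start", "end")]))
  data.frame(fxy[c("chrom", "start", "end", "n_sites")],
             fst_xy = fxy$fst, fst_xz = fxz$fst, fst_yz = fyz$fst,
             lsbl = lsbl(fxy$fst, fxz$fst, fyz$fst),
             stringsAsFactors = FALSE)
}
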