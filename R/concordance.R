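#' Sign-aligned per-component correlation of two PCA results
#'
#' Principal-component signs are arbitrary per platform, so for each
#' component the sign of the second result is chosen to maximize the Pearson
#' correlation before reporting it (equivalently, the absolute correlation
#' is reported along with the chosen sign).
#'
#' @param a,b `pca_result` objects on identical sample sets (matched by id).
#' @param n_components number of leading components to compare (default 2).
#' @return data.frame with `component`, `r` (after sign alignment), `sign`.
#' @export
align_and_correlate_pcs <- function(a, b, n_components = 2L) {
  ia <- rownames(a$scores); ib <- rownames(b$scores)
  if (!setequal(ia, ib)) {
    d <- c(setdiff(ia, ib), setdiff(ib, ia))
    stop("sample sets differ between PCA results: ", paste(d, collapse = ", "))
  }
  bs <- b$scores[match(ia, ib), , drop = FALSE]
  k <- min(n_components, ncol(a$scores), ncol(bs))
  r <- numeric(k); sgn <- numeric(k)
  for (j in seq_len(k)) {
    rj <- stats::cor(a$scores[, j], bs[, j])
    sgn[j] <- if (rj < 0) -1 else 1
    r[j] <- abs(rj)
  }
  data.frame(component = paste0("PC", seq_len(k)), r = r, sign = sgn,
             stringsAsFactors = FALSE)
}

#' Rank concordance of per-line diversity between two platforms
#'
#' @param a,b diversity summary data.frames (from [diversity_report()]'s
#'   `summary` or [heterozygosity_summary()]), sharing line labels.
#' @param stats columns to compare (default He and pi where present).
#' @return data.frame with `statistic`, `spearman_rho` (NA when fewer than 3
#'   lines) and `ordering_match` (TRUE iff rank vectors are identical).
#' @export
diversity_rank_concordance <- function(a, b, stats = intersect(c("he", "pi"),
                                                               intersect(names(a), names(b)))) {
  if (!setequal(a$line, b$line)) stop("line labels differ")
  b <- b[match(a$line, b$line), , drop = FALSE]
  res <- lapply(stats, function(s) {
    ra <- rank(a[[s]]); rb <- rank(b[[s]])
    rho <- if (length(ra) >= 3) stats::cor(ra, rb, method = "spearman")
           else NA_real_
    data.frame(statistic = s, spearman_rho = rho,
               ordering_match = identical(ra, rb), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Candidate-region overlap between two platforms
#'
#' Flagged windows are first merged per chromosome into maximal regions
#' (adjacent or overlapping windows fused), then compared: the Jaccard index
#' is overlapping bp / union bp under 1-based inclusive coordinates, and
#' reciprocal counts report how many regions of each set are hit (>= 1 bp)
#' by the other.
#'
#' @param a,b `candidate_regions` objects in the same coordinate space.
#' @return list with `jaccard`, `n_regions_a`, `n_regions_b`, `a_hit_by_b`,
#'   `b_hit_by_a`.
#' @export
region_overlap <- function(a, b) {
  merge_regions <- function(w) {
    if (nrow(w) == 0) return(NULL)
    lapply(split(w, w$chrom), function(x)
      IRanges::reduce(IRanges::IRanges(start = x$start, end = x$end)))
  }
  ra <- merge_regions(a$windows)
  rb <- merge_regions(b$windows)
  if (is.null(ra) || is.null(rb)) {
    warning("empty candidate set on one side; Jaccard reported as 0")
    return(list(jaccard = 0,
                n_regions_a = if (is.null(ra)) 0L else sum(vapply(ra, length, 1L)),
                n_regions_b = if (is.null(rb)) 0L else sum(vapply(rb, length, 1L)),
                a_hit_by_b = 0L, b_hit_by_a = 0L))
  }
  chroms <- union(names(ra), names(rb))
  inter_bp <- union_bp <- 0
  a_hit <- b_hit <- 0L
  for (ch in chroms) {
    x <- ra[[ch]] %||% IRanges::IRanges()
    y <- rb[[ch]] %||% IRanges::IRanges()
    inter_bp <- inter_bp + sum(IRanges::width(IRanges::intersect(x, y)))
    union_bp <- union_bp + sum(IRanges::width(IRanges::union(x, y)))
    a_hit <- a_hit + sum(IRanges::countOverlaps(x, y) > 0)
    b_hit <- b_hit + sum(IRanges::countOverlaps(y, x) > 0)
  }
  list(jaccard = if (union_bp > 0) inter_bp / union_bp else 0,
       n_regions_a = sum(vapply(ra, length, 1L)),
       n_regions_b = sum(vapply(rb, length, 1L)),
       a_hit_by_b = a_hit, b_hit_by_a = b_hit)
}

#' Ancestry-matrix agreement after best column permutation
#'
#' Q columns are identifiable only up to permutation, so the RMSE between
#' two Q matrices is minimized over all K! column permutations (K <= 8
#' enforced).
#'
#' @param qa,qb samples x K ancestry matrices with equal dimensions (rows
#'   matched by name when both are named).
#' @return list with `rmse` and `permutation` (columns of `qb` matched to
#'   `qa`).
#' @export
q_matrix_agreement <- function(qa, qb) {
  qa <- as.matrix(qa); qb <- as.matrix(qb)
  if (!all(dim(qa) == dim(qb))) stop("Q matrices must have equal dimensions (same K and samples)")
  k <- ncol(qa)
  if (k > 8) stop("K > 8 not supported for exhaustive permutation matching")
  if (!is.null(rownames(qa)) && !is.null(rownames(qb))) {
    if (!setequal(rownames(qa), rownames(qb))) stop("sample sets differ")
    qb <- qb[match(rownames(qa), rownames(qb)), , drop = FALSE]
  }
  best <- Inf
  best_perm <- seq_len(k)
  for (perm in all_permutations(k)) {
    rmse <- sqrt(mean((qa - qb[, perm, drop = FALSE])^2))
    if (rmse < best) {
      best <- rmse
      best_perm <- perm
    }
  }
  list(rmse = best, permutation = best_perm)
}

#' Assemble a cross-platform concordance report
#'
#' @param pca_a,pca_b `pca_result` objects for the two platforms.
#' @param div_a,div_b per-line diversity summaries.
#' @param regions_a,regions_b optional `candidate_regions` objects.
#' @param qa,qb optional Q matrices at matching K.
#' @param n_components PCs to compare.
#' @return list of class `concordance_report`.
#' @export
concordance_report <- function(pca_a, pca_b, div_a, div_b,
                               regions_a = NULL, regions_b = NULL,
                               qa = NULL, qb = NULL, n_components = 2L) {
  rep <- list(pc_correlation = align_and_correlate_pcs(pca_a, pca_b,
                                                       n_components),
              diversity_ranks = diversity_rank_concordance(div_a, div_b))
  if (!is.null(regions_a) && !is.null(regions_b))
    rep$region_overlap <- region_overlap(regions_a, regions_b)
  if (!is.null(qa) && !is.null(qb))
    rep$ancestry_rmse <- q_matrix_agreement(qa, qb)$rmse
  class(rep) <- "concordance_report"
  rep
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Cross-platform concordance\n")
  for (i in seq_len(nrow(x$pc_correlation)))
    cat(sprintf("  %s: r = %.4f\n", x$pc_correlation$component[i],
                x$pc_correlation$r[i]))
  for (i in seq_len(nrow(x$diversity_ranks)))
    cat(sprintf("  %s ranks: rho = %.3f, ordering %s\n",
                x$diversity_ranks$statistic[i],
                x$diversity_ranks$spearman_rho[i],
                if (x$diversity_ranks$ordering_match[i]) "identical" else "differs"))
  if (!is.null(x$region_overlap))
    cat(sprintf("  candidate regions: Jaccard = %.3f (%d vs %d regions)\n",
                x$region_overlap$jaccard, x$region_overlap$n_regions_a,
                x$region_overlap$n_regions_b))
  if (!is.null(x$ancestry_rmse))
    cat(sprintf("  ancestry Q RMSE (best permutation) = %.4f\n",
                x$ancestry_rmse))
  invisible(x)
}

#' Serialize a concordance report as JSON
#' @param rep a `concordance_report`.
#' @param path destination path.
#' @export
write_concordance <- function(rep, path) {
  jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
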