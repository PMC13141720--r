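#' Genotype PCA with Patterson scaling
#'
#' Missing dosages are mean-imputed per site; each site is centered by twice
#' its mean allele frequency and scaled by sqrt(p(1-p)) (the drift-variance
#' normalization standard for genotype PCA). Sites fixed after imputation
#' (p in {0, 1}) are dropped. Scores are the leading left singular vectors
#' scaled by the singular values; eigenvalues are those of the sample
#' covariance of the scaled matrix. The sign of each component is fixed by
#' making its largest-magnitude site loading positive, so results are
#' reproducible up to machine precision.
#'
#' @param gt a `genotype_table`.
#' @param n_components number of components to return (default 10).
#' @return list of class `pca_result`: `scores` (samples x components, row
#'   names = sample ids), `eigenvalues`, `site_means`, `site_scales`,
#'   `sites_used` (indices into the input variants).
#' @export
pca <- function(gt, n_components = 10L) {
  d <- gt$dosages
  if (nrow(d) < 2 || ncol(d) < 2) stop("pca needs >= 2 samples and >= 2 sites")
  mu <- colMeans(d, na.rm = TRUE)
  x <- d
  na_idx <- which(is.na(x))
  if (length(na_idx)) x[na_idx] <- mu[((na_idx - 1) %/% nrow(x)) + 1]
  p_hat <- mu / 2
  keep <- is.finite(p_hat) & p_hat > 0 & p_hat < 1
  if (sum(keep) < n_components)
    stop("fewer informative sites (", sum(keep), ") than components (",
         n_components, ")")
  x <- x[, keep, drop = FALSE]
  sc <- sqrt(p_hat[keep] * (1 - p_hat[keep]))
  x <- sweep(sweep(x, 2, 2 * p_hat[keep]), 2, sc, "/")
  k <- min(n_components, nrow(x) - 1L)
  sv <- svd(x, nu = k, nv = k)
  # sign convention: largest-|loading| positive per component
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)] * flip, nrow = k)
  dimnames(scores) <- list(gt$samples$sample_id, paste0("PC", seq_len(k)))
  structure(list(scores = scores,
                 eigenvalues = sv$d[seq_len(k)]^2 / (nrow(x) - 1),
                 site_means = 2 * p_hat[keep],
                 site_scales = sc,
                 sites_used = which(keep)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", ncol(x$scores),
      "components\n")
  pve <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat("variance explained (of returned components):",
      paste(sprintf("PC%d %.1f%%", seq_along(pve), pve), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write PCA scores and eigenvalues as tab-separated tables
#' @param p a `pca_result`.
#' @param scores_path,eigen_path destination paths.
#' @export
write_pca <- function(p, scores_path, eigen_path) {
  utils::write.table(data.frame(sample_id = rownames(p$scores), p$scores),
                     scores_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(component = seq_along(p$eigenvalues),
                                eigenvalue = p$eigenvalues),
                     eigen_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(scores_path)
}
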