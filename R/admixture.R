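#' Maximum-likelihood admixture model via EM
#'
#' Models each individual's genome as proportions Q over K ancestral
#' populations with allele frequencies P, genotypes binomial in f = QP.
#' The binomial log-likelihood
#' \deqn{L = \sum_{ij} [ g_{ij} \log f_{ij} + (2 - g_{ij}) \log(1 - f_{ij}) ]}
#' is maximized by the classical EM on per-allele ancestry assignments
#' (simultaneous closed-form M-step for Q and P), which increases the
#' likelihood monotonically. Missing genotype entries are excluded from the
#' likelihood. P is kept in [eps, 1 - eps] with eps = 1e-6; Q rows remain on
#' the simplex by construction.
#'
#' This is a plain monotone EM optimizer, not the quasi-Newton block
#' relaxation of the ADMIXTURE program; it is adequate at the scales this
#' package targets and its monotonicity is tested.
#'
#' @param gt a `genotype_table` or a samples x sites dosage matrix.
#' @param K number of ancestral components (1 <= K <= number of samples).
#' @param seed integer seed for the uniform random initialization.
#' @param max_iter iteration cap (default 2000).
#' @param tol stop when the log-likelihood gain drops below this (default
#'   1e-4).
#' @return list of class `ancestry_model`: `K`, `Q` (samples x K), `P`
#'   (K x sites), `loglik`, `loglik_trace`, `n_iter`, `converged`.
#' @export
admixture_fit <- function(gt, K, seed = 1L, max_iter = 2000L, tol = 1e-4) {
  g <- if (inherits(gt, "genotype_table")) gt$dosages else as.matrix(gt)
  n <- nrow(g); m <- ncol(g)
  if (K < 1 || K > n) stop("K must be between 1 and the number of samples")
  eps <- 1e-6
  w <- !is.na(g)
  g0 <- g; g0[!w] <- 0L
  storage.mode(g0) <- "double"
  w <- w * 1

  set.seed(derive_seed(seed, paste0("admixture-K", K)))
  q <- matrix(stats::runif(n * K, 0.1, 1), n, K)
  q <- q / rowSums(q)
  p <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)

  g2 <- (2 - g0) * w
  g1 <- g0 * w
  ll_trace <- numeric(max_iter)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    f <- q %*% p
    ll <- sum(g1 * log(f)) + sum(g2 * log1p(-f))  # at the current (q, p)
    ll_trace[it] <- ll
    if (is.finite(ll_old) && (ll - ll_old) < tol) {
      converged <- TRUE
      break   # q, p are the parameters that achieved ll
    }
    ll_old <- ll
    ag <- g1 / f          # zero where masked (g1, g2 already masked)
    bg <- g2 / (1 - f)
    # E-step posteriors folded into the closed-form simultaneous M-step
    qn <- q * (ag %*% t(p)) + q * (bg %*% t(1 - p))
    q <- qn / rowSums(qn)
    n1 <- crossprod(ag, q)            # m x K
    n2 <- crossprod(bg, q)
    num <- t(n1) * p
    den <- num + t(n2) * (1 - p)
    p_new <- num / den
    bad <- !(den > 0)                 # site unobserved: keep previous value
    if (any(bad)) p_new[bad] <- p[bad]
    p <- pmin(pmax(p_new, eps), 1 - eps)
  }
  ll_trace <- ll_trace[seq_len(it)]
  if (!converged) {   # max_iter exit: report the likelihood of the final state
    f <- q %*% p
    ll_trace[it] <- sum(g1 * log(f)) + sum(g2 * log1p(-f))
  }
  rownames(q) <- if (inherits(gt, "genotype_table")) gt$samples$sample_id
                 else rownames(g)
  structure(list(K = as.integer(K), Q = q, P = p,
                 loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace,
                 n_iter = it, converged = converged),
            class = "ancestry_model")
}

#' @export
print.ancestry_model <- function(x, ...) {
  cat("ancestry_model: K =", x$K, ",", nrow(x$Q), "samples,",
      ncol(x$P), "sites\n")
  cat(sprintf("log-likelihood %.2f after %d iteration(s)%s\n", x$loglik,
              x$n_iter, if (x$converged) " (converged)" else ""))
  if (!is.null(x$cv_error)) cat("CV error:", x$cv_error, "\n")
  invisible(x)
}

#' Write Q and P matrices in the conventional ancestry layout
#'
#' Q: one row per sample, whitespace-delimited proportions. P is written as
#' K rows of per-site frequencies.
#'
#' @param model an `ancestry_model`.
#' @param q_path,p_path destination paths (either may be `NULL` to skip).
#' @export
write_ancestry <- function(model, q_path, p_path = NULL) {
  if (!is.null(q_path))
    utils::write.table(format(model$Q, digits = 6), q_path, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  if (!is.null(p_path))
    utils::write.table(format(model$P, digits = 6), p_path, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(q_path)
}

#' Cross-validation error over K by genotype-entry masking
#'
#' Non-missing genotype entries are partitioned into `n_folds` masks
#' (seeded). For each fold the masked entries are held out, the admixture
#' model is fit on the rest, and the held-out entries are predicted as
#' 2 f_ij; the fold error is the root-mean-square deviation between held-out
#' dosages and predictions. The CV error per K is the mean over folds and
#' the K with the smallest error is reported as `best_k`. Partitions that
#' would mask every entry of some sample or site are redrawn (bounded
#' retries).
#'
#' @param gt a `genotype_table` or dosage matrix.
#' @param K_values candidate component counts (default 1:6).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed governing fold assignment and fits.
#' @param max_iter per-fit iteration cap (default 300; model selection needs
#'   relative fold errors, not fully polished fits).
#' @param tol per-fit convergence tolerance.
#' @return list of class `cv_result`: `table` (data.frame K, cv_error),
#'   `best_k`, `fold_errors` (K x fold matrix).
#' @export
cv_error <- function(gt, K_values = 1:6, n_folds = 5L, seed = 1L,
                     max_iter = 300L, tol = 1e-4) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  g <- if (inherits(gt, "genotype_table")) gt$dosages else as.matrix(gt)
  obs <- which(!is.na(g))
  set.seed(derive_seed(seed, "cv-folds"))
  folds <- NULL
  for (attempt in 1:20) {
    cand <- sample(rep(seq_len(n_folds), length.out = length(obs)))
    ok <- TRUE
    for (f in seq_len(n_folds)) {
      gm <- g
      gm[obs[cand == f]] <- NA
      if (any(rowSums(!is.na(gm)) == 0) || any(colSums(!is.na(gm)) == 0)) {
        ok <- FALSE
        break
      }
    }
    if (ok) { folds <- cand; break }
  }
  if (is.null(folds))
    stop("could not draw a fold partition keeping every sample and site observed")

  fold_err <- matrix(NA_real_, length(K_values), n_folds,
                     dimnames = list(paste0("K", K_values), NULL))
  for (ki in seq_along(K_values)) {
    K <- K_values[ki]
    for (f in seq_len(n_folds)) {
      held <- obs[folds == f]
      gm <- g
      gm[held] <- NA
      fit <- admixture_fit(gm, K, seed = derive_seed(seed, paste0("cv", K, "-", f)),
                           max_iter = max_iter, tol = tol)
      pred <- 2 * (fit$Q %*% fit$P)
      fold_err[ki, f] <- sqrt(mean((g[held] - pred[held])^2))
    }
  }
  cv <- rowMeans(fold_err)
  tab <- data.frame(K = K_values, cv_error = unname(cv))
  structure(list(table = tab,
                 best_k = K_values[which.min(cv)],
                 fold_errors = fold_err),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("lowest CV error at K =", x$best_k, "\n")
  invisible(x)
}
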