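#' Allele-sharing distance matrix
#'
#' d(i, j) = mean over pairwise-complete sites of |g_i - g_j| / 2: 0 for
#' identical genotypes, 1 for opposite homozygotes at every shared site.
#'
#' @param gt a `genotype_table`.
#' @return square symmetric matrix with sample ids as dimnames.
#' @export
distance_matrix <- function(gt) {
  dist_from_dosages(gt$dosages)
}

# Cross-product decomposition of the Manhattan distance over dosage classes:
# sum|g_i - g_j| = N01 + N10 + N12 + N21 + 2(N02 + N20), with Nuv the count
# of sites where sample i carries u and j carries v.
dist_from_dosages <- function(d) {
  i0 <- (!is.na(d) & d == 0L) * 1
  i1 <- (!is.na(d) & d == 1L) * 1
  i2 <- (!is.na(d) & d == 2L) * 1
  w <- i0 + i1 + i2
  npairs <- tcrossprod(w)
  if (any(npairs[upper.tri(npairs)] == 0))
    stop("a sample pair has zero pairwise-complete sites")
  s01 <- tcrossprod(i0, i1)
  s12 <- tcrossprod(i1, i2)
  s02 <- tcrossprod(i0, i2)
  total <- s01 + t(s01) + s12 + t(s12) + 2 * (s02 + t(s02))
  dm <- total / (2 * npairs)
  dimnames(dm) <- list(rownames(d), rownames(d))
  dm
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \code{ape::nj}); negative branch lengths
#' (a known NJ artifact on noisy distances) are clamped to zero with a
#' message. The result is an unrooted tree.
#'
#' @param dist square symmetric distance matrix with dimnames.
#' @return list of class `tree_result`: `tree` (an `ape::phylo`), `support`
#'   (`NULL` until [bootstrap_support()] is run).
#' @export
nj_tree <- function(dist) {
  if (!isSymmetric(unname(dist), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (nrow(dist) < 3) stop("neighbor joining needs >= 3 leaves")
  tr <- ape::nj(dist)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message("nj_tree: clamped ", sum(neg), " negative branch length(s) to 0")
    tr$edge.length[neg] <- 0
  }
  structure(list(tree = tr, support = NULL, n_replicates = NULL),
            class = "tree_result")
}

#' @export
print.tree_result <- function(x, ...) {
  cat("tree_result:", length(x$tree$tip.label), "leaves")
  if (!is.null(x$support))
    cat(";", x$n_replicates, "bootstrap replicates, median support",
        stats::median(x$support, na.rm = TRUE))
  cat("\n")
  invisible(x)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Sites are resampled with replacement `n_replicates` times (seeded); the
#' support of each internal edge of the point-estimate tree is the percent
#' of replicate trees containing the same leaf bipartition.
#'
#' @param gt a `genotype_table`.
#' @param n_replicates bootstrap replicates (default 1000, the conventional
#'   choice for distance trees).
#' @param seed integer seed.
#' @return `tree_result` with per-internal-node `support` (0-100) attached as
#'   node labels of the tree.
#' @export
bootstrap_support <- function(gt, n_replicates = 1000L, seed = 1L) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  res <- nj_tree(distance_matrix(gt))
  set.seed(derive_seed(seed, "bootstrap"))
  counts <- ape::boot.phylo(res$tree, gt$dosages,
                            function(x) ape::nj(dist_from_dosages(x)),
                            B = n_replicates, quiet = TRUE, rooted = FALSE)
  support <- 100 * counts / n_replicates
  res$support <- support[-1]  # drop the trivial root-node entry
  res$n_replicates <- n_replicates
  res$tree$node.label <- c("", format(round(res$support, 1), trim = TRUE))
  res
}

#' Write a tree as Newick with bootstrap support as node labels
#' @param tr a `tree_result`.
#' @param path destination path.
#' @export
write_newick <- function(tr, path) {
  ape::write.tree(tr$tree, file = path)
  invisible(path)
}
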