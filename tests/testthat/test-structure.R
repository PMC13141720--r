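test_that("PCA separates two lines differing by fixed differences", {
  # individuals identical within line -> each line maps to one point on PC1
  d <- rbind(matrix(0L, 5, 30), matrix(2L, 5, 30))
  d <- cbind(d, matrix(rep(c(0L, 1L, 2L, 1L, 0L), 6), 10, 3))  # shared variation
  gt <- toy_gt(d, lines = rep(c("X", "Y"), each = 5))
  p <- pca(gt, 2)
  pc1 <- p$scores[, 1]
  expect_lt(max(abs(pc1[1:5] - pc1[1])), 1e-8)
  expect_lt(max(abs(pc1[6:10] - pc1[6])), 1e-8)
  expect_gt(abs(pc1[1] - pc1[6]), 1)
})

test_that("PCA scores are orthogonal and deterministic in sign", {
  d <- random_dosages(20, 200, missing = 0.05, seed = 14)
  gt <- toy_gt(d)
  p <- pca(gt, 5)
  cp <- crossprod(p$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_identical(p$scores, pca(gt, 5)$scores)
})

test_that("PCA matches a dense eigendecomposition of the scaled covariance", {
  d <- random_dosages(20, 200, seed = 15)
  gt <- toy_gt(d)
  p <- pca(gt, 6)
  # oracle: scale by hand, eigendecompose the sample covariance of samples
  mu <- colMeans(d)
  ph <- mu / 2
  keep <- ph > 0 & ph < 1
  x <- sweep(sweep(d[, keep], 2, mu), 2, sqrt(ph[keep] * (1 - ph[keep])), "/")
  ev <- eigen(tcrossprod(x) / (ncol(x) - 1) * (ncol(x) - 1), symmetric = TRUE)
  # eigen of X X^T: eigenvalues d^2, eigenvectors U
  for (j in 1:6) {
    sc_oracle <- ev$vectors[, j] * sqrt(ev$values[j])
    expect_equal(abs(stats::cor(p$scores[, j], sc_oracle)), 1, tolerance = 1e-8)
    expect_equal(sd(p$scores[, j]), sd(sc_oracle), tolerance = 1e-8)
  }
  expect_equal(p$eigenvalues, ev$values[1:6] / (nrow(d) - 1), tolerance = 1e-8)
})

test_that("PCA tolerates missing entries and rejects uninformative input", {
  d <- random_dosages(15, 100, missing = 0.1, seed = 16)
  p <- pca(toy_gt(d), 2)
  expect_equal(nrow(p$scores), 15)
  expect_true(all(is.finite(p$scores)))
  expect_error(pca(toy_gt(matrix(0L, 5, 4)), 2), "informative sites")
})

test_that("allele-sharing distances match direct tallies", {
  d <- rbind(c(0L, 0L, 2L, 1L),
             c(0L, 0L, 2L, 1L),
             c(2L, 2L, 0L, NA),
             c(1L, 0L, 2L, 2L))
  gt <- toy_gt(d)
  dm <- distance_matrix(gt)
  expect_equal(dm["s01", "s02"], 0)
  expect_equal(dm["s01", "s03"], 1)          # opposite homozygotes, 3 shared sites
  expect_equal(dm["s01", "s04"], mean(c(1, 0, 0, 1) / 2))
  expect_equal(dm["s03", "s04"], mean(c(1 / 2, 1, 1)))
  expect_true(isSymmetric(dm))
  expect_equal(diag(dm), setNames(rep(0, 4), rownames(d) %||% paste0("s0", 1:4)))
})

test_that("NJ recovers the additive four-leaf tree exactly", {
  dm <- matrix(0, 4, 4, dimnames = list(c("w", "x", "y", "z"),
                                        c("w", "x", "y", "z")))
  dm["w", "x"] <- 3; dm["w", "y"] <- 5; dm["w", "z"] <- 6
  dm["x", "y"] <- 6; dm["x", "z"] <- 7; dm["y", "z"] <- 7
  dm <- dm + t(dm)
  tr <- nj_tree(dm)$tree
  # topology: (w,x) | (y,z); NJ is exact on additive matrices
  coph <- ape::cophenetic.phylo(tr)
  expect_equal(coph[rownames(dm), colnames(dm)], dm, tolerance = 1e-12)
  tip_len <- tr$edge.length[match(1:4, tr$edge[, 2])]
  names(tip_len) <- tr$tip.label
  expect_equal(tip_len[c("w", "x", "y", "z")],
               c(w = 1, x = 2, y = 3, z = 4))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(sum(internal), 1)
})

test_that("three equidistant leaves give a star with branches d/2", {
  dm <- matrix(4, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(dm) <- 0
  tr <- nj_tree(dm)$tree
  expect_equal(unname(tr$edge.length), rep(2, 3))
})

test_that("NJ topology is invariant to leaf order and exact on random additive trees", {
  set.seed(44)
  for (i in 1:8) {
    n <- sample(4:8, 1)
    true_tree <- ape::rtree(n, rooted = FALSE)
    true_tree$edge.length <- runif(length(true_tree$edge.length), 0.5, 2)
    dm <- ape::cophenetic.phylo(true_tree)
    rec <- nj_tree(dm)$tree
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true_tree),
                                           ape::unroot(rec))), 0)
    perm <- sample(n)
    rec2 <- nj_tree(dm[perm, perm])$tree
    expect_equal(as.numeric(ape::dist.topo(rec, rec2)), 0)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|leaves")
})

test_that("bootstrap support is high for a clear line split and reproducible", {
  cfg <- simulation_config(
    n_markers = 400, chromosome_lengths = c("1" = 1e6),
    line_specs = data.frame(label = c("X", "Y"), n_samples = 8L, f = 0.3,
                            stringsAsFactors = FALSE),
    seed = 61
  )
  gt <- simulate_populations(cfg)$gt
  res <- bootstrap_support(gt, n_replicates = 100, seed = 9)
  # locate the internal edge splitting the two lines
  pp <- ape::prop.part(res$tree)
  x_ids <- which(res$tree$tip.label %in%
                   gt$samples$sample_id[gt$samples$line == "X"])
  split_idx <- which(vapply(pp, function(s)
    setequal(s, x_ids) || setequal(s, setdiff(seq_len(16), x_ids)), TRUE))
  split_idx <- split_idx[split_idx > 1]  # skip the trivial all-tips partition
  expect_length(split_idx, 1L)
  expect_gte(res$support[split_idx - 1], 95)
  res2 <- bootstrap_support(gt, n_replicates = 100, seed = 9)
  expect_identical(res$support, res2$support)
})

test_that("admixture at K=1 reaches the pooled-frequency closed form", {
  d <- random_dosages(12, 80, missing = 0.05, seed = 18)
  gt <- toy_gt(d)
  fit <- admixture_fit(gt, 1, seed = 1)
  expect_true(all(fit$Q == 1))
  p_pool <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  eps <- 1e-6
  p_pool <- pmin(pmax(p_pool, eps), 1 - eps)
  ll_closed <- sum(d * log(rep(p_pool, each = 12)) +
                     (2 - d) * log(1 - rep(p_pool, each = 12)), na.rm = TRUE)
  expect_equal(fit$loglik, ll_closed, tolerance = 1e-8)
})

test_that("admixture EM log-likelihood is monotone non-decreasing", {
  for (seed in c(2, 7)) {
    d <- random_dosages(25, 150, missing = 0.1, seed = seed)
    fit <- admixture_fit(d, 3, seed = seed, max_iter = 150)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
  expect_error(admixture_fit(random_dosages(4, 10), 5), "between 1 and")
})

test_that("admixture recovers unadmixed two-population labels", {
  # at 2,000 sites and F = 0.1 the MLE of q has sampling s.e. ~ 0.035 per
  # individual, so the assertions here are on the assignment and the average
  # deviation; the tighter 0.05 max-deviation bound is asserted at an
  # information-sufficient marker count in the acceptance suite
  cfg <- simulation_config(
    n_markers = 2000, chromosome_lengths = c("1" = 1e7),
    line_specs = data.frame(label = c("X", "Y"), n_samples = 30L, f = 0.1,
                            stringsAsFactors = FALSE),
    seed = 71
  )
  gt <- simulate_populations(cfg)$gt
  fit <- admixture_fit(gt, 2, seed = 4)
  truth <- cbind(as.integer(gt$samples$line == "X"),
                 as.integer(gt$samples$line == "Y"))
  agree <- q_matrix_agreement(truth, fit$Q)
  qm <- fit$Q[, agree$permutation]
  expect_lt(mean(abs(qm - truth)), 0.02)
  expect_lt(max(abs(qm - truth)), 0.15)
  # every individual is dominated by its own line's component
  expect_true(all(apply(qm, 1, which.max) == apply(truth, 1, which.max)))
})

test_that("cross-validation error is reproducible and penalizes overfitting", {
  d <- random_dosages(30, 300, p = 0.35, missing = 0.02, seed = 26)  # one population
  cv1 <- cv_error(d, K_values = c(1, 3), n_folds = 4, seed = 6, max_iter = 150)
  cv2 <- cv_error(d, K_values = c(1, 3), n_folds = 4, seed = 6, max_iter = 150)
  expect_identical(cv1$table, cv2$table)
  expect_lte(cv1$table$cv_error[cv1$table$K == 1],
             cv1$table$cv_error[cv1$table$K == 3])
})

test_that("PCA scores are invariant to sample permutation up to sign", {
  d <- random_dosages(18, 120, missing = 0.05, seed = 27)
  gt <- toy_gt(d)
  p0 <- pca(gt, 4)
  perm <- sample(18)
  p1 <- pca(gt_subset(gt, samples = perm), 4)
  for (j in 1:4) {
    a <- p0$scores[rownames(p1$scores), j]
    expect_equal(abs(stats::cor(a, p1$scores[, j])), 1, tolerance = 1e-8)
    expect_equal(abs(a), abs(p1$scores[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_equal(p0$eigenvalues, p1$eigenvalues, tolerance = 1e-10)
})
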