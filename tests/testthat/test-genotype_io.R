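test_that("read_vcf decodes GT fields into dosages", {
  body <- c(
    "1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\t.\tG\tT\t.\tPASS\t.\tGT\t0|1\t./.\t1|1"
  )
  path <- write_vcf_text(body, c("s1", "s2", "s3"))
  gt <- read_vcf(path, toy_pop_map(c("s1", "s2", "s3"), c("A", "A", "B")))
  expect_equal(unname(gt$dosages[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(gt$dosages[, 2]), c(1L, NA, 2L))
  expect_equal(mean(is.na(gt$dosages[, 2])), 1 / 3)
  expect_equal(gt$samples$line, c("A", "A", "B"))
  expect_equal(attr(gt, "dropped_records"), 0L)
})

test_that("read_vcf drops multi-allelic and non-SNP records with a count", {
  body <- c(
    "1\t100\t.\tA\tC,T\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\t.\tAT\tA\t.\tPASS\t.\tGT\t0/0\t1/1",
    "1\t300\t.\tG\tT\t.\tPASS\t.\tGT\t1/1\t0/0"
  )
  path <- write_vcf_text(body, c("s1", "s2"))
  gt <- suppressMessages(
    read_vcf(path, toy_pop_map(c("s1", "s2"), c("A", "B")))
  )
  expect_equal(ncol(gt$dosages), 1L)
  expect_equal(gt$variants$pos, 300L)
  expect_equal(attr(gt, "dropped_records"), 2L)
})

test_that("read_vcf errors on unmapped samples, malformed GT, missing file", {
  body <- "1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1"
  path <- write_vcf_text(body, c("s1", "s2"))
  expect_error(read_vcf(path, toy_pop_map("s1", "A")), "absent from population map")
  expect_error(read_vcf(tempfile(), toy_pop_map("s1", "A")), "not found")
  body_bad <- "1\t500\t.\tA\tC\t.\tPASS\t.\tGT\t0/2\t0/1"
  path_bad <- write_vcf_text(body_bad, c("s1", "s2"))
  expect_error(read_vcf(path_bad, toy_pop_map(c("s1", "s2"), c("A", "B"))),
               "malformed GT.*1:500")
})

test_that("write_vcf and read_vcf round-trip, including missing entries", {
  d <- random_dosages(6, 40, missing = 0.1, seed = 3)
  gt <- toy_gt(d, lines = rep(c("A", "B"), each = 3))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gt, path)
  txt <- readLines(path)
  expect_true(any(grepl("\\./\\.", txt)))  # missing written as ./.
  back <- read_vcf(path, gt$samples)
  expect_equal(back$dosages, gt$dosages)
  expect_equal(back$variants[c("chrom", "pos", "ref", "alt")],
               gt$variants[c("chrom", "pos", "ref", "alt")])
})

test_that("write_vcf with no variants produces a header-only file", {
  gt <- toy_gt(matrix(0L, 2, 1))
  empty <- gt_subset(gt, sites = integer(0))
  path <- tempfile(fileext = ".vcf")
  write_vcf(empty, path)
  expect_true(all(startsWith(readLines(path), "#")))
})

test_that("apply_qc removes sites then samples at strict thresholds", {
  # 100 samples; site 1 has 2 missing genotypes (2% > 1%) -> removed;
  # boundary site with exactly 1% missing is retained
  d <- matrix(rep(c(0L, 1L), 50), nrow = 100, ncol = 5)
  d[1:2, 1] <- NA
  d[1, 2] <- NA
  gt <- toy_gt(d, lines = rep("A", 100))
  out <- apply_qc(gt, qc_config())
  expect_equal(ncol(out$dosages), 4L)
  expect_equal(out$variants$pos[1], 200L)
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_sites_high_missing, 1L)

  # sample missing 6% of genotypes with threshold 5% -> removed
  d3 <- matrix(1L, nrow = 200, ncol = 50)
  d3[1, 1:3] <- NA  # sample 1: 6%; per-site missing 0.5% <= 1% so sites survive
  gt3 <- toy_gt(d3, lines = rep("A", 200))
  out3 <- apply_qc(gt3, qc_config())
  expect_equal(nrow(out3$dosages), 199L)
  expect_false("s01" %in% out3$samples$sample_id)
})

test_that("apply_qc matches a brute-force recount and is idempotent", {
  set.seed(7)
  d <- random_dosages(40, 10, missing = 0.03, seed = 7)
  gt <- toy_gt(d, lines = rep(c("A", "B"), 20))
  cfg <- qc_config(max_site_missing = 0.05, max_sample_missing = 0.08)
  out <- apply_qc(gt, cfg)

  # independent recount: per-site then per-sample missing rates
  keep_site <- sapply(seq_len(ncol(d)), function(j) mean(is.na(d[, j])) <= 0.05)
  d_site <- d[, keep_site, drop = FALSE]
  keep_sample <- sapply(seq_len(nrow(d_site)),
                        function(i) mean(is.na(d_site[i, ])) <= 0.08)
  expect_equal(out$variants$pos, gt$variants$pos[keep_site])
  expect_equal(out$samples$sample_id, gt$samples$sample_id[keep_sample])

  twice <- apply_qc(out, cfg)
  expect_equal(twice$dosages, out$dosages)
})

test_that("apply_qc drops non-autosomal sites when configured", {
  d <- random_dosages(10, 6, seed = 1)
  gt <- toy_gt(d, chrom = c("1", "1", "Z", "2", "W", "scaffold_12"),
               pos = c(100L, 200L, 100L, 100L, 100L, 100L))
  out <- apply_qc(gt, qc_config())
  expect_setequal(unique(out$variants$chrom), c("1", "2"))
  expect_equal(attr(out, "filter_report")$n_sites_non_autosomal, 3L)
  keep_all <- apply_qc(gt, qc_config(autosomes_only = FALSE))
  expect_equal(ncol(keep_all$dosages), 6L)
})

# literal transcription of the windowed greedy rule, no shortcuts: the
# independent oracle for ld_prune
slow_prune <- function(d, window, step, r2_max) {
  m <- ncol(d)
  keep <- rep(TRUE, m)
  if (m < 2L || window < 2L) return(keep)
  repeat {
    removed <- FALSE
    alive <- which(keep)
    if (length(alive) < 2L) break
    start <- 1L
    while (start <= length(alive)) {
      win <- alive[start:min(start + window - 1L, length(alive))]
      win <- win[keep[win]]
      if (length(win) >= 2L) {
        r <- suppressWarnings(stats::cor(d[, win, drop = FALSE],
                                         use = "pairwise.complete.obs"))
        r[!is.finite(r)] <- 0
        r2 <- r * r
        diag(r2) <- 0
        nw <- length(win)
        for (a in seq_len(nw - 1L)) {
          if (!keep[win[a]]) next
          for (b in (a + 1L):nw) {
            if (!keep[win[b]]) next
            if (r2[a, b] > r2_max) {
              keep[win[b]] <- FALSE
              removed <- TRUE
            }
          }
        }
      }
      start <- start + step
    }
    if (!removed) break
  }
  keep
}

test_that("ld_prune keeps the earlier of a perfectly correlated pair", {
  set.seed(5)
  base <- rbinom(30, 2, 0.5)
  d <- cbind(base, base, rbinom(30, 2, 0.5))
  gt <- toy_gt(d)
  out <- ld_prune(gt, qc_config(ld_window_snps = 10, ld_step_snps = 2))
  expect_equal(ncol(out$dosages), 2L)
  expect_equal(out$variants$pos[1], 100L)  # earlier duplicate kept
})

test_that("ld_prune retains everything when all pairs are below threshold", {
  set.seed(9)
  d <- matrix(rbinom(60 * 12, 2, 0.5), 60, 12)
  r2 <- suppressWarnings(cor(d))^2
  diag(r2) <- 0
  skip_if(max(r2) > 0.2, "draw produced correlated columns")
  gt <- toy_gt(d)
  out <- ld_prune(gt, qc_config())
  expect_equal(ncol(out$dosages), 12L)
})

test_that("ld_prune equals the exhaustive windowed oracle on toy chromosomes", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 25
    d <- matrix(rbinom(n * 20, 2, 0.4), n, 20)
    for (k in sample(19, 6))  # inject LD
      d[, k + 1] <- ifelse(runif(n) < 0.85, d[, k], rbinom(n, 2, 0.4))
    d[runif(n * 20) < 0.04] <- NA
    gt <- toy_gt(d)
    cfg <- qc_config(ld_window_snps = 5, ld_step_snps = 2)
    out <- ld_prune(gt, cfg)
    keep_oracle <- slow_prune(d, 5L, 2L, 0.2)
    expect_equal(out$variants$pos, gt$variants$pos[keep_oracle],
                 info = paste("seed", seed))
    # subset property and first site always retained
    expect_true(all(out$variants$pos %in% gt$variants$pos))
    expect_equal(out$variants$pos[1], gt$variants$pos[1])
  }
})

test_that("ld_prune is a no-op for windows smaller than 2", {
  d <- random_dosages(10, 5, seed = 2)
  gt <- toy_gt(d)
  out <- ld_prune(gt, qc_config(ld_window_snps = 1, ld_step_snps = 1))
  expect_equal(ncol(out$dosages), 5L)
})
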