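# Hudson-style FST (ratio of averages) as an independent check of the
# simulator's divergence calibration; used only as an oracle here.
hudson_fst <- function(gt, line_a, line_b) {
  sa <- allele_stats(gt, line_a)
  sb <- allele_stats(gt, line_b)
  ok <- sa$called >= 4 & sb$called >= 4
  p1 <- sa$freq[ok]; p2 <- sb$freq[ok]
  n1 <- sa$called[ok]; n2 <- sb$called[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

two_line_cfg <- function(f, shared = FALSE, n_markers = 20000, seed = 21) {
  simulation_config(
    n_markers = n_markers,
    chromosome_lengths = c("1" = 5e7),
    line_specs = data.frame(label = c("X", "Y"), n_samples = 30L, f = f,
                            stringsAsFactors = FALSE),
    shared_ancestry = if (shared) list(c("X", "Y")) else NULL,
    seed = seed
  )
}

test_that("lines sharing one frequency vector are undifferentiated", {
  sim <- simulate_populations(two_line_cfg(0.1, shared = TRUE))
  expect_lt(abs(hudson_fst(sim$gt, "X", "Y")), 0.01)
  expect_equal(sim$truth$line_freq["X", ], sim$truth$line_freq["Y", ])
})

test_that("independent lines with drift F show pairwise F_ST near F", {
  sim <- simulate_populations(two_line_cfg(0.05))
  fst <- windowed_fst(sim$gt, "X", "Y", window_bp = 5e7, step_bp = 5e7)$fst
  expect_lt(abs(fst - 0.05), 0.015)
})

test_that("expected pairwise F_ST increases with the drift parameter", {
  fsts <- sapply(c(0.01, 0.05, 0.1), function(f) {
    sim <- simulate_populations(two_line_cfg(f, n_markers = 10000, seed = 31))
    windowed_fst(sim$gt, "X", "Y", window_bp = 5e7, step_bp = 5e7)$fst
  })
  expect_true(all(diff(fsts) > 0))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_populations(two_line_cfg(0.05, n_markers = 2000))
  b <- simulate_populations(two_line_cfg(0.05, n_markers = 2000))
  expect_identical(a$gt$dosages, b$gt$dosages)
  expect_identical(a$gt$variants, b$gt$variants)
  s1 <- paper_like_scenario(seed = 5, n_markers = 3000, n_chip = 300)
  s2 <- paper_like_scenario(seed = 5, n_markers = 3000, n_chip = 300)
  expect_identical(s1$wgs$dosages, s2$wgs$dosages)
  expect_identical(s1$chip$variants, s2$chip$variants)
})

test_that("drift parameters outside (0,1) are rejected", {
  expect_error(two_line_cfg(1), "f > 0")
  expect_error(two_line_cfg(0), "f > 0")
})

test_that("selection spikes shift the focal line's frequencies toward fixation", {
  spikes <- data.frame(line = "X", chrom = "1", start = 1e6, end = 3e6,
                       magnitude = 0.8, stringsAsFactors = FALSE)
  mk_cfg <- function(sp) simulation_config(
    n_markers = 5000, chromosome_lengths = c("1" = 5e7),
    line_specs = data.frame(label = c("X", "Y"), n_samples = 20L, f = 0.05,
                            stringsAsFactors = FALSE),
    selection_spikes = sp, seed = 13
  )
  sim <- simulate_populations(mk_cfg(spikes))
  base <- simulate_populations(mk_cfg(NULL))
  in_iv <- sim$truth$pos >= 1e6 & sim$truth$pos <= 3e6
  fx <- sim$truth$line_freq["X", in_iv]
  fx0 <- base$truth$line_freq["X", in_iv]
  expect_true(all(pmin(fx, 1 - fx) <= pmin(fx0, 1 - fx0) + 1e-12))
  expect_equal(sim$truth$line_freq["Y", ], base$truth$line_freq["Y", ])
  expect_equal(sim$truth$line_freq["X", !in_iv], base$truth$line_freq["X", !in_iv])
})

test_that("chip ascertainment filters by pooled MAF and preserves order", {
  d <- random_dosages(20, 100, p = 0.5, seed = 17)
  # force 90 sites to be (nearly) monomorphic: MAF < 0.05
  d[, 11:100] <- 0L
  d[1, 11:100] <- 1L  # MAF = 1/40 = 0.025
  gt <- toy_gt(d)
  chip <- ascertain_chip(gt, chip_config(maf_min = 0.05, n_chip_markers = 10,
                                         seed = 1))
  expect_equal(chip$variants$pos, gt$variants$pos[1:10])
  expect_error(ascertain_chip(gt, chip_config(maf_min = 0.05,
                                              n_chip_markers = 11, seed = 1)),
               "only 10 sites")
  # identity case
  all_sites <- ascertain_chip(gt, chip_config(maf_min = 0,
                                              n_chip_markers = 100, seed = 1))
  expect_equal(all_sites$dosages, gt$dosages)
})

test_that("ascertainment raises the mean MAF of the chip panel", {
  sim <- simulate_populations(two_line_cfg(0.1, n_markers = 8000, seed = 23))
  chip <- ascertain_chip(sim$gt, chip_config(maf_min = 0.05,
                                             n_chip_markers = 1000, seed = 23))
  maf_of <- function(gt) {
    p <- colMeans(gt$dosages, na.rm = TRUE) / 2
    mean(pmin(p, 1 - p))
  }
  expect_gte(maf_of(chip), maf_of(sim$gt))
})

test_that("simulated tables round-trip through the VCF writer and reader", {
  sim <- simulate_populations(
    simulation_config(n_markers = 300, chromosome_lengths = c("1" = 1e6, "2" = 1e6),
                      line_specs = data.frame(label = "X", n_samples = 8L, f = 0.05,
                                              stringsAsFactors = FALSE),
                      missing_rate = 0.05, seed = 3)
  )
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$gt, path)
  back <- read_vcf(path, sim$gt$samples)
  expect_equal(back$dosages, sim$gt$dosages)
  expect_equal(back$variants[c("chrom", "pos", "ref", "alt")],
               sim$gt$variants[c("chrom", "pos", "ref", "alt")])
})

test_that("the default four-line scenario has the configured diversity ordering", {
  scen <- paper_like_scenario(seed = 2, n_markers = 8000, n_chip = 800)
  for (panel in list(scen$wgs, scen$chip)) {
    he <- heterozygosity_summary(panel)
    expect_gt(he$he[he$line == "D"], he$he[he$line == "C"])
  }
})
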