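#' Simulation configuration for structured breeding lines
#'
#' Genotypes are generated under the Balding-Nichols model: each marker has
#' an ancestral frequency drawn Uniform(0.05, 0.95); each population unit
#' draws its frequency from Beta(p(1-F)/F, (1-p)(1-F)/F), so the drift
#' parameter F equals the expected F_ST of that unit against its parent
#' frequency vector. Two-level hierarchies (breed pools above lines) are
#' expressed through `parent_pools`; lines listed together in
#' `shared_ancestry` reuse a single frequency draw, emulating undifferentiated
#' sister lines.
#'
#' @param n_markers number of biallelic markers.
#' @param chromosome_lengths named numeric vector, bp per chromosome.
#' @param line_specs data.frame with columns `label`, `n_samples`, `f`
#'   (drift, in (0,1)) and optionally `parent` (a `parent_pools` name or
#'   `"ancestral"`).
#' @param parent_pools optional data.frame with columns `name`, `f`:
#'   intermediate frequency vectors drawn from the ancestral vector.
#' @param shared_ancestry optional list of character vectors; lines in one
#'   group share a single frequency draw (the group's first line defines the
#'   drift used).
#' @param admixture_rows optional matrix of per-sample ancestry proportions
#'   (rows sum to 1, columns named by line labels); each such sample draws
#'   each of its two allele copies from a line chosen by its proportions.
#' @param admixture_line label assigned to admixed samples.
#' @param selection_spikes optional data.frame with columns `line`, `chrom`,
#'   `start`, `end`, `magnitude`: within the interval, the focal line's
#'   frequencies are shifted deterministically toward the nearer fixation
#'   point by the given fraction of the remaining distance.
#' @param missing_rate fraction of genotype entries set missing uniformly.
#' @param seed integer seed; all draws are sub-seeded from it by named
#'   streams, so stages regenerate independently.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_markers,
                              chromosome_lengths,
                              line_specs,
                              parent_pools = NULL,
                              shared_ancestry = NULL,
                              admixture_rows = NULL,
                              admixture_line = "ADM",
                              selection_spikes = NULL,
                              missing_rate = 0,
                              seed = 1L) {
  line_specs <- as.data.frame(line_specs, stringsAsFactors = FALSE)
  if (is.null(line_specs$parent)) line_specs$parent <- "ancestral"
  stopifnot(all(c("label", "n_samples", "f") %in% names(line_specs)),
            all(line_specs$f > 0 & line_specs$f < 1),
            missing_rate >= 0, missing_rate < 1,
            !is.null(names(chromosome_lengths)))
  if (!is.null(parent_pools)) {
    parent_pools <- as.data.frame(parent_pools, stringsAsFactors = FALSE)
    stopifnot(all(parent_pools$f > 0 & parent_pools$f < 1))
  }
  if (!is.null(admixture_rows)) {
    admixture_rows <- as.matrix(admixture_rows)
    stopifnot(!is.null(colnames(admixture_rows)),
              all(colnames(admixture_rows) %in% line_specs$label),
              all(abs(rowSums(admixture_rows) - 1) < 1e-8))
  }
  if (!is.null(selection_spikes)) {
    selection_spikes <- as.data.frame(selection_spikes, stringsAsFactors = FALSE)
    stopifnot(all(c("line", "chrom", "start", "end", "magnitude") %in%
                    names(selection_spikes)),
              all(selection_spikes$magnitude >= 0 & selection_spikes$magnitude <= 1),
              all(selection_spikes$end <=
                    chromosome_lengths[as.character(selection_spikes$chrom)]))
  }
  structure(list(n_markers = as.integer(n_markers),
                 chromosome_lengths = chromosome_lengths,
                 line_specs = line_specs,
                 parent_pools = parent_pools,
                 shared_ancestry = shared_ancestry,
                 admixture_rows = admixture_rows,
                 admixture_line = admixture_line,
                 selection_spikes = selection_spikes,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# One Balding-Nichols draw of a frequency vector around parent p with drift f.
bn_draw <- function(p, f) {
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  bad <- which(!is.finite(a) | !is.finite(b) | a <= 0 | b <= 0)
  if (length(bad))
    stop("invalid Beta parameters (drift too close to 0 or 1) at marker ",
         bad[1])
  stats::rbeta(length(p), a, b)
}

#' Simulate genotypes for structured lines
#'
#' @param cfg a [simulation_config()].
#' @return list with `gt` (a [genotype_table()]) and `truth` (ancestral and
#'   per-line frequency vectors, spike intervals, admixture rows) sufficient
#'   to recompute every expected frequency.
#' @export
simulate_populations <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  m <- cfg$n_markers

  set.seed(derive_seed(cfg$seed, "positions"))
  lens <- cfg$chromosome_lengths
  n_per <- as.vector(stats::rmultinom(1, m, lens / sum(lens)))
  chrom <- rep(names(lens), n_per)
  pos <- unlist(lapply(seq_along(lens), function(i) {
    sort(sample.int(lens[i], n_per[i]))
  }), use.names = FALSE)
  ord <- order(chrom_order(chrom), pos)
  chrom <- chrom[ord]; pos <- pos[ord]

  set.seed(derive_seed(cfg$seed, "freqs"))
  p_anc <- stats::runif(m, 0.05, 0.95)

  pool_freq <- list(ancestral = p_anc)
  if (!is.null(cfg$parent_pools)) {
    for (i in seq_len(nrow(cfg$parent_pools)))
      pool_freq[[cfg$parent_pools$name[i]]] <-
        bn_draw(p_anc, cfg$parent_pools$f[i])
  }

  specs <- cfg$line_specs
  line_freq <- matrix(NA_real_, nrow = nrow(specs), ncol = m,
                      dimnames = list(specs$label, NULL))
  group_of <- setNames(specs$label, specs$label)  # default: own group
  if (!is.null(cfg$shared_ancestry)) {
    for (grp in cfg$shared_ancestry) group_of[grp] <- grp[1]
  }
  for (g in unique(group_of)) {
    spec <- specs[specs$label == g, ]
    parent <- pool_freq[[spec$parent]]
    if (is.null(parent)) stop("unknown parent pool: ", spec$parent)
    fq <- bn_draw(parent, spec$f)
    for (lab in names(group_of)[group_of == g])
      line_freq[lab, ] <- fq
  }

  # deterministic frequency shifts toward the nearer fixation point
  if (!is.null(cfg$selection_spikes)) {
    for (i in seq_len(nrow(cfg$selection_spikes))) {
      sp <- cfg$selection_spikes[i, ]
      in_iv <- chrom == as.character(sp$chrom) & pos >= sp$start & pos <= sp$end
      p <- line_freq[sp$line, in_iv]
      line_freq[sp$line, in_iv] <-
        ifelse(p >= 0.5, p + sp$magnitude * (1 - p), p * (1 - sp$magnitude))
    }
  }

  set.seed(derive_seed(cfg$seed, "genotypes"))
  blocks <- list()
  ids <- character(0)
  lines <- character(0)
  for (i in seq_len(nrow(specs))) {
    n <- specs$n_samples[i]
    f <- line_freq[specs$label[i], ]
    blocks[[i]] <- matrix(stats::rbinom(n * m, 2L, rep(f, each = n)), nrow = n)
    ids <- c(ids, sprintf("%s%03d", specs$label[i], seq_len(n)))
    lines <- c(lines, rep(specs$label[i], n))
  }
  d <- do.call(rbind, blocks)
  if (!is.null(cfg$admixture_rows)) {
    qrows <- cfg$admixture_rows
    labs <- colnames(qrows)
    adm <- matrix(0L, nrow = nrow(qrows), ncol = m)
    for (i in seq_len(nrow(qrows))) {
      k1 <- sample(labs, m, replace = TRUE, prob = qrows[i, ])
      k2 <- sample(labs, m, replace = TRUE, prob = qrows[i, ])
      a1 <- stats::rbinom(m, 1L, line_freq[cbind(k1, seq_len(m))])
      a2 <- stats::rbinom(m, 1L, line_freq[cbind(k2, seq_len(m))])
      adm[i, ] <- a1 + a2
    }
    d <- rbind(d, adm)
    ids <- c(ids, sprintf("%s%03d", cfg$admixture_line, seq_len(nrow(qrows))))
    lines <- c(lines, rep(cfg$admixture_line, nrow(qrows)))
  }

  if (cfg$missing_rate > 0) {
    set.seed(derive_seed(cfg$seed, "missing"))
    d[stats::runif(length(d)) < cfg$missing_rate] <- NA_integer_
  }

  ref_alt <- c("A", "C", "G", "T")
  set.seed(derive_seed(cfg$seed, "alleles"))
  ref <- sample(ref_alt, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(ref_alt, r), 1), "")

  gt <- genotype_table(
    d,
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
               stringsAsFactors = FALSE),
    data.frame(sample_id = ids, line = lines, stringsAsFactors = FALSE),
    chrom_lengths = lens
  )
  truth <- list(p_ancestral = p_anc,
                pool_freq = pool_freq,
                line_freq = line_freq,
                chrom = chrom, pos = pos,
                spikes = cfg$selection_spikes,
                admixture_rows = cfg$admixture_rows)
  list(gt = gt, truth = truth)
}

#' Chip ascertainment configuration
#' @param maf_min minimum pooled minor allele frequency for eligibility.
#' @param n_chip_markers number of markers to retain.
#' @param seed integer seed for the uniform thinning draw.
#' @return list of class `chip_config`.
#' @export
chip_config <- function(maf_min = 0.05, n_chip_markers, seed = 1L) {
  stopifnot(maf_min >= 0, maf_min < 0.5, n_chip_markers >= 1)
  structure(list(maf_min = maf_min,
                 n_chip_markers = as.integer(n_chip_markers),
                 seed = as.integer(seed)),
            class = "chip_config")
}

#' Derive a chip-like panel by MAF-ascertained thinning
#'
#' Restricts to sites whose pooled-sample minor allele frequency is at least
#' `maf_min`, then uniformly samples `n_chip_markers` of them without
#' replacement (seeded), preserving genomic order. The sample set is
#' unchanged, so platform differences downstream are purely ascertainment.
#'
#' @param gt a `genotype_table` (typically the dense simulated panel).
#' @param cfg a [chip_config()].
#' @return A `genotype_table` restricted to the ascertained sites.
#' @export
ascertain_chip <- function(gt, cfg) {
  stopifnot(inherits(cfg, "chip_config"))
  p <- colMeans(gt$dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  eligible <- which(!is.na(maf) & maf >= cfg$maf_min)
  if (length(eligible) < cfg$n_chip_markers)
    stop("only ", length(eligible), " sites pass MAF >= ", cfg$maf_min,
         "; cannot ascertain ", cfg$n_chip_markers)
  set.seed(derive_seed(cfg$seed, "chip"))
  idx <- sort(sample(eligible, cfg$n_chip_markers))
  gt_subset(gt, sites = idx)
}

#' Default four-line two-platform scenario
#'
#' One call producing the pipeline's default evaluation scenario: two breeds
#' of two parental lines each. Lines A (n = 20) and B (n = 34) share a single
#' breed-level frequency vector (nearly undifferentiated sister lines);
#' lines C (n = 34) and D (n = 40) drift independently from a second breed
#' pool, with weaker drift in D so that D retains the highest within-line
#' diversity and C the lowest. The dense panel is thinned to a 5,000-marker
#' chip panel at pooled MAF >= 0.05 on the same individuals.
#'
#' @param seed integer seed.
#' @param n_markers dense-panel marker count (default 60,000).
#' @param n_chip chip-panel marker count (default 5,000).
#' @param missing_rate uniform genotype missingness (default 0.005).
#' @param selection_spikes optional spike table passed through to
#'   [simulation_config()].
#' @return list with `wgs` and `chip` genotype tables, `pops` (the sample
#'   map) and `truth`.
#' @export
paper_like_scenario <- function(seed = 1L, n_markers = 60000L,
                                n_chip = 5000L, missing_rate = 0.005,
                                selection_spikes = NULL) {
  cfg <- simulation_config(
    n_markers = n_markers,
    chromosome_lengths = setNames(rep(4e7, 5), as.character(1:5)),
    line_specs = data.frame(
      label = c("A", "B", "C", "D"),
      n_samples = c(20L, 34L, 34L, 40L),
      f = c(0.02, 0.02, 0.10, 0.03),
      parent = c("Arp", "Arp", "RIR", "RIR"),
      stringsAsFactors = FALSE
    ),
    parent_pools = data.frame(name = c("Arp", "RIR"), f = c(0.15, 0.15),
                              stringsAsFactors = FALSE),
    shared_ancestry = list(c("A", "B")),
    selection_spikes = selection_spikes,
    missing_rate = missing_rate,
    seed = seed
  )
  sim <- simulate_populations(cfg)
  chip <- ascertain_chip(sim$gt, chip_config(maf_min = 0.05,
                                             n_chip_markers = n_chip,
                                             seed = seed))
  list(wgs = sim$gt, chip = chip, pops = sim$gt$samples, truth = sim$truth)
}
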