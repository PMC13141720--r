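#' Pipeline configuration
#'
#' One object carrying every stage's parameters for [run_pipeline()]. The
#' same seed propagates (through named sub-streams) to every stochastic
#' stage, so a run is reproducible end to end.
#'
#' @param mode `"simulate"` (default four-line scenario) or `"vcf-pair"`.
#' @param wgs_vcf,chip_vcf,population_map paths, used in `"vcf-pair"` mode.
#' @param seed integer seed.
#' @param qc a [qc_config()].
#' @param prune_structure LD-prune the input of PCA/tree/admixture stages
#'   (default TRUE); window statistics always use unpruned post-QC data.
#' @param diversity_window_bp,diversity_step_bp sliding-window grid for pi
#'   and pairwise F_ST (defaults 100 kb / 30 kb).
#' @param lsbl_window_bp non-overlapping window size for the LSBL scan.
#' @param top_fraction top quantile fraction for candidate windows.
#' @param ratio_tail_fraction per-tail fraction for the log2 pi-ratio.
#' @param lsbl_focal,lsbl_refs focal line label(s) (pooled when a vector)
#'   and two reference labels for the LSBL scan.
#' @param scan_pair the two lines contrasted in the joint F_ST-pi scan.
#' @param k_range candidate K values for the admixture CV (default 1:6 at
#'   simulation scale; extend as needed).
#' @param n_folds CV folds.
#' @param n_bootstrap tree bootstrap replicates (default 100 at simulation
#'   scale).
#' @param n_pcs components to compute and compare.
#' @param sim_markers,sim_chip_markers,sim_missing_rate simulation-scenario
#'   knobs passed to [paper_like_scenario()].
#' @param out_dir output directory for stage artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "vcf-pair"),
                            wgs_vcf = NULL, chip_vcf = NULL,
                            population_map = NULL,
                            seed = 1L,
                            qc = qc_config(),
                            prune_structure = TRUE,
                            diversity_window_bp = 1e5,
                            diversity_step_bp = 3e4,
                            lsbl_window_bp = 1e5,
                            top_fraction = 0.05,
                            ratio_tail_fraction = 0.025,
                            lsbl_focal = c("A", "B"),
                            lsbl_refs = c("C", "D"),
                            scan_pair = c("C", "D"),
                            k_range = 1:6,
                            n_folds = 5L,
                            n_bootstrap = 100L,
                            n_pcs = 10L,
                            sim_markers = 60000L,
                            sim_chip_markers = 5000L,
                            sim_missing_rate = 0.005,
                            out_dir = tempfile("chipconcord_run_")) {
  mode <- match.arg(mode)
  if (mode == "vcf-pair" &&
      (is.null(wgs_vcf) || is.null(chip_vcf) || is.null(population_map)))
    stop("vcf-pair mode needs wgs_vcf, chip_vcf and population_map")
  structure(as.list(environment()), class = "pipeline_config")
}

# Run every per-platform stage; internal worker of run_pipeline.
platform_stages <- function(gt, cfg, platform) {
  qcd <- apply_qc(gt, cfg$qc)
  structure_input <- if (cfg$prune_structure) ld_prune(qcd, cfg$qc) else qcd

  pc <- pca(structure_input, cfg$n_pcs)
  tr <- bootstrap_support(structure_input, cfg$n_bootstrap, seed = cfg$seed)
  cv <- cv_error(structure_input, cfg$k_range, cfg$n_folds, seed = cfg$seed)
  adm <- admixture_fit(structure_input, cv$best_k, seed = cfg$seed)

  div <- diversity_report(qcd, window_bp = cfg$diversity_window_bp,
                          step_bp = cfg$diversity_step_bp)
  ls <- lsbl_scan(qcd, cfg$lsbl_focal, cfg$lsbl_refs[1], cfg$lsbl_refs[2],
                  cfg$lsbl_window_bp)
  lsbl_regions <- empirical_top_fraction(ls, "lsbl", cfg$top_fraction)

  fst_cd <- windowed_fst(qcd, cfg$scan_pair[1], cfg$scan_pair[2],
                         cfg$diversity_window_bp, cfg$diversity_step_bp)
  joint <- fst_pi_joint_scan(fst_cd,
                             div$windows[[cfg$scan_pair[1]]],
                             div$windows[[cfg$scan_pair[2]]],
                             cfg$top_fraction, cfg$ratio_tail_fraction,
                             label_x = cfg$scan_pair[1],
                             label_y = cfg$scan_pair[2])
  list(platform = platform, qc = qcd,
       filter_report = attr(qcd, "filter_report"),
       structure_input = structure_input, pca = pc, tree = tr,
       cv = cv, admixture = adm, diversity = div,
       lsbl_windows = ls, lsbl_regions = lsbl_regions,
       fst_windows = fst_cd, joint_regions = joint)
}

write_window_table <- function(w, path) {
  utils::write.table(w, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full two-platform evaluation pipeline
#'
#' Simulates (or ingests) a dense panel and a chip panel on the same
#' individuals, runs identical QC, structure, diversity and selection stages
#' on each, computes cross-platform concordance, writes all stage artifacts
#' under `cfg$out_dir` and returns the results with a run manifest (config
#' echo plus md5 checksums of every written file).
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_run`: `platforms` (per-platform stage
#'   results), `concordance`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (cfg$mode == "simulate") {
    scen <- paper_like_scenario(cfg$seed, n_markers = cfg$sim_markers,
                                n_chip = cfg$sim_chip_markers,
                                missing_rate = cfg$sim_missing_rate)
    panels <- list(wgs = scen$wgs, chip = scen$chip)
  } else {
    panels <- list(
      wgs = read_vcf(cfg$wgs_vcf, cfg$population_map),
      chip = read_vcf(cfg$chip_vcf, cfg$population_map)
    )
  }

  stages <- lapply(names(panels), function(pl) {
    res <- tryCatch(platform_stages(panels[[pl]], cfg, pl),
                    error = function(e) stop("stage failure on platform '",
                                             pl, "': ", conditionMessage(e)))
    out <- file.path(cfg$out_dir, pl)
    dir.create(out, showWarnings = FALSE)
    write_filter_report(res$qc, file.path(out, "filter_report.json"))
    write_pca(res$pca, file.path(out, "pca_scores.tsv"),
              file.path(out, "pca_eigenvalues.tsv"))
    write_newick(res$tree, file.path(out, "nj_tree.nwk"))
    write_ancestry(res$admixture, file.path(out, "Q.txt"),
                   file.path(out, "P.txt"))
    utils::write.table(res$cv$table, file.path(out, "cv_error.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$diversity$summary,
                       file.path(out, "diversity_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_window_table(res$lsbl_windows, file.path(out, "lsbl_windows.tsv"))
    write_regions_bed(res$lsbl_regions, file.path(out, "lsbl_regions.bed"))
    write_window_table(res$fst_windows, file.path(out, "fst_windows.tsv"))
    write_regions_bed(res$joint_regions, file.path(out, "joint_regions.bed"))
    res
  })
  names(stages) <- names(panels)

  k_shared <- min(stages$wgs$cv$best_k, stages$chip$cv$best_k)
  q_wgs <- admixture_fit(stages$wgs$structure_input, k_shared, seed = cfg$seed)
  q_chip <- admixture_fit(stages$chip$structure_input, k_shared, seed = cfg$seed)
  conc <- concordance_report(stages$wgs$pca, stages$chip$pca,
                             stages$wgs$diversity$summary,
                             stages$chip$diversity$summary,
                             regions_a = stages$wgs$joint_regions,
                             regions_b = stages$chip$joint_regions,
                             qa = q_wgs$Q, qb = q_chip$Q,
                             n_components = 2L)
  write_concordance(conc, file.path(cfg$out_dir, "concordance.json"))

  rel <- list.files(cfg$out_dir, recursive = TRUE)
  sums <- tools::md5sum(file.path(cfg$out_dir, rel))
  names(sums) <- rel
  manifest <- list(
    package_version = as.character(utils::packageVersion("chipconcord")),
    seed = cfg$seed,
    mode = cfg$mode,
    prune_structure = cfg$prune_structure,
    checksums = as.list(sums)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(platforms = stages, concordance = conc, manifest = manifest,
                 out_dir = cfg$out_dir),
            class = "pipeline_run")
}

#' Summarize a pipeline run
#'
#' Builds one summary mirroring the result structure of a platform
#' comparison: per-PC correlations, the per-line-per-platform diversity
#' table, CV optima, and candidate-region counts and overlap. Incomplete
#' runs yield a partial summary flagged as such.
#'
#' @param run a `pipeline_run`.
#' @return list of class `run_report`.
#' @export
report_run <- function(run) {
  complete <- !is.null(run$concordance) && length(run$platforms) == 2
  div <- do.call(rbind, lapply(run$platforms, function(s) {
    if (is.null(s$diversity)) return(NULL)
    cbind(platform = s$platform, s$diversity$summary)
  }))
  rownames(div) <- NULL
  rep <- list(
    complete = complete,
    pc_correlation = run$concordance$pc_correlation,
    diversity_table = div,
    cv_best_k = vapply(run$platforms, function(s)
      if (is.null(s$cv)) NA_integer_ else as.integer(s$cv$best_k), 1L),
    lsbl_threshold = vapply(run$platforms, function(s)
      if (is.null(s$lsbl_regions)) NA_real_ else s$lsbl_regions$threshold, 1.0),
    n_candidate_regions = vapply(run$platforms, function(s)
      if (is.null(s$joint_regions)) NA_integer_
      else nrow(s$joint_regions$windows), 1L),
    region_overlap = run$concordance$region_overlap,
    ancestry_rmse = run$concordance$ancestry_rmse
  )
  class(rep) <- "run_report"
  rep
}

#' @export
print.run_report <- function(x, ...) {
  if (!x$complete) cat("[partial run]\n")
  cat("== Structure concordance ==\n")
  print(x$pc_correlation, row.names = FALSE)
  cat("== Diversity (per line, per platform) ==\n")
  print(x$diversity_table, row.names = FALSE, digits = 4)
  cat("== Model selection ==\n")
  print(x$cv_best_k)
  cat("== Selection scans ==\n")
  cat("LSBL top-5% thresholds:", sprintf("%s=%.4f", names(x$lsbl_threshold),
                                         x$lsbl_threshold), "\n")
  cat("joint-scan candidate windows:", sprintf("%s=%d",
      names(x$n_candidate_regions), x$n_candidate_regions), "\n")
  if (!is.null(x$region_overlap))
    cat(sprintf("region Jaccard: %.3f\n", x$region_overlap$jaccard))
  if (!is.null(x$ancestry_rmse))
    cat(sprintf("ancestry Q RMSE: %.4f\n", x$ancestry_rmse))
  invisible(x)
}
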