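#!/usr/bin/env Rscript
# Stage 2: population structure on both platforms.
#
# Applies identical QC and LD pruning to the dense and chip panels, then runs
# Patterson-scaled PCA, a bootstrapped neighbor-joining tree, and
# admixture-model cross-validation over K on each. Writes per-platform scores,
# trees, Q matrices and CV tables under results/structure/.
# Usage: Rscript analysis/02_structure.R [seed]   (after 01_simulate.R)

suppressPackageStartupMessages(library(chipconcord))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- qc_config()
for (platform in c("wgs", "chip")) {
  gt <- read_vcf(file.path("scratch/data", paste0(platform, ".vcf")),
                 "scratch/data/pops.tsv")
  qcd <- apply_qc(gt, cfg)
  rep <- attr(qcd, "filter_report")
  pruned <- ld_prune(qcd, cfg)
  cat(sprintf("[%s] %d sites in, %d after QC, %d after LD pruning\n",
              platform, rep$n_sites_in, rep$n_sites_out,
              ncol(pruned$dosages)))

  out <- file.path("results/structure", platform)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_filter_report(qcd, file.path(out, "filter_report.json"))

  pc <- pca(pruned, 10)
  write_pca(pc, file.path(out, "pca_scores.tsv"),
            file.path(out, "pca_eigenvalues.tsv"))
  pve <- 100 * pc$eigenvalues[1:2] / sum(pc$eigenvalues)
  cat(sprintf("[%s] PC1/PC2 explain %.1f%% / %.1f%% of retained variance\n",
              platform, pve[1], pve[2]))

  tr <- bootstrap_support(pruned, n_replicates = 100, seed = seed)
  write_newick(tr, file.path(out, "nj_tree.nwk"))
  cat(sprintf("[%s] NJ tree with median bootstrap support %.0f\n",
              platform, median(tr$support)))

  cv <- cv_error(pruned, K_values = 1:4, n_folds = 3, seed = seed)
  write.table(cv$table, file.path(out, "cv_error.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("[%s] CV optimum at K = %d\n", platform, cv$best_k))

  fit <- admixture_fit(pruned, cv$best_k, seed = seed)
  write_ancestry(fit, file.path(out, "Q.txt"), file.path(out, "P.txt"))
}
cat("Structure artifacts written to results/structure/\n")
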