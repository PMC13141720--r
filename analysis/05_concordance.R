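#!/usr/bin/env Rscript
# Stage 5: quantify cross-platform agreement — the evaluation this pipeline
# exists for. Reads the artifacts of stages 2-4 and reports:
#   - sign-aligned Pearson r of PC1/PC2 scores between platforms,
#   - Spearman rank concordance (and exact-ordering flag) of per-line He/pi,
#   - Jaccard overlap of merged joint-scan candidate regions,
#   - RMSE between ancestry Q matrices after best column permutation.
# Usage: Rscript analysis/05_concordance.R   (after 02, 03 and 04)

suppressPackageStartupMessages(library(chipconcord))

read_scores <- function(platform) {
  tab <- read.table(file.path("results/structure", platform, "pca_scores.tsv"),
                    header = TRUE, sep = "\t")
  scores <- as.matrix(tab[, -1])
  rownames(scores) <- tab$sample_id
  structure(list(scores = scores), class = "pca_result")
}
read_summary <- function(platform) {
  read.table(file.path("results/diversity", paste0(platform, "_summary.tsv")),
             header = TRUE, sep = "\t")
}
read_bed_regions <- function(platform, stem) {
  path <- file.path("results/selection", sprintf("%s_%s.bed", platform, stem))
  bed <- tryCatch(read.table(path, sep = "\t"), error = function(e) NULL)
  w <- if (is.null(bed)) {
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  } else data.frame(chrom = as.character(bed$V1), start = bed$V2 + 1L,
                    end = bed$V3)
  structure(list(statistic = stem, fraction = 0.05, threshold = NA,
                 windows = w),
            class = "candidate_regions")
}
read_q <- function(platform) {
  as.matrix(read.table(file.path("results/structure", platform, "Q.txt")))
}

pcs <- align_and_correlate_pcs(read_scores("wgs"), read_scores("chip"), 2)
ranks <- diversity_rank_concordance(read_summary("wgs"), read_summary("chip"))
regions <- region_overlap(read_bed_regions("wgs", "joint_CD"),
                          read_bed_regions("chip", "joint_CD"))
q_wgs <- read_q("wgs")
q_chip <- read_q("chip")
ancestry_rmse <- if (ncol(q_wgs) == ncol(q_chip))
  q_matrix_agreement(q_wgs, q_chip)$rmse else NA

report <- list(pc_correlation = pcs, diversity_ranks = ranks,
               region_overlap = regions, ancestry_rmse = ancestry_rmse)
class(report) <- "concordance_report"
print(report)
write_concordance(report, "results/concordance.json")
cat("Concordance report written to results/concordance.json\n")
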