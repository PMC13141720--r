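#!/usr/bin/env Rscript
# Stage 4: selection scans on both platforms.
#
# Two complementary scans, run identically on each platform's QC-passed
# (unpruned) data:
#   (a) LSBL over non-overlapping 100-kb windows with the pooled A+B lines as
#       the focal branch and C, D as references; candidate windows are the
#       top 5% of the empirical LSBL distribution.
#   (b) joint F_ST / log2 pi-ratio scan between lines C and D (100 kb/30 kb
#       windows): top-5% F_ST AND either 2.5% tail of the log2 ratio, each
#       flagged window labeled with its reduced-diversity line.
# Writes window tables and candidate BED files under results/selection/.
# Usage: Rscript analysis/04_selection.R   (after 01_simulate.R)

suppressPackageStartupMessages(library(chipconcord))
cfg <- qc_config()
dir.create("results/selection", recursive = TRUE, showWarnings = FALSE)

for (platform in c("wgs", "chip")) {
  gt <- read_vcf(file.path("scratch/data", paste0(platform, ".vcf")),
                 "scratch/data/pops.tsv")
  qcd <- apply_qc(gt, cfg)

  ls <- lsbl_scan(qcd, focal = c("A", "B"), ref1 = "C", ref2 = "D")
  write.table(ls, file.path("results/selection",
                            paste0(platform, "_lsbl_windows.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  lsbl_regions <- empirical_top_fraction(ls, "lsbl", 0.05)
  write_regions_bed(lsbl_regions,
                    file.path("results/selection",
                              paste0(platform, "_lsbl_top5.bed")))
  cat(sprintf("[%s] LSBL: %d/%d windows flagged at threshold %.4f\n",
              platform, nrow(lsbl_regions$windows), lsbl_regions$n_total,
              lsbl_regions$threshold))

  joint <- fst_pi_joint_scan(windowed_fst(qcd, "C", "D"),
                             windowed_pi(qcd, "C"),
                             windowed_pi(qcd, "D"),
                             label_x = "C", label_y = "D")
  write_regions_bed(joint, file.path("results/selection",
                                     paste0(platform, "_joint_CD.bed")))
  cat(sprintf(
    "[%s] joint F_ST-pi: %d windows flagged (F_ST >= %.4f; reduced in C: %d, in D: %d)\n",
    platform, nrow(joint$windows), joint$threshold,
    sum(joint$windows$reduced_line == "C"),
    sum(joint$windows$reduced_line == "D")))
}
cat("Selection artifacts written to results/selection/\n")
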