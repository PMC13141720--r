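# Shared fixture builders; all fixtures are generated in code.

# Small genotype table from an explicit dosage matrix (rows = samples).
toy_gt <- function(dosages, pos = NULL, chrom = NULL, lines = NULL,
                   chrom_lengths = NULL) {
  d <- as.matrix(dosages)
  m <- ncol(d)
  n <- nrow(d)
  pos <- pos %||% (seq_len(m) * 100L)
  chrom <- chrom %||% rep("1", m)
  lines <- lines %||% rep("A", n)
  genotype_table(
    d,
    data.frame(chrom = chrom, pos = pos, ref = rep("A", m),
               alt = rep("C", m), stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("s%02d", seq_len(n)), line = lines,
               stringsAsFactors = FALSE),
    chrom_lengths = chrom_lengths
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random dosage matrix with optional missingness, seeded.
random_dosages <- function(n, m, p = 0.4, missing = 0, seed = 1) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, p), n, m)
  if (missing > 0) d[runif(n * m) < missing] <- NA
  d
}

# Write a small VCF from explicit body lines; returns the path.
write_vcf_text <- function(body, samples, dir = tempdir()) {
  path <- tempfile("toy_", fileext = ".vcf", tmpdir = dir)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  path
}

toy_pop_map <- function(samples, lines) {
  data.frame(sample_id = samples, line = lines, stringsAsFactors = FALSE)
}
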