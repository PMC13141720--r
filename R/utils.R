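# Internal helpers shared across modules.

# Deterministic sub-seed for a named random stream, so each stage of a run
# can be regenerated independently from one user-facing seed. Kept below
# .Machine$integer.max.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483647)
}

# Natural chromosome ordering: numeric names first in numeric order, then
# the rest alphabetically ("1" < "2" < "10" < "Z").
chrom_order <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(u))
  lev <- c(u[!is.na(num)][order(num[!is.na(num)])], sort(u[is.na(num)]))
  factor(as.character(chrom), levels = lev)
}

# All permutations of 1..n as a list (n small; used for Q-column matching).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    for (p in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
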