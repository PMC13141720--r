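# Independent transcription of the 1984 variance-component estimator in its
# general r-population notation (nc written via the squared coefficient of
# variation of sample sizes), evaluated site by site: the oracle for
# wc_components.
wc_oracle_site <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  C2 <- sum((n - nbar)^2) / (r * nbar^2)   # squared CV of sample sizes
  nC <- nbar * (1 - C2 / (r - 1))
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nC) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}
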