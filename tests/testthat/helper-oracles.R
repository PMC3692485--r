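# Small independent oracles used across test files.

# Gaussian BIC straight from the log-density sum (independent of the
# closed-form expression used by the package).
brute_force_bic <- function(residuals, d) {
  m <- length(residuals)
  sigma2 <- sum(residuals^2) / m
  -2 * sum(stats::dnorm(residuals, mean = 0, sd = sqrt(sigma2),
                        log = TRUE)) + d * log(m)
}

# First-order partial correlation from raw data via explicit lm residuals.
lm_residual_pcor <- function(a, b, c) {
  ra <- stats::residuals(stats::lm(a ~ c))
  rb <- stats::residuals(stats::lm(b ~ c))
  stats::cor(ra, rb)
}

# GRanges constructor shorthand for interval fixtures (1-based closed).
gr <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start, end = end),
                         strand = strand)
}

# F1 of an estimated undirected edge set against a true one.
edge_f1 <- function(est, tru) {
  key <- function(e) paste(pmin(e$a, e$b), pmax(e$a, e$b))
  tp <- length(intersect(key(est), key(tru)))
  2 * tp / (nrow(est) + nrow(tru))
}
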