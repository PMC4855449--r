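# Small fixtures built in code: panels, genotype files, VCFs.

tiny_panel_df <- function() {
  data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(1e6, 3e6, 1e6),
    allele1 = c("A", "C", "G"),
    allele2 = c("G", "T", "A"),
    p_eu = c(0.90, 0.10, 0.80),
    p_ai = c(0.60, 0.20, 0.60),
    p_af = c(0.10, 0.70, 0.20),
    stringsAsFactors = FALSE)
}

tiny_panel <- function() as_parental_panel(tiny_panel_df())

# A random valid panel (no delta structure) for property checks.
random_panel <- function(G, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  as_parental_panel(data.frame(
    snp_id = sprintf("r%03d", seq_len(G)),
    chrom = "1",
    pos = seq_len(G) * 1e6,
    allele1 = "A", allele2 = "G",
    p_eu = runif(G, 0.02, 0.98),
    p_ai = runif(G, 0.02, 0.98),
    p_af = runif(G, 0.02, 0.98),
    stringsAsFactors = FALSE))
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Independent brute-force grid oracle: dbinom-based log-likelihood,
# exhaustive enumeration, first-maximum tie-break.
oracle_grid_mle <- function(dosages, panel, step, clamp = 1e-3) {
  k <- round(1 / step)
  best <- c(-Inf, NA, NA)
  keep <- !is.na(dosages)
  d <- dosages[keep]
  for (i1 in 0:k) {
    for (i2 in 0:(k - i1)) {
      m1 <- i1 * step
      m2 <- i2 * step
      p <- panel$p_af + m1 * (panel$p_eu - panel$p_af) +
        m2 * (panel$p_ai - panel$p_af)
      p <- pmin(pmax(p, clamp), 1 - clamp)
      ll <- sum(dbinom(d, 2, p[keep], log = TRUE))
      if (ll > best[1]) best <- c(ll, m1, m2)
    }
  }
  best
}

# Expected log-likelihood with genotype probabilities held at m0 and
# log-probabilities varying with m: the function whose negated Hessian at
# m = m0 is the Fisher information.
expected_loglik_fn <- function(panel, m0, clamp = 1e-3) {
  p0 <- hybrid_freq(m0[1], m0[2], panel, clamp = clamp)
  probs0 <- cbind((1 - p0)^2, 2 * p0 * (1 - p0), p0^2)
  function(m) {
    p <- hybrid_freq(m[1], m[2], panel, clamp = clamp)
    lp <- cbind(2 * log1p(-p), log(2) + log(p) + log1p(-p), 2 * log(p))
    sum(probs0 * lp)
  }
}
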