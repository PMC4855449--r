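# Internal helpers shared across modules.

# Clamp frequencies away from 0/1 so log-likelihood terms stay finite.
clamp01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

# x * log(x) with the 0 * log(0) = 0 convention (entropy terms).
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# Rank chromosomes numerically where possible ("1" < "2" < "10"),
# non-numeric labels after, alphabetically.
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  num[is.na(num)] <- Inf
  order(order(num, as.character(chrom)))
}

# Integer lattice over the simplex {m1 >= 0, m2 >= 0, m1 + m2 <= k},
# ordered by m1 ascending then m2 ascending so that the first maximum
# encountered is the tie-break winner (smallest m1, then smallest m2).
# Cached: the step-0.001 grid has 501,501 points.
.grid_cache <- new.env(parent = emptyenv())

simplex_grid_int <- function(k) {
  key <- as.character(k)
  g <- get0(key, envir = .grid_cache, inherits = FALSE)
  if (!is.null(g)) return(g)
  m1 <- rep.int(0:k, k + 1L - 0:k)
  m2 <- sequence(k + 1L - 0:k, from = 0L, by = 1L)
  g <- cbind(m1 = m1, m2 = m2)
  if (k <= 1000L) assign(key, g, envir = .grid_cache)
  g
}

# The three pairwise population contrasts and the frequency columns they use.
contrast_pairs <- function() {
  list("EU-AI" = c("p_eu", "p_ai"),
       "EU-AF" = c("p_eu", "p_af"),
       "AI-AF" = c("p_ai", "p_af"))
}
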