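# Core maximum-likelihood estimator of individual genetic ancestry under a
# three-ancestral-population model with fixed parental allele frequencies.
#
# The model: an individual with ancestry proportions (m1, m2, m3), m3 = 1 -
# m1 - m2, carries allele 1 at SNP g with expected ("hybrid") frequency
#   P_g = p_af_g + m1 * (p_eu_g - p_af_g) + m2 * (p_ai_g - p_af_g),
# and under Hardy-Weinberg equilibrium the genotype dosage d in {0, 1, 2}
# is Binomial(2, P_g). The log-likelihood is maximized on a lattice over
# the simplex (default step 0.001); variances come from inverting the 2x2
# information matrix, with V(m3) = V(m1) + V(m2) + 2 Cov(m1, m2).

#' Signed allele-frequency differences of a panel
#'
#' For each SNP, the allele-1 differences relative to the African
#' reference: `delta1 = p_eu - p_af` and `delta2 = p_ai - p_af`. For a
#' biallelic SNP the allele-2 differences are their negatives
#' (`delta3 = -delta1`, `delta4 = -delta2`).
#'
#' @param panel a `parental_panel`.
#' @return data frame with columns `snp_id`, `delta1`, `delta2`,
#'   `delta3`, `delta4`.
#' @export
compute_deltas <- function(panel) {
  stopifnot(inherits(panel, "parental_panel"))
  d1 <- panel$p_eu - panel$p_af
  d2 <- panel$p_ai - panel$p_af
  data.frame(snp_id = panel$snp_id, delta1 = d1, delta2 = d2,
             delta3 = -d1, delta4 = -d2, stringsAsFactors = FALSE)
}

check_simplex <- function(m1, m2, tol = 1e-9) {
  if (any(m1 < -tol) || any(m2 < -tol) || any(m1 + m2 > 1 + tol)) {
    stop("(m1, m2) outside the ancestry simplex: need m1, m2 >= 0 and m1 + m2 <= 1")
  }
}

#' Expected allele-1 frequency in an admixed individual
#'
#' The convex combination `m1 * p_eu + m2 * p_ai + (1 - m1 - m2) * p_af`,
#' computed as `p_af + m1 * delta1 + m2 * delta2` and clamped to
#' `[clamp, 1 - clamp]` so downstream logarithms stay finite when a
#' reference frequency is 0 or 1.
#'
#' @param m1,m2 European and American Indian ancestry proportions;
#'   must satisfy `m1, m2 >= 0`, `m1 + m2 <= 1`.
#' @param snp one or more panel rows (any data frame with `p_eu`, `p_ai`,
#'   `p_af`).
#' @param clamp clamping threshold (default 1e-3).
#' @return numeric vector of hybrid allele-1 frequencies.
#' @export
hybrid_freq <- function(m1, m2, snp, clamp = 1e-3) {
  check_simplex(m1, m2)
  p <- snp$p_af + m1 * (snp$p_eu - snp$p_af) + m2 * (snp$p_ai - snp$p_af)
  clamp01(p, clamp)
}

#' Log-likelihood of one genotype given a hybrid allele frequency
#'
#' Hardy-Weinberg genotype probabilities on the natural-log scale:
#' dosage 2 gives `log(p^2)`, dosage 1 `log(2 p (1 - p))`, dosage 0
#' `log((1 - p)^2)`.
#'
#' @param dosage allele-1 dosage(s) in `{0, 1, 2}`.
#' @param p_h hybrid allele-1 frequency, in (0, 1) after clamping.
#' @return log-likelihood contribution(s).
#' @export
genotype_loglik <- function(dosage, p_h) {
  if (any(!(dosage %in% c(0, 1, 2)))) stop("dosage must be 0, 1 or 2")
  dosage * log(p_h) + (2 - dosage) * log1p(-p_h) + (dosage == 1) * log(2)
}

#' Total log-likelihood of a dosage vector at given ancestry proportions
#'
#' Sums [genotype_loglik()] over the non-missing SNPs of the vector.
#'
#' @param dosages allele-1 dosages aligned to the panel; `NA` entries are
#'   skipped.
#' @param panel a `parental_panel`.
#' @param m1,m2 ancestry proportions on the simplex.
#' @param clamp hybrid-frequency clamping threshold.
#' @return the summed log-likelihood.
#' @export
total_loglik <- function(dosages, panel, m1, m2, clamp = 1e-3) {
  stopifnot(inherits(panel, "parental_panel"), length(dosages) == nrow(panel))
  keep <- !is.na(dosages)
  if (!any(keep)) stop("all genotypes missing: no data to compute a likelihood")
  p <- hybrid_freq(m1, m2, panel[keep, , drop = FALSE], clamp = clamp)
  sum(genotype_loglik(dosages[keep], p))
}

# Evaluate the log-likelihood of every individual at a block of grid
# points and fold into the running per-individual maximum.
#
# Dm: dosages with NA -> 0; W: (2 - dosage) with NA -> 0 -- so missing
# SNPs contribute nothing. grid_int: B x 2 integer matrix in units of
# `step`, ordered (m1 asc, m2 asc). `best` carries val/m1i/m2i/tie across
# blocks; blocks must be supplied in ascending grid order so that on ties
# the earlier (smaller m1, then m2) point is kept.
.fold_grid_block <- function(Dm, W, grid_int, step, p_af, d1, d2, clamp, best) {
  M <- grid_int * step
  P <- M %*% rbind(d1, d2)
  P <- P + rep(p_af, each = nrow(M))
  P <- clamp01(P, clamp)
  LL <- Dm %*% t(log(P)) + W %*% t(log1p(-P))
  j <- max.col(LL, ties.method = "first")
  idx <- cbind(seq_len(nrow(LL)), j)
  val <- LL[idx]
  tie_in_block <- rowSums(LL == val) > 1L
  upd <- val > best$val
  tie <- tie_in_block | (is.finite(val) & val == best$val)
  best$tie <- best$tie | tie
  best$val[upd] <- val[upd]
  best$m1i[upd] <- grid_int[j[upd], 1L]
  best$m2i[upd] <- grid_int[j[upd], 2L]
  best
}

.new_best <- function(n) {
  list(val = rep(-Inf, n), m1i = rep(NA_integer_, n),
       m2i = rep(NA_integer_, n), tie = rep(FALSE, n))
}

# Exhaustive lattice maximization, blocked to bound memory.
.search_exact <- function(Dm, W, k, step, p_af, d1, d2, clamp) {
  grid <- simplex_grid_int(k)
  G <- length(p_af)
  block <- max(1024L, as.integer(5e6 / max(G, 1L)))
  best <- .new_best(nrow(Dm))
  for (start in seq(1L, nrow(grid), by = block)) {
    end <- min(start + block - 1L, nrow(grid))
    best <- .fold_grid_block(Dm, W, grid[start:end, , drop = FALSE], step,
                             p_af, d1, d2, clamp, best)
  }
  best
}

# Coarse-to-fine maximization: a global pass at 10x the step, then the
# full-resolution lattice inside a +/- 2-coarse-step window around each
# coarse optimum. The log-likelihood is concave in (m1, m2) (log of an
# affine function), so the window contains the global lattice optimum.
.search_coarse_fine <- function(Dm, W, k, step, p_af, d1, d2, clamp) {
  if (k %% 10L != 0L || k <= 100L) {
    return(.search_exact(Dm, W, k, step, p_af, d1, d2, clamp))
  }
  coarse <- simplex_grid_int(k %/% 10L) * 10L
  best <- .new_best(nrow(Dm))
  best <- .fold_grid_block(Dm, W, coarse, step, p_af, d1, d2, clamp, best)

  centers <- unique(cbind(best$m1i, best$m2i))
  offsets <- as.matrix(expand.grid(o2 = -20:20, o1 = -20:20))[, c("o1", "o2")]
  final <- .new_best(nrow(Dm))
  final$tie <- best$tie
  for (r in seq_len(nrow(centers))) {
    who <- which(best$m1i == centers[r, 1L] & best$m2i == centers[r, 2L])
    cand <- cbind(centers[r, 1L] + offsets[, 1L],
                  centers[r, 2L] + offsets[, 2L])
    ok <- cand[, 1L] >= 0L & cand[, 2L] >= 0L & rowSums(cand) <= k
    cand <- cand[ok, , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    sub <- .fold_grid_block(Dm[who, , drop = FALSE], W[who, , drop = FALSE],
                            cand, step, p_af, d1, d2, clamp,
                            .new_best(length(who)))
    final$val[who] <- sub$val
    final$m1i[who] <- sub$m1i
    final$m2i[who] <- sub$m2i
    final$tie[who] <- final$tie[who] | sub$tie
  }
  final
}

# Per-individual information matrix entries at the individual's own
# (m1, m2), summed over that individual's non-missing SNPs.
.info_cohort <- function(D, panel, m1, m2, clamp, type = "expected") {
  d1 <- panel$p_eu - panel$p_af
  d2 <- panel$p_ai - panel$p_af
  N <- nrow(D)
  P <- outer(m1, d1) + outer(m2, d2) + rep(panel$p_af, each = N)
  P <- clamp01(P, clamp)
  mask <- !is.na(D)
  if (type == "expected") {
    # Fisher: E[d] = 2P under the HWE binomial, giving 2 delta^2 / (P(1-P)).
    w <- mask * (2 / (P * (1 - P)))
  } else {
    # Observed: negated Hessian of the realized log-likelihood.
    Dm <- D
    Dm[!mask] <- 0
    w <- mask * (Dm / P^2 + (2 - Dm) / (1 - P)^2)
    w[!mask] <- 0
  }
  list(i_m1 = drop(w %*% (d1 * d1)),
       i_m2 = drop(w %*% (d2 * d2)),
       i_m1m2 = drop(w %*% (d1 * d2)))
}

#' Information matrix for one individual's ancestry estimate
#'
#' Entries of the symmetric 2x2 information matrix for (m1, m2), summed
#' over the individual's non-missing SNPs. With `type = "expected"`
#' (default) the Fisher information under the Hardy-Weinberg binomial is
#' used: per SNP, `2 delta1^2 / (P(1-P))`, `2 delta2^2 / (P(1-P))` and
#' `2 delta1 delta2 / (P(1-P))` with `P` the hybrid frequency. With
#' `type = "observed"` the negated Hessian of the realized log-likelihood
#' is summed instead (a sensitivity option; both coincide in expectation).
#'
#' @param dosages allele-1 dosages aligned to the panel (`NA` = missing).
#' @param panel a `parental_panel`.
#' @param m1,m2 ancestry proportions, normally the maximum-likelihood
#'   estimates.
#' @param clamp hybrid-frequency clamping threshold.
#' @param type `"expected"` (Fisher) or `"observed"`.
#' @return list of class `information_matrix` with `i_m1`, `i_m2`,
#'   `i_m1m2`.
#' @export
information_matrix <- function(dosages, panel, m1, m2, clamp = 1e-3,
                               type = c("expected", "observed")) {
  type <- match.arg(type)
  stopifnot(inherits(panel, "parental_panel"), length(dosages) == nrow(panel))
  check_simplex(m1, m2)
  info <- .info_cohort(matrix(dosages, nrow = 1), panel, m1, m2, clamp, type)
  structure(lapply(info, drop), class = "information_matrix")
}

#' Invert an information matrix into variances and standard errors
#'
#' The inverse of the 2x2 information matrix gives `V(m1)`, `V(m2)` and
#' their covariance; `V(m3) = V(m1) + V(m2) + 2 Cov(m1, m2)` by the
#' simplex constraint, and standard errors are square roots. A singular
#' or near-singular matrix (determinant at or below `tol` relative to the
#' entry scale) raises a degenerate-information error: it is the explicit
#' form of the warning that an estimate from insufficient information
#' carries a large, untrustworthy standard error.
#'
#' @param info an `information_matrix` (or a list with `i_m1`, `i_m2`,
#'   `i_m1m2`).
#' @param tol relative determinant tolerance.
#' @return list with `v_m1`, `v_m2`, `cov_m1m2`, `v_m3`, `se_m1`,
#'   `se_m2`, `se_m3`.
#' @export
invert_information <- function(info, tol = 1e-12) {
  i1 <- info$i_m1
  i2 <- info$i_m2
  i12 <- info$i_m1m2
  det <- i1 * i2 - i12 * i12
  scale <- max(abs(i1 * i2), i12 * i12, 1)
  if (!is.finite(det) || det <= tol * scale) {
    stop("degenerate information matrix (determinant ~ 0): ",
         "the data do not identify the ancestry components")
  }
  v1 <- i2 / det
  v2 <- i1 / det
  cv <- -i12 / det
  v3 <- v1 + v2 + 2 * cv
  list(v_m1 = v1, v_m2 = v2, cov_m1m2 = cv, v_m3 = v3,
       se_m1 = sqrt(v1), se_m2 = sqrt(v2), se_m3 = sqrt(max(v3, 0)))
}

# Vectorized inversion for a cohort; degenerate rows become NA (counted
# by the caller) instead of aborting the whole cohort.
.invert_cohort <- function(info, tol = 1e-12) {
  det <- info$i_m1 * info$i_m2 - info$i_m1m2^2
  scale <- pmax(abs(info$i_m1 * info$i_m2), info$i_m1m2^2, 1)
  ok <- is.finite(det) & det > tol * scale
  v1 <- ifelse(ok, info$i_m2 / det, NA_real_)
  v2 <- ifelse(ok, info$i_m1 / det, NA_real_)
  cv <- ifelse(ok, -info$i_m1m2 / det, NA_real_)
  v3 <- v1 + v2 + 2 * cv
  list(v_m1 = v1, v_m2 = v2, cov_m1m2 = cv, v_m3 = v3,
       se_m1 = sqrt(v1), se_m2 = sqrt(v2), se_m3 = sqrt(pmax(v3, 0)),
       n_degenerate = sum(!ok))
}

.as_dosage_matrix <- function(genotypes, panel) {
  if (inherits(genotypes, "genotype_matrix")) {
    if (!identical(genotypes$panel$snp_id, panel$snp_id)) {
      stop("genotype matrix is aligned to a different panel")
    }
    return(genotypes$dosages)
  }
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1)
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != nrow(panel)) {
    stop("genotypes have ", ncol(genotypes), " SNPs but the panel has ",
         nrow(panel))
  }
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) > 0 && !all(vals %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  genotypes
}

#' Maximum-likelihood ancestry estimates with standard errors
#'
#' Maximizes the Hardy-Weinberg genotype log-likelihood over a lattice on
#' the ancestry simplex (`m1 + m2 <= 1`, `m3 = 1 - m1 - m2`), per
#' individual, and attaches variances and standard errors from the
#' inverse information matrix evaluated at the optimum.
#'
#' The default `"coarse-to-fine"` search runs a global pass at ten times
#' the step and then the full-resolution lattice in a window of two
#' coarse steps around the coarse optimum; because the log-likelihood is
#' concave in (m1, m2) this returns the same lattice point as the
#' exhaustive `"exact-grid"` search. Ties between lattice points are
#' broken toward the smallest m1, then the smallest m2, with a warning.
#'
#' @param genotypes a `genotype_matrix`, a dosage matrix (individuals x
#'   SNPs) or a single dosage vector, aligned to `panel`.
#' @param panel a `parental_panel`.
#' @param grid_step lattice resolution (default 0.001).
#' @param mode `"coarse-to-fine"` (default) or `"exact-grid"`.
#' @param clamp hybrid-frequency clamping threshold.
#' @param compute_se compute information-matrix standard errors
#'   (default `TRUE`).
#' @param info_type `"expected"` Fisher information (default) or
#'   `"observed"`.
#' @return data frame of class `admixture_estimates`, one row per
#'   individual: `sample_id`, `n_snps_used`, `m_eu`, `m_ai`, `m_af`,
#'   `loglik`, `v_eu`, `v_ai`, `cov_eu_ai`, `v_af`, `se_eu`, `se_ai`,
#'   `se_af`. Rows with a degenerate information matrix carry `NA`
#'   variances and a warning reports their count.
#' @export
estimate_admixture <- function(genotypes, panel, grid_step = 0.001,
                               mode = c("coarse-to-fine", "exact-grid"),
                               clamp = 1e-3, compute_se = TRUE,
                               info_type = c("expected", "observed")) {
  mode <- match.arg(mode)
  info_type <- match.arg(info_type)
  stopifnot(inherits(panel, "parental_panel"))
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 0.5) {
    stop("grid_step must be in (0, 0.5]")
  }
  D <- .as_dosage_matrix(genotypes, panel)
  n_used <- rowSums(!is.na(D))
  if (any(n_used == 0)) {
    stop("individual(s) with no non-missing genotypes: ",
         paste(head(rownames(D)[n_used == 0], 3), collapse = ", "))
  }
  ids <- rownames(D)
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(nrow(D)))

  k <- as.integer(round(1 / grid_step))
  d1 <- panel$p_eu - panel$p_af
  d2 <- panel$p_ai - panel$p_af
  Dm <- D
  Dm[is.na(D)] <- 0
  W <- 2 - D
  W[is.na(D)] <- 0

  best <- if (mode == "exact-grid") {
    .search_exact(Dm, W, k, grid_step, panel$p_af, d1, d2, clamp)
  } else {
    .search_coarse_fine(Dm, W, k, grid_step, panel$p_af, d1, d2, clamp)
  }
  if (any(best$tie)) {
    warning(sum(best$tie), " individual(s) had tied lattice optima; ",
            "smallest m1 (then m2) kept")
  }
  m1 <- best$m1i * grid_step
  m2 <- best$m2i * grid_step
  m3 <- (k - best$m1i - best$m2i) * grid_step
  n_het <- rowSums(D == 1, na.rm = TRUE)
  out <- data.frame(sample_id = ids, n_snps_used = n_used,
                    m_eu = m1, m_ai = m2, m_af = m3,
                    loglik = best$val + n_het * log(2),
                    stringsAsFactors = FALSE)
  if (compute_se) {
    info <- .info_cohort(D, panel, m1, m2, clamp, info_type)
    v <- .invert_cohort(info)
    if (v$n_degenerate > 0) {
      warning(v$n_degenerate, " individual(s) with a degenerate information",
              " matrix; variances set to NA")
    }
    out$v_eu <- v$v_m1
    out$v_ai <- v$v_m2
    out$cov_eu_ai <- v$cov_m1m2
    out$v_af <- v$v_m3
    out$se_eu <- v$se_m1
    out$se_ai <- v$se_m2
    out$se_af <- v$se_m3
  }
  rownames(out) <- NULL
  class(out) <- c("admixture_estimates", "data.frame")
  out
}
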