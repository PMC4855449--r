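# Synthetic data: parental panels with controlled contrast structure and
# admixed cohorts with known truth. These emulate the structure of a real
# balanced AIM panel (three maximized-contrast sets, maximized delta
# around 0.53, off-contrast deltas below 0.3) and of multi-group admixed
# study cohorts, so every estimator property is testable without any
# external genotype resource.

#' Configuration for a synthetic AIM panel
#'
#' Defaults mirror the structure of a balanced 1300-SNP three-way AIM
#' panel: sets of 450 / 450 / 400 SNPs maximizing the EU-AI, EU-AF and
#' AI-AF contrasts, maximized delta drawn from Normal(0.53, 0.022)
#' truncated to valid values, off-contrast deltas below 0.3, and parental
#' frequencies kept off the 0/1 boundary by `freq_floor`.
#'
#' @param set_sizes named SNP counts per maximized contrast.
#' @param delta_mean,delta_sd target mean and spread of the maximized
#'   delta; `delta_mean` must be at least 0.5 (the maximization
#'   threshold).
#' @param delta_off_max off-contrast delta ceiling, below 0.5.
#' @param freq_floor minimum distance of any parental frequency from 0
#'   and 1.
#' @param spacing base-pair distance between adjacent synthetic SNPs
#'   (default 1 Mb, comfortably above the 500 kb independence rule).
#' @param n_chrom number of pseudo-chromosomes markers are spread over.
#' @param id_prefix prefix of generated SNP ids (lets two independent
#'   panels carry disjoint ids).
#' @param seed RNG seed for [simulate_panel()]; `NULL` uses the current
#'   RNG state.
#' @return validated list of class `panel_sim_config`.
#' @export
panel_sim_config <- function(set_sizes = c("EU-AI" = 450, "EU-AF" = 450,
                                           "AI-AF" = 400),
                             delta_mean = 0.53, delta_sd = 0.022,
                             delta_off_max = 0.3, freq_floor = 0.01,
                             spacing = 1e6, n_chrom = 22,
                             id_prefix = "sim", seed = NULL) {
  if (!all(names(contrast_pairs()) %in% names(set_sizes))) {
    stop("set_sizes must name all three contrasts: EU-AI, EU-AF, AI-AF")
  }
  if (any(set_sizes <= 0)) stop("set sizes must be positive")
  if (delta_mean < 0.5) stop("delta_mean must be >= 0.5 (the maximization rule)")
  if (delta_off_max >= 0.5) stop("delta_off_max must be < 0.5")
  if (freq_floor < 0 || freq_floor >= 0.5) stop("freq_floor must be in [0, 0.5)")
  if (delta_mean >= 2 * delta_off_max) {
    stop("infeasible config: a maximized delta of ", delta_mean,
         " leaves no room for both off-contrast deltas below ", delta_off_max)
  }
  structure(list(set_sizes = set_sizes, delta_mean = delta_mean,
                 delta_sd = delta_sd, delta_off_max = delta_off_max,
                 freq_floor = freq_floor, spacing = spacing,
                 n_chrom = n_chrom, id_prefix = id_prefix, seed = seed),
            class = "panel_sim_config")
}

# Truncated-normal draws of the maximized delta, rejected into
# [0.5, 2 * delta_off_max) so the third population can sit within the
# off-contrast bound of both maximized populations. Aborts if the
# acceptance rate collapses (infeasible configuration).
.draw_deltas <- function(n, cfg) {
  lo <- 0.5
  hi <- min(1, 2 * cfg$delta_off_max) - 1e-9
  out <- numeric(0)
  tried <- 0
  while (length(out) < n) {
    m <- max(2L * n, 1000L)
    draw <- stats::rnorm(m, cfg$delta_mean, cfg$delta_sd)
    out <- c(out, draw[draw >= lo & draw < hi])
    tried <- tried + m
    if (tried >= 1e6 && length(out) / tried < 0.001) {
      stop("infeasible panel configuration: delta rejection rate >= 99.9%")
    }
  }
  out[seq_len(n)]
}

# Unambiguous allele pairs (no A/T, no C/G).
.allele_pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"),
                       c("C", "A"), c("G", "A"), c("T", "C"), c("T", "G"))

#' Simulate a balanced parental AIM panel
#'
#' For each SNP of a maximized set, the two contrast populations are
#' placed `delta` apart (delta from the truncated normal of the config,
#' side chosen at random, both frequencies within
#' `[freq_floor, 1 - freq_floor]`) and the third population is drawn
#' uniformly inside the interval where both of its deltas stay below
#' `delta_off_max`. The three sets are proportionally interleaved and
#' laid out round-robin over the pseudo-chromosomes with uniform spacing,
#' so within-set distances always exceed the 500 kb independence rule.
#' Deterministic under the config seed.
#'
#' @param config a [panel_sim_config()].
#' @return a `parental_panel` with `set_label` set.
#' @export
simulate_panel <- function(config = panel_sim_config()) {
  stopifnot(inherits(config, "panel_sim_config"))
  if (!is.null(config$seed)) withr::local_seed(config$seed)
  pairs <- contrast_pairs()
  sets <- names(pairs)
  per_set <- lapply(sets, function(s) {
    n <- config$set_sizes[[s]]
    delta <- .draw_deltas(n, config)
    lo_bound <- config$freq_floor
    hi_bound <- 1 - config$freq_floor
    low <- stats::runif(n, lo_bound, hi_bound - delta)
    high <- low + delta
    flip <- stats::runif(n) < 0.5
    a <- ifelse(flip, high, low)   # first population of the pair
    b <- ifelse(flip, low, high)   # second population of the pair
    z_lo <- pmax(pmax(a, b) - config$delta_off_max, lo_bound)
    z_hi <- pmin(pmin(a, b) + config$delta_off_max, hi_bound)
    z <- stats::runif(n, z_lo, z_hi)
    freqs <- matrix(NA_real_, nrow = n, ncol = 3,
                    dimnames = list(NULL, c("p_eu", "p_ai", "p_af")))
    freqs[, pairs[[s]][1]] <- a
    freqs[, pairs[[s]][2]] <- b
    freqs[, setdiff(colnames(freqs), pairs[[s]])] <- z
    data.frame(freqs, set_label = s, stringsAsFactors = FALSE)
  })

  # Proportional interleave of the sets, then round-robin chromosomes.
  keys <- unlist(lapply(per_set, function(df) {
    (seq_len(nrow(df)) - stats::runif(nrow(df))) / nrow(df)
  }))
  x <- do.call(rbind, per_set)[order(keys), , drop = FALSE]
  G <- nrow(x)
  x$chrom <- as.character(((seq_len(G) - 1L) %% config$n_chrom) + 1L)
  x$pos <- config$spacing * (1L + (seq_len(G) - 1L) %/% config$n_chrom)
  x$snp_id <- sprintf("%s%05d", config$id_prefix, seq_len(G))
  ap <- .allele_pairs[sample.int(nrow(.allele_pairs), G, replace = TRUE), ,
                      drop = FALSE]
  x$allele1 <- ap[, 1]
  x$allele2 <- ap[, 2]
  as_parental_panel(x)
}

#' FIND-like cohort truth: group-structured ancestry proportions
#'
#' Draws per-individual true ancestry vectors from Dirichlet
#' distributions centered on the mean admixture of four self-identified
#' heritage groups of a multi-ethnic nephropathy study: European
#' Americans (EU 0.961, AI 0.014, AF 0.025), American Indians (0.045,
#' 0.945, 0.010), Mexican Americans (0.476, 0.447, 0.077) and African
#' Americans (0.149, 0.021, 0.830).
#'
#' @param n_per_group individuals per group: a single count or a vector
#'   named by group.
#' @param group_means data frame with columns `group`, `mu_eu`, `mu_ai`,
#'   `mu_af` (rows summing to 1); defaults to the four groups above.
#' @param concentration Dirichlet concentration (sum of shape
#'   parameters); larger is tighter around the group mean. `Inf` returns
#'   the group mean exactly. Default 10, giving within-group spreads of
#'   the order seen in such cohorts (SD roughly 0.05-0.15).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return data frame of class `cohort_truth`: `sample_id`, `group`,
#'   `mu_eu`, `mu_ai`, `mu_af`.
#' @export
find_like_truth <- function(n_per_group = 100,
                            group_means = NULL,
                            concentration = 10, seed = NULL) {
  if (is.null(group_means)) {
    group_means <- data.frame(
      group = c("European American", "American Indian",
                "Mexican American", "African American"),
      mu_eu = c(0.961, 0.045, 0.476, 0.149),
      mu_ai = c(0.014, 0.945, 0.447, 0.021),
      mu_af = c(0.025, 0.010, 0.077, 0.830),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("group", "mu_eu", "mu_ai", "mu_af") %in% names(group_means)))
  sums <- group_means$mu_eu + group_means$mu_ai + group_means$mu_af
  if (any(abs(sums - 1) > 1e-6)) stop("group means must sum to 1")
  if (length(concentration) != 1 || concentration <= 0) {
    stop("concentration must be a single positive number")
  }
  if (length(n_per_group) == 1) {
    n_per_group <- stats::setNames(rep(n_per_group, nrow(group_means)),
                                   group_means$group)
  }
  if (any(n_per_group <= 0)) stop("n_per_group must be positive")
  if (!is.null(seed)) withr::local_seed(seed)

  rows <- lapply(seq_len(nrow(group_means)), function(i) {
    g <- group_means$group[i]
    n <- n_per_group[[g]]
    mu <- c(group_means$mu_eu[i], group_means$mu_ai[i], group_means$mu_af[i])
    if (is.infinite(concentration)) {
      draws <- matrix(mu, nrow = n, ncol = 3, byrow = TRUE)
    } else {
      shape <- concentration * mu
      draws <- matrix(stats::rgamma(3 * n, shape = rep(shape, each = n)),
                      nrow = n)
      tot <- rowSums(draws)
      tot[tot == 0] <- 1
      draws <- draws / tot
    }
    data.frame(group = g, mu_eu = draws[, 1], mu_ai = draws[, 2],
               mu_af = draws[, 3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(sample_id = sprintf("ind%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cohort_truth", "data.frame")
  out
}

#' Simulate genotypes for a cohort with known ancestry
#'
#' Each dosage is Binomial(2, P) with P the individual's hybrid allele-1
#' frequency at the SNP ([hybrid_freq()]); entries are then masked
#' missing at `missing_rate`. Deterministic under `seed`.
#'
#' @param panel a `parental_panel`.
#' @param truth a `cohort_truth` (or any data frame with `mu_eu`,
#'   `mu_ai`, `mu_af` rows on the simplex).
#' @param missing_rate proportion of genotypes masked missing, in
#'   \[0, 0.5\].
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return a `genotype_matrix`.
#' @export
simulate_cohort <- function(panel, truth, missing_rate = 0, seed = NULL) {
  stopifnot(inherits(panel, "parental_panel"))
  stopifnot(all(c("mu_eu", "mu_ai", "mu_af") %in% names(truth)))
  if (nrow(truth) < 1) stop("truth must have at least one individual")
  if (missing_rate < 0 || missing_rate > 0.5) {
    stop("missing_rate must be in [0, 0.5]")
  }
  bad <- truth$mu_eu < 0 | truth$mu_ai < 0 | truth$mu_af < 0 |
    abs(truth$mu_eu + truth$mu_ai + truth$mu_af - 1) > 1e-6
  if (any(bad)) {
    stop("truth row ", which(bad)[1], " is off the ancestry simplex")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  N <- nrow(truth)
  d1 <- panel$p_eu - panel$p_af
  d2 <- panel$p_ai - panel$p_af
  P <- outer(truth$mu_eu, d1) + outer(truth$mu_ai, d2) +
    rep(panel$p_af, each = N)
  P <- pmin(pmax(P, 0), 1)
  d <- matrix(stats::rbinom(length(P), 2L, P), nrow = N)
  if (missing_rate > 0) {
    d[stats::runif(length(d)) < missing_rate] <- NA_integer_
  }
  ids <- if ("sample_id" %in% names(truth)) truth$sample_id else
    sprintf("ind%05d", seq_len(N))
  rownames(d) <- ids
  genotype_matrix(d, panel, ids)
}
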