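# Desk-scale experiment harnesses: how the standard error of ancestry
# estimates shrinks as markers accumulate, how unbalanced panels fail on
# pure-ancestry cohorts, and how concordant two disjoint balanced panels
# are on the same individuals.

.mean_se_by_group <- function(est, groups) {
  # Equal group weights: average SEs over individuals within a group,
  # over the three components, then over groups.
  per_group <- tapply(seq_len(nrow(est)), groups, function(i) {
    c(eu = mean(est$se_eu[i], na.rm = TRUE),
      ai = mean(est$se_ai[i], na.rm = TRUE),
      af = mean(est$se_af[i], na.rm = TRUE))
  })
  m <- do.call(rbind, per_group)
  c(mean_se = mean(m), mean_se_eu = mean(m[, "eu"]),
    mean_se_ai = mean(m[, "ai"]), mean_se_af = mean(m[, "af"]))
}

#' Standard error versus number of markers
#'
#' Simulates a cohort from `truth` on `panel`, orders the SNPs, and for
#' each requested prefix length re-estimates every individual on that
#' prefix, recording the mean information-matrix standard error (averaged
#' over individuals within each group, over the three ancestry
#' components, then over groups with equal weight).
#'
#' The default ordering randomly interleaves the three maximized sets in
#' proportion, so every prefix is itself approximately balanced; a real
#' panel's chromosome-and-position order interleaves its sets in much the
#' same way, and `"chromosome-position"` ordering is available for that
#' convention. An unbalanced panel triggers a warning but the curve is
#' still computed, since the failure mode is itself of interest.
#'
#' @param truth a `cohort_truth` (see [find_like_truth()]).
#' @param panel a `parental_panel`, normally balanced and carrying
#'   `set_label`.
#' @param snp_counts increasing prefix lengths to evaluate; default every
#'   10th count up to the panel size.
#' @param ordering `"randomized-interleaved"` (default) or
#'   `"chromosome-position"`.
#' @param missing_rate genotype missingness passed to
#'   [simulate_cohort()].
#' @param grid_step,clamp estimator settings (see
#'   [estimate_admixture()]).
#' @param seed RNG seed for the cohort simulation and ordering.
#' @return data frame of class `se_curve`: `n_snps`, `mean_se`,
#'   `mean_se_eu`, `mean_se_ai`, `mean_se_af`, with the ordering stored
#'   in attribute `"ordering"`.
#' @export
se_curve <- function(truth, panel, snp_counts = NULL,
                     ordering = c("randomized-interleaved",
                                  "chromosome-position"),
                     missing_rate = 0, grid_step = 0.001, clamp = 1e-3,
                     seed = NULL) {
  ordering <- match.arg(ordering)
  stopifnot(inherits(panel, "parental_panel"))
  G <- nrow(panel)
  if (is.null(snp_counts)) snp_counts <- seq(10, G, by = 10)
  snp_counts <- sort(unique(as.integer(snp_counts)))
  if (any(snp_counts < 1 | snp_counts > G)) {
    stop("snp_counts must lie in 1..", G)
  }
  if ("set_label" %in% names(panel)) {
    rep_bal <- balance_report(panel)
    if (!rep_bal$balanced) {
      warning("panel is unbalanced; the SE curve will reflect the imbalance")
    }
  }
  if (!is.null(seed)) withr::local_seed(seed)

  perm <- if (ordering == "chromosome-position") {
    seq_len(G)  # panels are stored in chromosome-and-position order
  } else if ("set_label" %in% names(panel)) {
    keys <- numeric(G)
    for (s in unique(panel$set_label)) {
      i <- which(panel$set_label == s)
      keys[i] <- (sample.int(length(i)) - stats::runif(length(i))) / length(i)
    }
    order(keys)
  } else {
    sample.int(G)
  }

  gm <- simulate_cohort(panel, truth, missing_rate = missing_rate)
  D <- gm$dosages[, perm, drop = FALSE]
  panel_perm <- as.data.frame(panel)[perm, , drop = FALSE]
  groups <- if ("group" %in% names(truth)) truth$group else
    rep("all", nrow(truth))

  rows <- lapply(snp_counts, function(ct) {
    sub_panel <- as_parental_panel(panel_perm[seq_len(ct), , drop = FALSE])
    sub_d <- D[, seq_len(ct), drop = FALSE]
    # as_parental_panel re-sorts by position; realign dosage columns
    sub_d <- sub_d[, match(sub_panel$snp_id, colnames(sub_d)), drop = FALSE]
    est <- suppressWarnings(
      estimate_admixture(sub_d, sub_panel, grid_step = grid_step,
                         clamp = clamp))
    c(n_snps = ct, .mean_se_by_group(est, groups))
  })
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "ordering") <- ordering
  class(out) <- c("se_curve", "data.frame")
  out
}

#' Vertex-recovery experiment: balanced versus single-set estimation
#'
#' Simulates pure-ancestry ("vertex") cohorts for each of the three
#' ancestral populations and estimates each cohort four times: with each
#' maximized contrast set alone and with the full panel. A balanced
#' full panel recovers each cohort's own component near 1.0; a single
#' maximized set that does not involve the cohort's ancestry returns
#' biased means with much larger spread.
#'
#' @param panel a `parental_panel` with `set_label`.
#' @param n_per_population vertex-cohort size (default 100).
#' @param grid_step,clamp estimator settings.
#' @param seed RNG seed.
#' @return data frame of class `vertex_recovery`: one row per
#'   (estimation SNP set x source population), with mean and SD of each
#'   estimated component.
#' @export
vertex_recovery_experiment <- function(panel, n_per_population = 100,
                                       grid_step = 0.001, clamp = 1e-3,
                                       seed = NULL) {
  stopifnot(inherits(panel, "parental_panel"))
  if (!"set_label" %in% names(panel)) {
    stop("panel must carry set_label (three maximized sets)")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  vertices <- list(EU = c(1, 0, 0), AI = c(0, 1, 0), AF = c(0, 0, 1))
  set_names <- names(contrast_pairs())

  rows <- list()
  for (src in names(vertices)) {
    mu <- vertices[[src]]
    truth <- data.frame(mu_eu = rep(mu[1], n_per_population),
                        mu_ai = mu[2], mu_af = mu[3])
    gm <- simulate_cohort(panel, truth)
    for (est_set in c(set_names, "all")) {
      cols <- if (est_set == "all") seq_len(nrow(panel)) else
        which(panel$set_label == est_set)
      sub_panel <- as_parental_panel(as.data.frame(panel)[cols, , drop = FALSE])
      sub_d <- gm$dosages[, cols, drop = FALSE]
      sub_d <- sub_d[, match(sub_panel$snp_id, colnames(sub_d)), drop = FALSE]
      est <- suppressWarnings(
        estimate_admixture(sub_d, sub_panel, grid_step = grid_step,
                           clamp = clamp, compute_se = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        estimation_set = est_set, source = src, n = n_per_population,
        mean_eu = mean(est$m_eu), sd_eu = stats::sd(est$m_eu),
        mean_ai = mean(est$m_ai), sd_ai = stats::sd(est$m_ai),
        mean_af = mean(est$m_af), sd_af = stats::sd(est$m_af),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("vertex_recovery", "data.frame")
  out
}

#' Replicate-panel concordance
#'
#' Estimates every individual of a cohort twice, with two disjoint
#' balanced panels, and summarizes the per-individual differences of each
#' ancestry component. With both panels balanced the differences center
#' tightly on zero, which is the practical check that a panel's estimates
#' are reproducible rather than panel-specific.
#'
#' @param panel_a,panel_b two `parental_panel`s sharing no SNP ids.
#' @param truth a `cohort_truth`.
#' @param grid_step,clamp estimator settings.
#' @param seed RNG seed (genotypes on the two panels are independent
#'   draws given the truth).
#' @return data frame with one row per component (`eu`, `ai`, `af`):
#'   `mean_diff`, `median_diff`, `sd_diff`; per-individual differences in
#'   attribute `"differences"`.
#' @export
replicate_concordance_experiment <- function(panel_a, panel_b, truth,
                                             grid_step = 0.001, clamp = 1e-3,
                                             seed = NULL) {
  stopifnot(inherits(panel_a, "parental_panel"),
            inherits(panel_b, "parental_panel"))
  if (length(intersect(panel_a$snp_id, panel_b$snp_id)) > 0) {
    stop("panels share SNP ids; replicate panels must be disjoint")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  gm_a <- simulate_cohort(panel_a, truth)
  gm_b <- simulate_cohort(panel_b, truth)
  est_a <- estimate_admixture(gm_a, panel_a, grid_step = grid_step,
                              clamp = clamp, compute_se = FALSE)
  est_b <- estimate_admixture(gm_b, panel_b, grid_step = grid_step,
                              clamp = clamp, compute_se = FALSE)
  diffs <- data.frame(eu = est_a$m_eu - est_b$m_eu,
                      ai = est_a$m_ai - est_b$m_ai,
                      af = est_a$m_af - est_b$m_af)
  out <- data.frame(component = names(diffs),
                    mean_diff = vapply(diffs, mean, numeric(1)),
                    median_diff = vapply(diffs, stats::median, numeric(1)),
                    sd_diff = vapply(diffs, stats::sd, numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "differences") <- diffs
  out
}
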