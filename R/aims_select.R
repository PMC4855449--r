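# Marker-informativeness statistics and construction of balanced
# ancestry-informative-marker (AIM) panels.
#
# A three-ancestry model has three pairwise information contrasts
# (EU-AI, EU-AF, AI-AF). Each AIM is chosen to maximize one contrast
# (absolute frequency difference delta >= 0.5) while staying weak in the
# other two (delta < 0.3); the three resulting sets are then balanced so
# that no contrast dominates the total information. Unbalanced panels
# produce biased ancestry estimates with inflated error.

#' Informativeness for assignment (In) of a set of SNPs
#'
#' The entropy-based assignment-information statistic summed over SNPs:
#' per SNP and allele, `-pbar log pbar + mean_i(p_i log p_i)` where
#' `pbar` is the unweighted mean frequency over the K populations.
#' In `"both-alleles"` mode (the statistic's standard biallelic form) the
#' term is evaluated for allele 1 and allele 2 and added, which makes
#' `In >= 0` with equality iff all populations share identical
#' frequencies; `"allele1-only"` evaluates the printed single-allele sum.
#' Natural logarithms throughout; `0 log 0 = 0`.
#'
#' @param freqs numeric matrix (or data frame) of allele-1 frequencies,
#'   SNPs in rows, one column per population (K >= 2).
#' @param allele_mode `"both-alleles"` (default) or `"allele1-only"`.
#' @return the In value (a single number; additive over disjoint SNP sets).
#' @export
informativeness_in <- function(freqs,
                               allele_mode = c("both-alleles", "allele1-only")) {
  allele_mode <- match.arg(allele_mode)
  freqs <- as.matrix(freqs)
  if (nrow(freqs) == 0) stop("empty SNP set: In is undefined")
  if (ncol(freqs) < 2) stop("In needs at least K = 2 populations")
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must lie in [0, 1]")
  term <- function(p) {
    pbar <- rowMeans(p)
    -xlogx(pbar) + rowMeans(xlogx(p))
  }
  total <- term(freqs)
  if (allele_mode == "both-alleles") total <- total + term(1 - freqs)
  sum(total)
}

#' Weir-Cockerham theta (Fst) between two population samples
#'
#' The Weir & Cockerham (1984) variance-components estimator of
#' per-locus differentiation for two populations, computed from genotype
#' counts. Loci monomorphic in both samples have undefined theta and are
#' reported as `NA` (and excluded from the summaries, with a count).
#'
#' @param counts_pop1,counts_pop2 data frames, one row per SNP, with
#'   columns `n` (individuals genotyped), `het` (heterozygote count) and
#'   `allele1` (allele-1 copy count, 0..2n).
#' @return list with `theta` (per-SNP estimates), `mean_theta` and
#'   `sd_theta` (mean of per-SNP theta, the per-locus summary),
#'   `ratio_of_sums` (sum(a) / sum(a + b + c), the multi-locus
#'   estimator), and `n_undefined`.
#' @export
weir_cockerham_fst <- function(counts_pop1, counts_pop2) {
  for (cc in list(counts_pop1, counts_pop2)) {
    if (!all(c("n", "het", "allele1") %in% names(cc))) {
      stop("genotype counts need columns 'n', 'het' and 'allele1'")
    }
    if (any(cc$n <= 0)) stop("each sample must be non-empty at every SNP")
  }
  if (nrow(counts_pop1) != nrow(counts_pop2)) {
    stop("the two count tables must cover the same SNPs")
  }
  n1 <- counts_pop1$n
  n2 <- counts_pop2$n
  p1 <- counts_pop1$allele1 / (2 * n1)
  p2 <- counts_pop2$allele1 / (2 * n2)
  h1 <- counts_pop1$het / n1
  h2 <- counts_pop2$het / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  denom <- a + b + c_
  theta <- ifelse(abs(denom) < .Machine$double.eps * 8, NA_real_, a / denom)
  ok <- !is.na(theta)
  list(theta = theta,
       mean_theta = mean(theta[ok]),
       sd_theta = stats::sd(theta[ok]),
       ratio_of_sums = sum(a[ok]) / sum(denom[ok]),
       n_undefined = sum(!ok))
}

#' Per-SNP contrast classification
#'
#' Computes the three absolute allele-frequency differences (delta) per
#' SNP and labels the SNP with the contrast it maximizes: a contrast is
#' maximized when its delta is at least `delta_max` while both other
#' deltas are below `delta_off`. At most one contrast can satisfy the
#' rule (with the default 0.5 / 0.3 thresholds), so labels are exclusive;
#' SNPs meeting it for none are labelled `"none"`.
#'
#' @param panel a `parental_panel`.
#' @param delta_max maximized-contrast threshold (default 0.5).
#' @param delta_off off-contrast ceiling (default 0.3).
#' @return data frame with `snp_id`, `delta_eu_ai`, `delta_eu_af`,
#'   `delta_ai_af`, `maximized_contrast`.
#' @export
classify_contrasts <- function(panel, delta_max = 0.5, delta_off = 0.3) {
  stopifnot(inherits(panel, "parental_panel"))
  d <- data.frame(snp_id = panel$snp_id,
                  delta_eu_ai = abs(panel$p_eu - panel$p_ai),
                  delta_eu_af = abs(panel$p_eu - panel$p_af),
                  delta_ai_af = abs(panel$p_ai - panel$p_af),
                  stringsAsFactors = FALSE)
  dm <- as.matrix(d[, c("delta_eu_ai", "delta_eu_af", "delta_ai_af")])
  labels <- c("EU-AI", "EU-AF", "AI-AF")
  maxed <- rep("none", nrow(d))
  for (j in 1:3) {
    others <- dm[, -j, drop = FALSE]
    hit <- dm[, j] >= delta_max & others[, 1] < delta_off & others[, 2] < delta_off
    maxed[hit] <- labels[j]
  }
  d$maximized_contrast <- maxed
  d
}

#' Select a balanced AIM panel from a candidate table
#'
#' The selection pipeline: (1) drop strand-ambiguous A/T and C/G allele
#' pairs; (2) drop SNPs whose replicate-typing discordance exceeds
#' `replicate_max` (when the column is present); (3) classify each
#' survivor by maximized contrast ([classify_contrasts()]) and keep those
#' maximizing one; (4) within each contrast set, select greedily in
#' descending maximized-delta order subject to a minimum distance of
#' `spacing` base pairs from already-selected SNPs of the same set on the
#' same chromosome (an LD proxy); (5) trim each set to `target_sizes`
#' when given (lowest-delta SNPs dropped), otherwise trim from the
#' lowest-delta end of the most informative set until the per-set In
#' values agree within `in_tolerance`.
#'
#' @param candidates a `parental_panel` of candidate SNPs, optionally with
#'   a `replicate_discordance` column.
#' @param delta_max,delta_off classification thresholds (0.5 / 0.3).
#' @param spacing minimum within-set distance between syntenic SNPs in
#'   base pairs (default 500000).
#' @param replicate_max replicate-discordance ceiling (default 0.032).
#' @param target_sizes optional named vector of set sizes, e.g.
#'   `c("EU-AI" = 450, "EU-AF" = 450, "AI-AF" = 400)`.
#' @param in_tolerance relative per-set In tolerance used when no target
#'   sizes are given.
#' @return list with `panel` (the selected `parental_panel` carrying
#'   `set_label`) and `report` (its [balance_report()]).
#' @export
select_aims <- function(candidates, delta_max = 0.5, delta_off = 0.3,
                        spacing = 5e5, replicate_max = 0.032,
                        target_sizes = NULL, in_tolerance = 0.02) {
  stopifnot(inherits(candidates, "parental_panel"))
  x <- as.data.frame(candidates)

  ambiguous <- (x$allele1 == "A" & x$allele2 == "T") |
    (x$allele1 == "T" & x$allele2 == "A") |
    (x$allele1 == "C" & x$allele2 == "G") |
    (x$allele1 == "G" & x$allele2 == "C")
  x <- x[!ambiguous, , drop = FALSE]

  if ("replicate_discordance" %in% names(x)) {
    keep <- is.na(x$replicate_discordance) |
      x$replicate_discordance <= replicate_max
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) == 0) stop("no candidate survives the ambiguity/replicate filters")

  cls <- classify_contrasts(as_parental_panel(x), delta_max, delta_off)
  x$maximized_contrast <- cls$maximized_contrast[match(x$snp_id, cls$snp_id)]
  dmat <- cls[match(x$snp_id, cls$snp_id),
              c("delta_eu_ai", "delta_eu_af", "delta_ai_af")]
  x$max_delta <- ifelse(x$maximized_contrast == "EU-AI", dmat$delta_eu_ai,
                 ifelse(x$maximized_contrast == "EU-AF", dmat$delta_eu_af,
                        dmat$delta_ai_af))
  x <- x[x$maximized_contrast != "none", , drop = FALSE]

  sets <- names(contrast_pairs())
  selected <- list()
  for (s in sets) {
    cand <- x[x$maximized_contrast == s, , drop = FALSE]
    if (nrow(cand) == 0) {
      stop("no candidate maximizes the ", s,
           " contrast: a balanced panel cannot be built")
    }
    cand <- cand[order(-cand$max_delta, chrom_rank(cand$chrom), cand$pos), ,
                 drop = FALSE]
    keep <- integer(0)
    for (i in seq_len(nrow(cand))) {
      same_chr <- keep[cand$chrom[keep] == cand$chrom[i]]
      if (length(same_chr) == 0 ||
          all(abs(cand$pos[same_chr] - cand$pos[i]) >= spacing)) {
        keep <- c(keep, i)
      }
    }
    sel <- cand[keep, , drop = FALSE]
    if (!is.null(target_sizes) && s %in% names(target_sizes)) {
      sel <- utils::head(sel, target_sizes[[s]])
    }
    sel$set_label <- s
    selected[[s]] <- sel
  }

  if (is.null(target_sizes)) {
    # Per-set In over the maximized pair; trim the strongest set's weakest
    # SNP until the three agree. In is additive over SNPs, so each removal
    # subtracts that SNP's own contribution.
    pairs <- contrast_pairs()
    in_of <- function(df, s) {
      informativeness_in(df[, pairs[[s]], drop = FALSE])
    }
    ins <- vapply(sets, function(s) in_of(selected[[s]], s), numeric(1))
    repeat {
      if (max(ins) / min(ins) <= 1 + in_tolerance) break
      s <- sets[which.max(ins)]
      df <- selected[[s]]
      if (nrow(df) <= 1) break
      drop_i <- which.min(df$max_delta)
      ins[s] <- ins[s] -
        informativeness_in(df[drop_i, pairs[[s]], drop = FALSE])
      selected[[s]] <- df[-drop_i, , drop = FALSE]
    }
  }

  out <- do.call(rbind, selected)
  out$max_delta <- NULL
  out$maximized_contrast <- NULL
  panel <- as_parental_panel(out)
  list(panel = panel, report = balance_report(panel))
}

#' Balance audit of an AIM panel
#'
#' Summarizes the information a panel carries in each of the three
#' pairwise contrasts: per maximized set (when `set_label` is present),
#' the SNP count, the In of the set over its two contrast populations,
#' and the mean and SD of the maximized delta; and, over all SNPs, the In
#' and mean delta of each contrast. The panel is judged balanced when the
#' largest and smallest of the three all-SNP In values differ by at most
#' `in_tolerance` (relative). Mean per-SNP Weir-Cockerham Fst per
#' contrast is added when genotype counts are supplied.
#'
#' @param panel a `parental_panel`, normally carrying `set_label`.
#' @param genotype_counts optional named list with elements `eu`, `ai`,
#'   `af`, each a data frame of genotype counts (`n`, `het`, `allele1`)
#'   aligned to panel rows, enabling the Fst summaries.
#' @param in_tolerance relative tolerance for the balance verdict
#'   (default 0.10).
#' @param allele_mode In allele mode, passed to [informativeness_in()].
#' @return object of class `panel_balance_report`: list with `per_set`,
#'   `per_contrast`, `balanced`, `in_tolerance`.
#' @export
balance_report <- function(panel, genotype_counts = NULL,
                           in_tolerance = 0.10,
                           allele_mode = "both-alleles") {
  stopifnot(inherits(panel, "parental_panel"))
  pairs <- contrast_pairs()

  per_set <- NULL
  if ("set_label" %in% names(panel) && !all(is.na(panel$set_label))) {
    rows <- lapply(names(pairs), function(s) {
      sub <- panel[!is.na(panel$set_label) & panel$set_label == s, ,
                   drop = FALSE]
      if (nrow(sub) == 0) return(NULL)
      p <- as.matrix(sub[, pairs[[s]], drop = FALSE])
      deltas <- abs(p[, 1] - p[, 2])
      data.frame(set_label = s, n_snps = nrow(sub),
                 in_stat = informativeness_in(p, allele_mode),
                 mean_delta = mean(deltas), sd_delta = stats::sd(deltas),
                 stringsAsFactors = FALSE)
    })
    per_set <- do.call(rbind, rows)
  }

  per_contrast <- do.call(rbind, lapply(names(pairs), function(s) {
    p <- as.matrix(panel[, pairs[[s]], drop = FALSE])
    deltas <- abs(p[, 1] - p[, 2])
    data.frame(contrast = s, n_snps = nrow(panel),
               in_stat = informativeness_in(p, allele_mode),
               mean_delta = mean(deltas), sd_delta = stats::sd(deltas),
               stringsAsFactors = FALSE)
  }))

  if (!is.null(genotype_counts)) {
    pops <- list("EU-AI" = c("eu", "ai"), "EU-AF" = c("eu", "af"),
                 "AI-AF" = c("ai", "af"))
    per_contrast$mean_fst <- vapply(per_contrast$contrast, function(s) {
      weir_cockerham_fst(genotype_counts[[pops[[s]][1]]],
                         genotype_counts[[pops[[s]][2]]])$mean_theta
    }, numeric(1))
  }

  balanced <- max(per_contrast$in_stat) / min(per_contrast$in_stat) <=
    1 + in_tolerance
  structure(list(per_set = per_set, per_contrast = per_contrast,
                 balanced = balanced, in_tolerance = in_tolerance),
            class = "panel_balance_report")
}

#' @export
print.panel_balance_report <- function(x, ...) {
  cat("AIM panel balance report\n")
  if (!is.null(x$per_set)) {
    cat("\nPer maximized set:\n")
    print(x$per_set, row.names = FALSE, digits = 4)
  }
  cat("\nPer contrast, all SNPs:\n")
  print(x$per_contrast, row.names = FALSE, digits = 4)
  cat("\nBalanced (all-SNP In within ", 100 * x$in_tolerance, "%): ",
      x$balanced, "\n", sep = "")
  invisible(x)
}
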