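test_that("informativeness for assignment has its closed-form anchors", {
  # identical frequencies carry no assignment information
  expect_equal(informativeness_in(cbind(c(.3, .7), c(.3, .7))), 0)
  # a reciprocally fixed biallelic SNP carries ln 2 (K = 2, both alleles)
  expect_equal(informativeness_in(cbind(1, 0)), log(2))
  # direct evaluation of the formula at p = (0.9, 0.1)
  expect_equal(informativeness_in(cbind(0.9, 0.1)), 0.36806421, tolerance = 1e-7)
  # the printed single-allele form is half of the symmetric case's value
  expect_equal(informativeness_in(cbind(0.9, 0.1), "allele1-only"),
               0.36806421 / 2, tolerance = 1e-7)
  expect_error(informativeness_in(matrix(numeric(0), 0, 2)), "empty")
})

test_that("In is additive over disjoint SNP sets and zero only at identical frequencies", {
  withr::local_seed(60)
  a <- cbind(runif(10), runif(10), runif(10))
  b <- cbind(runif(6), runif(6), runif(6))
  expect_equal(informativeness_in(rbind(a, b)),
               informativeness_in(a) + informativeness_in(b))
  expect_gt(informativeness_in(a), 0)
})

test_that("Weir-Cockerham theta hits its boundary anchors and a variance-component oracle", {
  fixed1 <- data.frame(n = 100, het = 0, allele1 = 200)
  fixed0 <- data.frame(n = 100, het = 0, allele1 = 0)
  expect_equal(weir_cockerham_fst(fixed1, fixed0)$theta, 1)

  # two samples from one population: theta near 0 (possibly slightly negative)
  withr::local_seed(61)
  p <- runif(200, 0.2, 0.8)
  draw <- function(p, n) {
    g <- vapply(p, function(pp) {
      geno <- rbinom(n, 2, pp)
      c(het = sum(geno == 1), allele1 = sum(geno))
    }, numeric(2))
    data.frame(n = n, het = g["het", ], allele1 = g["allele1", ])
  }
  wc <- weir_cockerham_fst(draw(p, 500), draw(p, 500))
  expect_lt(abs(wc$mean_theta), 0.01)

  # small-count instance against an independent transcription of the
  # 1984 variance components
  c1 <- data.frame(n = c(20, 15), het = c(8, 3), allele1 = c(22, 5))
  c2 <- data.frame(n = c(25, 30), het = c(10, 12), allele1 = c(12, 40))
  oracle <- function(n1, h1c, x1, n2, h2c, x2) {
    r <- 2; p1 <- x1 / (2 * n1); p2 <- x2 / (2 * n2)
    h1 <- h1c / n1; h2 <- h2c / n2
    nbar <- mean(c(n1, n2))
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a / (a + b + cc)
  }
  exp_theta <- c(oracle(20, 8, 22, 25, 10, 12), oracle(15, 3, 5, 30, 12, 40))
  expect_equal(weir_cockerham_fst(c1, c2)$theta, exp_theta, tolerance = 1e-10)

  # monomorphic in both samples: undefined, counted
  mono <- data.frame(n = 50, het = 0, allele1 = 100)
  wc2 <- weir_cockerham_fst(mono, mono)
  expect_true(is.na(wc2$theta))
  expect_equal(wc2$n_undefined, 1)
})

test_that("contrast classification applies the maximized/off-contrast rule exclusively", {
  p <- as_parental_panel(data.frame(
    snp_id = c("a", "b", "c"), chrom = "1", pos = c(1e6, 2e6, 3e6),
    allele1 = "A", allele2 = "G",
    p_eu = c(0.90, 0.5, 0.9), p_ai = c(0.37, 0.5, 0.1),
    p_af = c(0.62, 0.5, 0.5)))
  cls <- classify_contrasts(p)
  expect_equal(cls$delta_eu_ai, c(0.53, 0, 0.8))
  expect_equal(cls$delta_eu_af, c(0.28, 0, 0.4))
  expect_equal(cls$delta_ai_af, c(0.25, 0, 0.4))
  # a: EU-AI maximized; b: no information; c: off-contrast deltas too large
  expect_equal(cls$maximized_contrast, c("EU-AI", "none", "none"))

  # exclusivity on a random panel: the rule never matches two contrasts,
  # and the label is exactly the contrast that satisfies it
  rp <- random_panel(200, seed = 62)
  cls2 <- classify_contrasts(rp)
  d <- as.matrix(cls2[, c("delta_eu_ai", "delta_eu_af", "delta_ai_af")])
  hits <- sapply(1:3, function(j) {
    d[, j] >= 0.5 & rowSums(d[, -j, drop = FALSE] < 0.3) == 2
  })
  expect_true(all(rowSums(hits) <= 1))
  labels <- c("EU-AI", "EU-AF", "AI-AF")
  derived <- ifelse(rowSums(hits) == 0, "none",
                    labels[apply(hits, 1, which.max)])
  expect_equal(cls2$maximized_contrast, derived)
})

test_that("greedy AIM selection honors filters, spacing and target sizes", {
  cand <- data.frame(
    snp_id = sprintf("c%d", 1:8),
    chrom = c("1", "1", "2", "2", "3", "3", "4", "4"),
    pos = c(1e6, 1.4e6, 1e6, 2e6, 1e6, 2e6, 1e6, 2e6),
    allele1 = c("A", "A", "A", "A", "A", "A", "A", "C"),
    allele2 = c("G", "G", "G", "G", "G", "G", "T", "T"),
    p_eu = c(0.90, 0.88, 0.90, 0.88, 0.62, 0.60, 0.95, 0.90),
    p_ai = c(0.35, 0.36, 0.62, 0.60, 0.90, 0.88, 0.05, 0.37),
    p_af = c(0.62, 0.60, 0.35, 0.36, 0.35, 0.36, 0.50, 0.62),
    replicate_discordance = c(NA, NA, NA, NA, NA, NA, NA, 0.05),
    stringsAsFactors = FALSE)
  # c1/c2 maximize EU-AI but sit 400 kb apart: only c1 (higher delta) kept;
  # c7 is an ambiguous A/T pair; c8 exceeds the replicate-error ceiling.
  sel <- select_aims(as_parental_panel(cand),
                     target_sizes = c("EU-AI" = 2, "EU-AF" = 2, "AI-AF" = 2))
  expect_equal(nrow(sel$panel), 5)
  expect_setequal(sel$panel$snp_id, c("c1", "c3", "c4", "c5", "c6"))
  expect_false("c2" %in% sel$panel$snp_id)
  expect_false("c7" %in% sel$panel$snp_id)
  expect_false("c8" %in% sel$panel$snp_id)
  expect_s3_class(sel$report, "panel_balance_report")

  # an empty contrast class is a hard error
  no_aiaf <- cand[1:4, ]
  expect_error(select_aims(as_parental_panel(no_aiaf)), "AI-AF")
})

test_that("selected panels satisfy their classification and spacing rules exhaustively", {
  base <- simulate_panel(panel_sim_config(
    set_sizes = c("EU-AI" = 40, "EU-AF" = 40, "AI-AF" = 40), seed = 63))
  cand <- as.data.frame(base)
  withr::local_seed(64)
  cand$chrom <- sample(as.character(1:4), nrow(cand), replace = TRUE)
  cand$pos <- sample.int(3e7, nrow(cand))
  cand$set_label <- NULL
  sel <- select_aims(as_parental_panel(cand))
  out <- sel$panel
  cls <- classify_contrasts(out)
  expect_equal(cls$maximized_contrast[match(out$snp_id, cls$snp_id)],
               out$set_label)
  for (s in unique(out$set_label)) {
    sub <- out[out$set_label == s, ]
    for (ch in unique(sub$chrom)) {
      pos <- sort(sub$pos[sub$chrom == ch])
      if (length(pos) > 1) expect_true(all(diff(pos) >= 5e5))
    }
  }
})

test_that("balance reports separate balanced panels from single-set panels", {
  panel <- simulate_panel(panel_sim_config(
    set_sizes = c("EU-AI" = 60, "EU-AF" = 60, "AI-AF" = 55), seed = 65))
  rep_full <- balance_report(panel)
  expect_true(rep_full$balanced)
  expect_equal(sum(rep_full$per_set$n_snps), nrow(panel))
  # generator cross-check: observed maximized-set mean delta near config
  expect_equal(rep_full$per_set$mean_delta, rep(0.53, 3), tolerance = 0.02)

  one_set <- as_parental_panel(
    as.data.frame(panel)[panel$set_label == "EU-AI", ])
  rep_one <- balance_report(one_set)
  expect_false(rep_one$balanced)

  # Fst summaries appear when genotype counts are supplied, and a fixed
  # difference pushes mean theta toward its ceiling
  p2 <- as_parental_panel(data.frame(
    snp_id = c("x1", "x2"), chrom = "1", pos = c(1e6, 2e6),
    allele1 = "A", allele2 = "G", p_eu = c(1, 1), p_ai = c(0, 0),
    p_af = c(0.5, 0.5), set_label = "EU-AI"))
  counts <- list(
    eu = data.frame(n = c(50, 50), het = 0, allele1 = c(100, 100)),
    ai = data.frame(n = c(50, 50), het = 0, allele1 = c(0, 0)),
    af = data.frame(n = c(50, 50), het = c(25, 25), allele1 = c(50, 50)))
  rep2 <- balance_report(p2, genotype_counts = counts)
  expect_equal(rep2$per_contrast$mean_fst[rep2$per_contrast$contrast == "EU-AI"], 1)
})
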