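test_that("frequency differences follow the allele-1/allele-2 symmetry", {
  p <- tiny_panel()  # rs1: p_eu .9, p_ai .6, p_af .1
  d <- compute_deltas(p)
  expect_equal(d$delta1[d$snp_id == "rs1"], 0.8)
  expect_equal(d$delta2[d$snp_id == "rs1"], 0.5)

  rp <- random_panel(50, seed = 4)
  dr <- compute_deltas(rp)
  expect_equal(dr$delta3, -dr$delta1)
  expect_equal(dr$delta4, -dr$delta2)
  expect_true(all(abs(dr$delta1) <= 1 & abs(dr$delta2) <= 1))

  flat <- as_parental_panel(transform(tiny_panel_df(), p_eu = 0.4,
                                      p_ai = 0.4, p_af = 0.4))
  df <- compute_deltas(flat)
  expect_true(all(df$delta1 == 0 & df$delta2 == 0))
})

test_that("hybrid frequency is the ancestry-weighted parental mixture", {
  snp <- data.frame(p_eu = 0.8, p_ai = 0.6, p_af = 0.2)
  expect_equal(hybrid_freq(0, 0, snp), 0.2)       # pure-AF limit
  expect_equal(hybrid_freq(1, 0, data.frame(p_eu = 0.9, p_ai = 0.5,
                                            p_af = 0.1)), 0.9)
  expect_equal(hybrid_freq(0.5, 0.25, snp), 0.6)  # 0.2 + .5*.6 + .25*.4
  # algebraically the convex combination m1 p_eu + m2 p_ai + m3 p_af
  rp <- random_panel(20, seed = 7)
  expect_equal(hybrid_freq(0.3, 0.45, rp),
               0.3 * rp$p_eu + 0.45 * rp$p_ai + 0.25 * rp$p_af)
  expect_error(hybrid_freq(0.7, 0.5, snp), "simplex")
  expect_error(hybrid_freq(-0.1, 0.5, snp), "simplex")
})

test_that("genotype log-likelihoods are the HWE genotype probabilities", {
  expect_equal(genotype_loglik(1, 0.5), log(0.5))
  expect_equal(genotype_loglik(0, 0.3), log(0.49))
  expect_equal(genotype_loglik(2, 1 - 1e-3), 2 * log1p(-1e-3))
  expect_error(genotype_loglik(3, 0.5), "dosage")
})

test_that("the total log-likelihood sums over non-missing SNPs only", {
  p <- tiny_panel()
  snp1 <- as_parental_panel(tiny_panel_df()[1, ])
  # single SNP at p_h = 0.5: m chosen so p_af + m1*0.8 + m2*0.5 = 0.5
  expect_equal(total_loglik(1, snp1, 0.5, 0), log(0.5))
  ll12 <- total_loglik(c(1, 0, NA), p, 0.2, 0.1)
  expect_equal(ll12, total_loglik(c(1, NA, NA), p, 0.2, 0.1) +
                 total_loglik(c(NA, 0, NA), p, 0.2, 0.1))
  expect_error(total_loglik(c(NA, NA, NA), p, 0.2, 0.1), "missing")
})

test_that("grid MLE matches an independent exhaustive oracle on small instances", {
  withr::local_seed(42)
  for (i in 1:12) {
    G <- sample(2:8, 1)
    rp <- random_panel(G)
    d <- sample(0:2, G, replace = TRUE)
    orc <- oracle_grid_mle(d, rp, step = 0.01)
    est <- suppressWarnings(
      estimate_admixture(d, rp, grid_step = 0.01, mode = "exact-grid",
                         compute_se = FALSE))
    expect_equal(c(est$m_eu, est$m_ai), orc[2:3])
    expect_equal(est$loglik, orc[1])
  }
})

test_that("coarse-to-fine search returns the exact-grid lattice point", {
  withr::local_seed(43)
  for (i in 1:8) {
    G <- sample(3:10, 1)
    rp <- random_panel(G)
    d <- sample(0:2, G, replace = TRUE)
    e1 <- suppressWarnings(estimate_admixture(d, rp, mode = "coarse-to-fine",
                                              compute_se = FALSE))
    e2 <- suppressWarnings(estimate_admixture(d, rp, mode = "exact-grid",
                                              compute_se = FALSE))
    expect_equal(c(e1$m_eu, e1$m_ai, e1$loglik),
                 c(e2$m_eu, e2$m_ai, e2$loglik))
  }
})

test_that("estimates live on the simplex and recover vertices from decisive data", {
  vert <- as_parental_panel(data.frame(
    snp_id = sprintf("v%02d", 1:50), chrom = "1", pos = (1:50) * 1e6,
    allele1 = "A", allele2 = "G", p_eu = 0.999, p_ai = 0.001, p_af = 0.001))
  est <- estimate_admixture(rep(2, 50), vert, compute_se = FALSE)
  expect_equal(c(est$m_eu, est$m_ai, est$m_af), c(1, 0, 0))

  withr::local_seed(44)
  rp <- random_panel(30)
  D <- matrix(sample(c(0:2, NA), 10 * 30, replace = TRUE,
                     prob = c(.3, .3, .3, .1)), nrow = 10)
  est2 <- suppressWarnings(estimate_admixture(D, rp, compute_se = FALSE))
  expect_true(all(est2$m_eu >= 0 & est2$m_ai >= 0 & est2$m_af >= 0))
  expect_equal(est2$m_eu + est2$m_ai + est2$m_af, rep(1, 10),
               tolerance = 1e-12)
  expect_equal(est2$n_snps_used, rowSums(!is.na(D)))
})

test_that("shuffling SNP order changes no estimate", {
  withr::local_seed(45)
  rp <- random_panel(40)
  D <- matrix(sample(0:2, 5 * 40, replace = TRUE), nrow = 5)
  perm <- sample(40)
  rp_perm <- as_parental_panel(as.data.frame(rp)[perm, ])
  idx <- match(rp_perm$snp_id, rp$snp_id)
  e1 <- suppressWarnings(estimate_admixture(D, rp))
  e2 <- suppressWarnings(estimate_admixture(D[, idx], rp_perm))
  expect_equal(e1[c("m_eu", "m_ai", "m_af", "se_eu", "se_ai", "se_af")],
               e2[c("m_eu", "m_ai", "m_af", "se_eu", "se_ai", "se_af")])
})

test_that("information matrix entries match their closed forms and accumulate monotonically", {
  # single SNP engineered to delta1 = .5, delta2 = 0, P = .5
  snp <- as_parental_panel(data.frame(
    snp_id = "s", chrom = "1", pos = 1, allele1 = "A", allele2 = "G",
    p_eu = 0.9, p_ai = 0.4, p_af = 0.4))
  info <- information_matrix(1, snp, m1 = 0.2, m2 = 0)
  expect_equal(info$i_m1, 2)
  expect_equal(info$i_m2, 0)
  expect_equal(info$i_m1m2, 0)

  # an uninformative SNP contributes nothing
  flat <- as_parental_panel(data.frame(
    snp_id = "f", chrom = "1", pos = 1, allele1 = "A", allele2 = "G",
    p_eu = 0.3, p_ai = 0.3, p_af = 0.3))
  info0 <- information_matrix(2, flat, 0.2, 0.3)
  expect_equal(unlist(info0), c(i_m1 = 0, i_m2 = 0, i_m1m2 = 0))

  # adding SNPs never decreases diagonal information
  withr::local_seed(46)
  rp <- random_panel(30)
  prev <- c(0, 0)
  for (G in c(5, 10, 20, 30)) {
    sub <- as_parental_panel(as.data.frame(rp)[1:G, ])
    inf <- information_matrix(rep(1, G), sub, 0.3, 0.3)
    expect_gte(inf$i_m1, prev[1])
    expect_gte(inf$i_m2, prev[2])
    prev <- c(inf$i_m1, inf$i_m2)
  }
})

test_that("Fisher entries equal the negated Hessian of the expected log-likelihood", {
  skip_if_not_installed("pracma")
  withr::local_seed(47)
  for (i in 1:5) {
    rp <- random_panel(15)
    m0 <- c(runif(1, 0.1, 0.6), runif(1, 0.1, 0.35))
    f <- expected_loglik_fn(rp, m0)
    H <- -pracma::hessian(f, m0)
    info <- information_matrix(rep(1, 15), rp, m0[1], m0[2])
    expect_equal(info$i_m1, H[1, 1], tolerance = 1e-4)
    expect_equal(info$i_m2, H[2, 2], tolerance = 1e-4)
    expect_equal(info$i_m1m2, H[1, 2], tolerance = 1e-4)
  }
})

test_that("information inversion yields variances, the m3 identity and SEs", {
  v <- invert_information(list(i_m1 = 100, i_m2 = 100, i_m1m2 = 0))
  expect_equal(v$v_m1, 0.01)
  expect_equal(v$v_m2, 0.01)
  expect_equal(v$cov_m1m2, 0)
  expect_equal(v$v_m3, 0.02)
  expect_equal(v$se_m3, sqrt(0.02))

  v2 <- invert_information(list(i_m1 = 4, i_m2 = 1, i_m1m2 = 0))
  expect_equal(v2$se_m1, 0.5)
  expect_equal(v2$se_m2, 1)

  expect_error(invert_information(list(i_m1 = 1, i_m2 = 1, i_m1m2 = 1)),
               "degenerate")

  # v_m3 identity on estimator output
  withr::local_seed(48)
  rp <- random_panel(40)
  D <- matrix(sample(0:2, 4 * 40, replace = TRUE), nrow = 4)
  est <- suppressWarnings(estimate_admixture(D, rp))
  expect_equal(est$v_af, est$v_eu + est$v_ai + 2 * est$cov_eu_ai)
  expect_equal(est$se_eu, sqrt(est$v_eu))
})

test_that("observed information is available and matches Fisher in expectation scale", {
  withr::local_seed(49)
  rp <- random_panel(200)
  truth <- data.frame(mu_eu = 0.4, mu_ai = 0.35, mu_af = 0.25)
  gm <- simulate_cohort(rp, truth)
  fis <- information_matrix(gm$dosages[1, ], rp, 0.4, 0.35, type = "expected")
  obs <- information_matrix(gm$dosages[1, ], rp, 0.4, 0.35, type = "observed")
  expect_gt(obs$i_m1, 0)
  # same order of magnitude; they estimate the same quantity
  expect_lt(abs(log(obs$i_m1 / fis$i_m1)), log(1.5))
})
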