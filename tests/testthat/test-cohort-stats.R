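test_that("roi averaging reduces nodes to label means", {
  f <- matrix(c(0.4, 0.8, 1.0, 0.2, 0.6, 1.4), nrow = 2, byrow = TRUE)
  lab <- data.frame(node_id = 1:3, roi_id = c(1, 1, 2),
                    roi_name = c("a", "a", "b"))
  out <- roi_average(f, lab)
  expect_equal(dim(out), c(2, 2))
  expect_equal(unname(out[1, ]), c(mean(c(0.4, 0.8)), 1.0))

  # identity partition returns the input
  lab1 <- data.frame(node_id = 1:3, roi_id = 1:3)
  expect_equal(unname(roi_average(f, lab1)), unname(f))

  # atlas-scale fixture: 148 labels over 8196 nodes
  f2 <- matrix(rnorm(2 * 8196), 2)
  expect_equal(ncol(roi_average(f2, synthetic_label_map(8196, 148))), 148)

  expect_error(roi_average(f, data.frame(node_id = 1:2, roi_id = 1:2)),
               "unmapped")
})

test_that("the pseudo t statistic matches hand calculations and handles s0", {
  expect_equal(pseudo_t(c(1, 2, 3), c(1, 2, 3), s0 = 0.1), 0)
  expect_error(pseudo_t(rep(1, 4), rep(0, 4), s0 = 0), "denominator")
  expect_equal(pseudo_t(rep(1, 4), rep(0, 4), s0 = 0.5), 1 / 0.5)
  # A = {1,2,3}, B = {0,1,2}: t = 1 / sqrt(1/3 + 1/3)
  expect_equal(pseudo_t(c(1, 2, 3), c(0, 1, 2)), 1 / sqrt(2 / 3),
               tolerance = 1e-12)
})

test_that("maxstat corrected p are invariant to node order and level shifts", {
  fc <- simulate_feature_cohort(8, 12, seed = 31)
  r1 <- maxstat_permutation(fc$features, fc$groups, n_perm = 150, seed = 7)
  perm <- sample(12)
  r2 <- maxstat_permutation(fc$features[, perm], fc$groups, n_perm = 150,
                            seed = 7)
  expect_equal(r2$p_corrected, r1$p_corrected[perm])
  r3 <- maxstat_permutation(fc$features + 5, fc$groups, n_perm = 150, seed = 7)
  expect_equal(r3$p_corrected, r1$p_corrected)
  expect_true(all(r1$p_corrected >= 1 / (r1$n_perm + 1)))
  expect_identical(r1$mask, r1$p_corrected <= r1$alpha)
})

test_that("small cohorts trigger exhaustive enumeration", {
  fc <- simulate_feature_cohort(4, 6, seed = 13)
  r <- maxstat_permutation(fc$features, fc$groups, n_perm = 100, seed = 1)
  expect_true(r$exact)
  expect_equal(r$n_perm, choose(8, 4))
})

test_that("a large injected shift reaches the minimum attainable corrected p", {
  fc <- simulate_feature_cohort(25, 30, effect_nodes = 5, delta = 0.3,
                                noise_sd = 0.1, seed = 3)  # 3 pooled SDs
  r <- maxstat_permutation(fc$features, fc$groups, n_perm = 200, seed = 9)
  expect_equal(r$p_corrected[5], 1 / 201)
  expect_true(r$mask[5])
})

test_that("BH-FDR matches the hand step-up case and the brute-force oracle", {
  expect_equal(sum(bh_fdr(rep(1, 10))$mask), 0)
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_equal(r$q, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(r$mask, c(TRUE, TRUE, TRUE, FALSE))

  set.seed(8)
  for (rep in 1:40) {
    m <- sample(1:12, 1)
    p <- round(runif(m), sample(c(1, 2, 3), 1))   # coarse rounding forces ties
    ours <- bh_fdr(p, alpha = 0.05)
    ref <- bh_oracle(p, alpha = 0.05)
    expect_equal(ours$q, ref$q)
    expect_identical(ours$mask, ref$mask)
  }
})

test_that("correlation maps behave under exact coupling and affine/monotone maps", {
  set.seed(12)
  X <- matrix(rnorm(20 * 6), 20, 6)
  cov <- X[, 4]
  r <- clinical_correlation(X, cov)
  expect_equal(r$r[4], 1, tolerance = 1e-10)
  expect_lt(r$p[4], 1e-12)
  expect_true(r$mask[4])
  expect_gte(min(r$q - r$p), 0)

  # Pearson invariant under positive affine maps of the covariate
  r2 <- clinical_correlation(X, 3 * cov + 7)
  expect_equal(r2$r, r$r, tolerance = 1e-12)
  # Spearman invariant under monotone transforms
  s1 <- clinical_correlation(X, cov, method = "spearman")
  s2 <- clinical_correlation(X, exp(cov), method = "spearman")
  expect_equal(s1$r, s2$r, tolerance = 1e-12)
  expect_true(all(is.na(s1$q)))
  expect_false(attr(s1, "corrected"))

  expect_error(clinical_correlation(X, rep(1, 20)), "constant")
  cov_na <- cov; cov_na[1:16] <- NA
  expect_error(suppressMessages(clinical_correlation(X, cov_na)), "fewer than 5")
})

test_that("null correlations stay near nominal false-positive rates", {
  set.seed(77)
  X <- matrix(rnorm(25 * 100), 25, 100)
  r <- clinical_correlation(X, rnorm(25))
  expect_lt(abs(mean(r$p < 0.05) - 0.05), 0.06)
  expect_equal(sum(r$mask), 0)
})

test_that("the mediation check reports correlation and shared variance", {
  set.seed(2)
  dose <- runif(25, 5, 25)
  expect_equal(mediation_check(score = dose, dose = dose)$r_squared, 1)
  ind <- mediation_check(score = rnorm(200), dose = rnorm(200))
  expect_lt(ind$r_squared, 0.05)

  r2s <- sapply(1:30, function(s) {
    co <- simulate_cohort(synthetic_cohort_spec(n_per_group = 25, seed = s))
    p <- co$subjects$group == "patient"
    mediation_check(score = co$subjects$sans[p],
                    dose = co$subjects$medication_mg[p])$r_squared
  })
  expect_lt(abs(mean(r2s) - 0.3), 0.1)
  expect_error(mediation_check(score = rep(1, 10), dose = rnorm(10)),
               "constant")
})
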