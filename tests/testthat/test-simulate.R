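test_that("H = 0.5 fGn increments are white", {
  ac <- sapply(1:20, function(s) {
    x <- simulate_fgn_fbm(2^12, 0.5, seed = s, increments = TRUE)$samples
    cor(x[-1], x[-length(x)])
  })
  expect_lt(abs(mean(ac)), 0.02)
})

test_that("fBm increment-variance scaling follows k^(2H)", {
  ks <- 2^(0:6)
  lv <- matrix(NA_real_, 20, length(ks))
  for (s in 1:20) {
    x <- simulate_fgn_fbm(2^13, 0.7, seed = 100 + s)$samples
    lv[s, ] <- vapply(ks, function(k) var(x[-(1:k)] - x[1:(length(x) - k)]),
                      numeric(1))
  }
  slope <- coef(lm(colMeans(log2(lv)) ~ log2(ks)))[2]
  expect_lt(abs(slope - 1.4), 0.05)
})

test_that("lambda2 = 0 reduces the MRW exactly to fBm", {
  a <- simulate_mrw(2^10, 0.7, 0, seed = 77)
  b <- simulate_fgn_fbm(2^10, 0.7, seed = 77)
  expect_identical(a$samples, b$samples)
})

test_that("the log-normal cascade produces heavy-tailed increments", {
  ex_kurt <- sapply(1:20, function(s) {
    x <- diff(simulate_mrw(2^13, 0.7, 0.08, seed = 900 + s)$samples)
    mean((x - mean(x))^4) / var(x)^2 - 3
  })
  expect_gt(mean(ex_kurt), 0.5)
  expect_gt(mean(ex_kurt > 0), 0.9)
})

test_that("cohorts are bit-exact reproducible from the master seed", {
  spec <- synthetic_cohort_spec(n_per_group = 4, n_nodes = 6,
                                n_samples = 2^10, seed = 42)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$truth, b$truth)
  expect_identical(subject_signals(a, 3), subject_signals(b, 3))
})

test_that("ground-truth maps implement the gradients and patient offsets", {
  spec <- synthetic_cohort_spec(n_nodes = 50)
  co <- simulate_cohort(spec)
  gm <- co$truth$group_maps
  expect_true(all(diff(gm$H$control) > 0))          # ascending rostro-caudal c1
  expect_true(all(diff(gm$lambda2$control) > 0))    # descending c2 (= -lambda2)
  # attenuated gradient in patients outside the offset sets
  mid <- setdiff(seq_len(50), c(gm$frontal_nodes, gm$posterior_nodes))
  expect_lt(diff(range(gm$H$patient[mid])), diff(range(gm$H$control[mid])))
  # frontal nodes more self-similar, posterior nodes less multifractal
  expect_true(all(gm$H$patient[gm$frontal_nodes] >
                  gm$H$control[gm$frontal_nodes]))
  expect_true(all(gm$lambda2$patient[gm$posterior_nodes] <
                  gm$lambda2$control[gm$posterior_nodes]))
  expect_true(all(co$truth$H_subject > 0 & co$truth$H_subject < 1))
  expect_true(all(co$truth$lambda2_subject >= 0))
})

test_that("clinical scores couple to regional ground truth at the target strength", {
  co <- simulate_cohort(synthetic_cohort_spec(seed = 11))
  pat <- which(co$subjects$group == "patient")
  m1 <- rowMeans(co$truth$c1_true[pat, co$truth$frontal_nodes])
  r <- cor(co$subjects$sans[pat], m1)
  expect_gt(r, 0.6); expect_lt(r, 0.95)
  rd <- cor(co$subjects$sans[pat], co$subjects$medication_mg[pat])
  expect_gt(rd, 0.2); expect_lt(rd, 0.85)
  expect_true(all(is.na(co$subjects$sans[co$subjects$group == "control"])))
})

test_that("estimated control c1 follows the node gradient", {
  spec <- synthetic_cohort_spec(n_per_group = 4, n_nodes = 5,
                                n_samples = 2^13, subject_H_sd = 0.02,
                                seed = 5)
  co <- simulate_cohort(spec)
  ctl <- which(co$subjects$group == "control")
  prof <- colMeans(t(sapply(ctl, function(i) {
    sigs <- subject_signals(co, i)
    apply(sigs, 1, function(x) est_c1c2(x, j1 = 3, j2 = 8)["c1"])
  })))
  expect_gt(cor(prof, seq_along(prof), method = "spearman"), 0.85)
})

test_that("feature-level cohorts carry the requested effect", {
  fc <- simulate_feature_cohort(10, 20, effect_nodes = c(3, 7), delta = 0.5,
                                seed = 2)
  expect_equal(dim(fc$features), c(20, 20))
  d <- colMeans(fc$features[11:20, ]) - colMeans(fc$features[1:10, ])
  expect_true(all(rank(-d)[c(3, 7)] <= 2))
  # identical seeds reproduce
  expect_identical(fc$features,
                   simulate_feature_cohort(10, 20, effect_nodes = c(3, 7),
                                           delta = 0.5, seed = 2)$features)
})

test_that("synthetic label maps partition the nodes", {
  lm148 <- synthetic_label_map(8196, 148)
  expect_equal(nrow(lm148), 8196)
  expect_equal(length(unique(lm148$roi_id)), 148)
  expect_true(all(table(lm148$roi_id) >= 1))
})
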