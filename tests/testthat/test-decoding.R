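test_that("stratified folds balance classes and are seed-deterministic", {
  g <- rep(c("ctl", "pat"), each = 25)
  f <- stratified_folds(g, k = 10, seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 5))
  per_class <- table(f, g)
  expect_true(all(per_class >= 2 & per_class <= 3))

  g2 <- rep(c("a", "b"), each = 4)
  f2 <- stratified_folds(g2, k = 4, seed = 3)
  expect_true(all(table(f2, g2) == 1))

  expect_identical(stratified_folds(g, 10, seed = 5),
                   stratified_folds(g, 10, seed = 5))
  expect_false(identical(stratified_folds(g, 10, seed = 5),
                         stratified_folds(g, 10, seed = 6)))
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 20)), k = 5), "smaller")
})

test_that("separable and constant features give DA = 1 and 0.5", {
  g <- rep(c("a", "b"), each = 20)
  x <- c(rnorm(20, -3, 0.3), rnorm(20, 3, 0.3))
  expect_equal(decode_single_feature(x, g, k = 10, seed = 1), 1.0)
  expect_equal(decode_single_feature(rep(1, 40), g, k = 10, seed = 1), 0.5)
})

test_that("cross-validated DA approaches the Bayes rate for d-prime = 1", {
  # Monte-Carlo oracle: optimal accuracy for two unit-variance Gaussians
  # one SD apart, estimated directly from the generative model
  set.seed(99)
  z <- c(rnorm(2e5, 0), rnorm(2e5, 1))
  lab <- rep(0:1, each = 2e5)
  bayes <- mean((z > 0.5) == lab)
  das <- sapply(1:200, function(s) {
    set.seed(1000 + s)
    x <- c(rnorm(25, 0), rnorm(25, 1))
    decode_single_feature(x, rep(c("a", "b"), each = 25), k = 10, seed = s)
  })
  expect_lt(abs(mean(das) - bayes), 0.03)
})

test_that("shuffled-label DA is centred on one half for balanced cohorts", {
  set.seed(55)
  x <- rnorm(50)
  g <- rep(0:1, each = 25)
  das <- sapply(1:1000, function(b) {
    yb <- critmf:::with_seed(b, sample(g))
    decode_single_feature(x, yb, k = 10, seed = b)
  })
  # cross-validation under the permutation null is known to sit slightly
  # below one half (pessimistic small-sample bias); the distribution is
  # centred near 0.5, not exactly on it
  expect_gt(mean(das), 0.45)
  expect_lt(mean(das), 0.53)
})

test_that("the chance threshold respects 0.5, grows with the node family, and reproduces", {
  fc <- simulate_feature_cohort(25, 50, seed = 41)
  thr <- sapply(c(10, 25, 50), function(m)
    decoding_null_threshold(fc$features[, 1:m, drop = FALSE], fc$groups,
                            k = 10, n_perm = 100, alpha = 0.05,
                            seed = 4)$threshold)
  expect_true(all(diff(thr) >= 0))
  expect_gte(thr[1], 0.5)

  r1 <- decoding_null_threshold(fc$features[, 1:10], fc$groups, k = 10,
                                n_perm = 100, seed = 12)
  r2 <- decoding_null_threshold(fc$features[, 1:10], fc$groups, k = 10,
                                n_perm = 100, seed = 12)
  expect_identical(r1$da, r2$da)
  expect_identical(r1$null_max, r2$null_max)
  expect_identical(r1$mask, r1$da > r1$threshold)
  expect_error(decoding_null_threshold(fc$features, fc$groups, n_perm = 50),
               "n_perm")
})
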