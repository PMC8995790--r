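exact_leaders <- function(slope = 0.8, counts = c(512, 256, 128, 64)) {
  make_leaders(lapply(seq_along(counts), function(j)
    rep(2^(j * slope), counts[j])))
}

test_that("dispersion-free dyadic leaders give c1 = slope, c2 = 0 exactly", {
  est <- log_cumulants(exact_leaders(0.8), j1 = 1, j2 = 4)
  expect_equal(est$c1, 0.8, tolerance = 1e-12)
  expect_equal(est$c2, 0, tolerance = 1e-12)
  expect_false(est$flags$positive_c2)
  z <- estimate_zeta(exact_leaders(0.8), q_list = c(-1, 0.5, 1, 2, 3),
                     j1 = 1, j2 = 4)
  expect_equal(unname(z), 0.8 * c(-1, 0.5, 1, 2, 3), tolerance = 1e-10)
})

test_that("fit-range and leader-count preconditions are enforced", {
  el <- exact_leaders(0.8)
  expect_error(log_cumulants(el, 3, 3), "j1 < j2")
  expect_error(log_cumulants(el, 1, 9), "exceeds")
  few <- make_leaders(list(rep(1.5, 100), rep(2, 4)))
  expect_error(log_cumulants(few, 1, 2), "insufficient")
})

test_that("positive c2 is reported, flagged, and refused by the spectrum", {
  # leaders whose log-variance grows with scale force a positive slope
  set.seed(3)
  vals <- lapply(1:4, function(j) exp(rnorm(2^(9 - j), j * 0.5, sqrt(j * 0.1))))
  est <- log_cumulants(make_leaders(vals), 1, 4)
  expect_gt(est$c2, 0)
  expect_true(est$flags$positive_c2)
  expect_error(legendre_spectrum(est), "undefined")
})

test_that("the parabolic singularity spectrum has unit apex, zero edges and symmetry", {
  est <- log_cumulants(exact_leaders(0.8), 1, 4)
  est$c2 <- -0.02
  sp <- legendre_spectrum(est)
  expect_equal(sp$apex, 0.8)
  expect_equal(max(sp$D), 1)
  expect_equal(sp$h[which.max(sp$D)], 0.8, tolerance = 1e-6)
  # direct parabola evaluation: D(0.6) = 1 + 0.04 / (2 * -0.02) = 0
  expect_equal(1 + (0.6 - 0.8)^2 / (2 * -0.02), 0)
  expect_equal(min(sp$D), 0, tolerance = 1e-12)
  expect_equal(sp$width, 2 * sqrt(0.04))
  expect_equal(sp$D, rev(sp$D), tolerance = 1e-10)      # symmetric about c1
  expect_true(all(sp$D <= 1))

  est$c2 <- 0
  expect_error(legendre_spectrum(est), "undefined")     # monofractal point
})

test_that("zeta is concave on multifractal ensembles", {
  viol <- sapply(1:6, function(s) {
    w <- dwt_coefficients(simulate_mrw(2^14, 0.7, 0.08, seed = 70 + s))
    z <- estimate_zeta(p_leaders(w, 2), c(0, 1, 2), 3, 9)
    z[["2"]] - 2 * z[["1"]] + z[["0"]]
  })
  expect_true(all(viol < 0.02))
})

test_that("fBm log-cumulants at desk scale recover (H, 0)", {
  ests <- sapply(1:8, function(s)
    est_c1c2(simulate_fgn_fbm(2^14, 0.7, seed = 300 + s)))
  expect_lt(abs(mean(ests["c1", ]) - 0.7), 0.06)
  expect_lt(abs(mean(ests["c2", ])), 0.02)
})

test_that("bootstrap CIs collapse on dispersion-free leaders and behave on fBm", {
  ci <- bootstrap_ci(exact_leaders(0.8, counts = c(1024, 512, 256, 128)),
                     j1 = 1, j2 = 3, n_boot = 60, seed = 1)
  expect_equal(diff(ci$c1), 0, tolerance = 1e-12)
  expect_equal(ci$c1[1], 0.8, tolerance = 1e-12)

  covered <- logical(10)
  for (s in 1:10) {
    pl <- p_leaders(dwt_coefficients(simulate_fgn_fbm(2^16, 0.7, seed = 2000 + s)))
    ci <- bootstrap_ci(pl, 4, 11, n_boot = 100, seed = s)
    covered[s] <- ci$c1[1] <= 0.7 && 0.7 <= ci$c1[2]
  }
  expect_gte(mean(covered), 0.8)

  # width shrinks (on average) with signal length
  w_short <- mean(sapply(1:3, function(s) {
    pl <- p_leaders(dwt_coefficients(simulate_fgn_fbm(2^12, 0.7, seed = 600 + s)))
    diff(bootstrap_ci(pl, 3, 6, n_boot = 60, seed = s)$c1)
  }))
  w_long <- mean(sapply(1:3, function(s) {
    pl <- p_leaders(dwt_coefficients(simulate_fgn_fbm(2^15, 0.7, seed = 700 + s)))
    diff(bootstrap_ci(pl, 3, 6, n_boot = 60, seed = s)$c1)
  }))
  expect_lt(w_long, w_short)

  tiny <- make_leaders(list(rep(2, 64), rep(4, 32), rep(8, 8)))
  expect_error(bootstrap_ci(tiny, 1, 3, n_boot = 60), "blocks")
  expect_error(bootstrap_ci(exact_leaders(0.8), 1, 3, n_boot = 10), "n_boot")
})
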