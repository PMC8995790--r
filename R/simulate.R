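## Exact stationary Gaussian sampling by circulant embedding of an
## autocovariance sequence acf[1..n] (lags 0..n-1). Returns one real sample
## of length n. Slightly negative embedding eigenvalues (non-PSD embedding)
## are clipped to zero; beyond `tol` relative mass this degrades to an
## approximate spectral synthesis and is reported via a message.
circulant_gaussian <- function(acf, tol = 1e-8) {
  n <- length(acf)
  row <- c(acf, 0, rev(acf[-1]))        # circulant first row, size 2n
  m <- length(row)
  ev <- Re(stats::fft(row))
  if (min(ev) < -tol * max(ev))
    message(sprintf(
      "circulant embedding not positive semidefinite (min eigenvalue %.3g); falling back to approximate spectral synthesis",
      min(ev)))
  ev[ev < 0] <- 0
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  Re(stats::fft(sqrt(ev) * z))[seq_len(n)] / sqrt(m)
}

fgn_acf <- function(n, H) {
  k <- 0:(n - 1)
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

#' Simulate fractional Brownian motion (fBm)
#'
#' Draws exact-covariance fractional Gaussian noise by circulant embedding of
#' the fGn autocovariance
#' `gamma(k) = (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H)) / 2`
#' and cumulates it to fBm. fBm is the canonical monofractal signal:
#' `c1 = H`, `c2 = 0`.
#'
#' @param n number of samples.
#' @param H Hurst exponent, in (0, 1).
#' @param seed optional integer seed (local stream; the caller's RNG state is
#'   untouched).
#' @param sampling_rate Hz, attached to the returned signal.
#' @param increments if `TRUE`, return the fGn increments instead of fBm.
#' @return a [signal_vector()].
#' @export
simulate_fgn_fbm <- function(n, H, seed = NULL, sampling_rate = 1,
                             increments = FALSE) {
  if (H <= 0 || H >= 1) stop("H must lie in (0, 1)")
  x <- with_seed(seed, circulant_gaussian(fgn_acf(n, H)))
  if (!increments) x <- cumsum(x)
  signal_vector(x, sampling_rate)
}

#' Simulate a multifractal random walk (MRW)
#'
#' Increments `dX_i = eps_i * exp(omega_i)` with `eps` fractional Gaussian
#' noise of exponent `H` and `omega` an independent Gaussian sequence with
#' logarithmic covariance
#' `Cov(omega_i, omega_j) = lambda2 * max(0, ln(L / (|i-j| + 1)))`,
#' correlation horizon `L = n/8`, and mean `-Var(omega)/2` (normalizing the
#' moments of `exp(omega)`). The cumulated walk is the canonical log-normal
#' multifractal: theoretical log-cumulants `c1 = H + lambda2/2`,
#' `c2 = -lambda2`. `lambda2 = 0` reduces exactly to [simulate_fgn_fbm()].
#'
#' @param n number of samples.
#' @param H Hurst exponent of the Gaussian backbone, in (0, 1).
#' @param lambda2 cascade intensity (`>= 0`, `<= 0.2`); `-lambda2` is the
#'   target second log-cumulant.
#' @param seed optional integer seed (local stream).
#' @param L correlation horizon of the log-normal cascade; default `n / 8`.
#' @param sampling_rate Hz.
#' @return a [signal_vector()] holding the cumulated walk.
#' @export
simulate_mrw <- function(n, H, lambda2, seed = NULL, L = n / 8,
                         sampling_rate = 1) {
  if (H <= 0 || H >= 1) stop("H must lie in (0, 1)")
  if (lambda2 < 0 || lambda2 > 0.2) stop("lambda2 must lie in [0, 0.2]")
  x <- with_seed(seed, {
    eps <- circulant_gaussian(fgn_acf(n, H))
    if (lambda2 == 0) {
      eps
    } else {
      k <- 0:(n - 1)
      om_acf <- lambda2 * pmax(0, log(L / (k + 1)))
      om <- circulant_gaussian(om_acf) - lambda2 * max(0, log(L)) / 2
      eps * exp(om)
    }
  })
  signal_vector(cumsum(x), sampling_rate)
}

#' Specification of a synthetic two-group cohort with known ground truth
#'
#' Describes a control/patient cohort of per-node scale-free signals whose
#' true self-similarity and multifractality maps follow opposing
#' rostro-caudal gradients along an abstract node coordinate `x` in `[0, 1]`
#' (0 = frontal pole stand-in, 1 = occipital pole stand-in):
#' controls have `H(x)` increasing and cascade intensity `lambda2(x)`
#' increasing with `x` (so `c2 = -lambda2` decreases, i.e. multifractality
#' grows toward the back). The patient group gets (a) the same gradients
#' attenuated around their midpoint by `patient_gradient_factor`, (b) a
#' positive offset `patient_dH` on the designated "fronto-temporal" nodes
#' (more self-similar), and (c) a reduction of `lambda2` by
#' `patient_dlambda2` on the "parieto-occipital" nodes (multifractality
#' pushed toward 0). Per-subject variation enters as a global `H` shift
#' (`subject_H_sd`) and a multiplicative `lambda2` factor
#' (`subject_lambda2_sd` on the log scale is approximated by a truncated
#' normal factor).
#'
#' Clinical covariates exist for patients only: negative-symptom score
#' coupled linearly to the mean true `c1` over the frontal coupling set,
#' positive-symptom score coupled to the mean true `c2` over the posterior
#' set (both with Gaussian noise `score_noise_sd` scaled for a target
#' correlation near 0.8 at the default geometry), and a medication dose
#' correlated with the negative-symptom score at level `dose_score_cor`.
#'
#' @param n_per_group subjects per group.
#' @param n_nodes number of cortical nodes.
#' @param n_samples samples per signal.
#' @param sampling_rate Hz.
#' @param H_range control-group `H` at `x = 0` and `x = 1` (linear gradient).
#' @param lambda2_range control-group `lambda2` at `x = 0` and `x = 1`.
#' @param patient_gradient_factor slope attenuation in patients (< 1).
#' @param patient_dH `H` offset added on frontal-set nodes in patients.
#' @param patient_dlambda2 `lambda2` subtracted (floored at 0) on
#'   posterior-set nodes in patients.
#' @param frontal_frac,posterior_frac fractions of the node axis forming the
#'   frontal and posterior node sets.
#' @param subject_H_sd SD of the per-subject global `H` shift.
#' @param subject_lambda2_sd SD of the per-subject multiplicative `lambda2`
#'   factor (mean 1, truncated at 0.1).
#' @param score_coupling_H,score_coupling_c2 linear coupling coefficients of
#'   the two clinical scores.
#' @param score_noise_sd SD of the additive score noise (same units as the
#'   scores).
#' @param dose_score_cor target correlation between medication dose and the
#'   negative-symptom score.
#' @param seed master seed; every per-subject, per-node stream is derived
#'   from it deterministically.
#' @return object of class `critmf_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_per_group = 25, n_nodes = 50,
                                  n_samples = 2^14, sampling_rate = 600,
                                  H_range = c(0.5, 0.9),
                                  lambda2_range = c(0.001, 0.02),
                                  patient_gradient_factor = 0.6,
                                  patient_dH = 0.10,
                                  patient_dlambda2 = 0.008,
                                  frontal_frac = 0.2, posterior_frac = 0.2,
                                  subject_H_sd = 0.05,
                                  subject_lambda2_sd = 0.15,
                                  score_coupling_H = 100,
                                  score_coupling_c2 = 3000,
                                  score_noise_sd = 3.75,
                                  dose_score_cor = 0.55,
                                  seed = 1L) {
  stopifnot(n_per_group >= 2, n_nodes >= 2, n_samples >= 256,
            sampling_rate > 0,
            all(H_range > 0), all(H_range < 1),
            all(lambda2_range >= 0), patient_gradient_factor > 0,
            subject_H_sd >= 0, score_noise_sd > 0,
            abs(dose_score_cor) <= 1)
  spec <- list(n_per_group = n_per_group, n_nodes = n_nodes,
               n_samples = n_samples, sampling_rate = sampling_rate,
               H_range = H_range, lambda2_range = lambda2_range,
               patient_gradient_factor = patient_gradient_factor,
               patient_dH = patient_dH, patient_dlambda2 = patient_dlambda2,
               frontal_frac = frontal_frac, posterior_frac = posterior_frac,
               subject_H_sd = subject_H_sd,
               subject_lambda2_sd = subject_lambda2_sd,
               score_coupling_H = score_coupling_H,
               score_coupling_c2 = score_coupling_c2,
               score_noise_sd = score_noise_sd,
               dose_score_cor = dose_score_cor,
               seed = as.integer(seed))
  class(spec) <- "critmf_cohort_spec"
  spec
}

## group-level ground-truth maps along the node axis
cohort_truth_maps <- function(spec) {
  x <- seq(0, 1, length.out = spec$n_nodes)
  H_ctl <- spec$H_range[1] + diff(spec$H_range) * x
  l_ctl <- spec$lambda2_range[1] + diff(spec$lambda2_range) * x
  g <- spec$patient_gradient_factor
  frontal <- which(x <= spec$frontal_frac)
  posterior <- which(x >= 1 - spec$posterior_frac)
  H_pat <- mean(spec$H_range) + g * (H_ctl - mean(spec$H_range))
  H_pat[frontal] <- H_pat[frontal] + spec$patient_dH
  l_pat <- mean(spec$lambda2_range) + g * (l_ctl - mean(spec$lambda2_range))
  l_pat[posterior] <- pmax(0, l_pat[posterior] - spec$patient_dlambda2)
  list(x = x, H = list(control = H_ctl, patient = H_pat),
       lambda2 = list(control = pmax(0, l_ctl), patient = pmax(0, l_pat)),
       frontal_nodes = frontal, posterior_nodes = posterior)
}

#' Simulate a two-group cohort with known ground truth
#'
#' Materializes the subject table, per-subject true `(H, lambda2)` node maps,
#' clinical covariates and the per-signal seeds from a
#' [synthetic_cohort_spec()]. Signals themselves are generated lazily per
#' subject via [subject_signals()] (a full cohort of long records does not
#' need to reside in memory at once). Everything is bit-exact reproducible
#' from the master seed.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return object of class `critmf_cohort`: `spec`, `truth` (group maps,
#'   node sets, per-subject `H` and `lambda2` matrices, theoretical per-node
#'   `c1 = H + lambda2/2` and `c2 = -lambda2`), `subjects` (data.frame with
#'   id, group, SANS-like and SAPS-like scores, medication dose), and the
#'   seed matrix for the per-signal streams.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "critmf_cohort_spec"))
  n <- 2L * spec$n_per_group
  maps <- cohort_truth_maps(spec)
  groups <- rep(c("control", "patient"), each = spec$n_per_group)
  ids <- sprintf("S%03d", seq_len(n))

  draws <- with_seed(spec$seed, {
    u <- stats::rnorm(n, 0, spec$subject_H_sd)
    lf <- pmax(0.1, stats::rnorm(n, 1, spec$subject_lambda2_sd))
    e1 <- stats::rnorm(spec$n_per_group, 0, spec$score_noise_sd)
    e2 <- stats::rnorm(spec$n_per_group, 0, spec$score_noise_sd)
    zd <- stats::rnorm(spec$n_per_group)
    seeds <- matrix(sample.int(2147483646L, n * spec$n_nodes, replace = TRUE),
                    nrow = n)
    list(u = u, lf = lf, e1 = e1, e2 = e2, zd = zd, seeds = seeds)
  })

  H_subj <- matrix(NA_real_, n, spec$n_nodes)
  l_subj <- matrix(NA_real_, n, spec$n_nodes)
  for (i in seq_len(n)) {
    gm <- if (groups[i] == "control") "control" else "patient"
    H_subj[i, ] <- pmin(0.98, pmax(0.05, maps$H[[gm]] + draws$u[i]))
    l_subj[i, ] <- pmin(0.2, pmax(0, maps$lambda2[[gm]] * draws$lf[i]))
  }
  c1_true <- H_subj + l_subj / 2
  c2_true <- -l_subj

  pat <- which(groups == "patient")
  m1 <- rowMeans(c1_true[pat, maps$frontal_nodes, drop = FALSE])
  m2 <- rowMeans(c2_true[pat, maps$posterior_nodes, drop = FALSE])
  sans <- 40 + spec$score_coupling_H * (m1 - mean(m1)) + draws$e1
  saps <- 35 + spec$score_coupling_c2 * (m2 - mean(m2)) + draws$e2
  rho <- spec$dose_score_cor
  zs <- (sans - mean(sans)) / stats::sd(sans)
  dose <- pmax(0, 12 + 8 * (rho * zs + sqrt(1 - rho^2) * draws$zd))

  subjects <- data.frame(
    id = ids, group = groups,
    sans = NA_real_, saps = NA_real_, medication_mg = NA_real_,
    stringsAsFactors = FALSE)
  subjects$sans[pat] <- sans
  subjects$saps[pat] <- saps
  subjects$medication_mg[pat] <- dose

  structure(list(
    spec = spec,
    subjects = subjects,
    truth = list(x = maps$x, group_maps = maps,
                 H_subject = H_subj, lambda2_subject = l_subj,
                 c1_true = c1_true, c2_true = c2_true,
                 frontal_nodes = maps$frontal_nodes,
                 posterior_nodes = maps$posterior_nodes),
    seeds = draws$seeds),
    class = "critmf_cohort")
}

#' Generate one subject's node-by-sample signal matrix
#'
#' Draws the multifractal random walks for every node of one subject from
#' the cohort's per-signal seed matrix.
#'
#' @param cohort a `critmf_cohort` from [simulate_cohort()].
#' @param subject subject index (row of `cohort$subjects`).
#' @return numeric matrix, `n_nodes` rows by `n_samples` columns.
#' @export
subject_signals <- function(cohort, subject) {
  stopifnot(inherits(cohort, "critmf_cohort"))
  spec <- cohort$spec
  out <- matrix(NA_real_, spec$n_nodes, spec$n_samples)
  for (v in seq_len(spec$n_nodes)) {
    out[v, ] <- simulate_mrw(spec$n_samples,
                             H = cohort$truth$H_subject[subject, v],
                             lambda2 = cohort$truth$lambda2_subject[subject, v],
                             seed = cohort$seeds[subject, v],
                             sampling_rate = spec$sampling_rate)$samples
  }
  out
}

#' @export
print.critmf_cohort <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<critmf_cohort> %d + %d subjects, %d nodes, %d samples @ %g Hz\n",
              s$n_per_group, s$n_per_group, s$n_nodes, s$n_samples,
              s$sampling_rate))
  invisible(x)
}

#' Feature-level synthetic cohort
#'
#' Emulates the output of the per-node log-cumulant stage directly: a
#' subjects-by-nodes feature matrix equal to a ground-truth node profile plus
#' independent Gaussian estimator noise, with an optional group effect
#' `delta` injected at designated nodes of group B. This is the workhorse
#' for calibration and power studies of the group-statistics and decoding
#' stages, where thousands of cohorts are needed and signal-level synthesis
#' would be pointless overhead: under the null (`delta = 0`) both groups are
#' exchangeable by construction.
#'
#' @param n_per_group subjects per group.
#' @param n_nodes number of nodes.
#' @param effect_nodes integer indices receiving the group effect.
#' @param delta effect size added to group B at `effect_nodes` (feature
#'   units; the default estimator noise SD is 0.1, so `delta = 0.15` is 1.5
#'   pooled SDs).
#' @param noise_sd estimator noise SD (default 0.1, the typical c1
#'   dispersion of desk-scale estimates).
#' @param profile optional length-`n_nodes` baseline profile; default a
#'   linear 0.5..0.9 gradient.
#' @param seed optional integer seed.
#' @return list: `features` (matrix), `groups` (factor), `effect_nodes`.
#' @export
simulate_feature_cohort <- function(n_per_group = 25, n_nodes = 50,
                                    effect_nodes = integer(0), delta = 0,
                                    noise_sd = 0.1, profile = NULL,
                                    seed = NULL) {
  if (is.null(profile)) profile <- seq(0.5, 0.9, length.out = n_nodes)
  stopifnot(length(profile) == n_nodes)
  n <- 2L * n_per_group
  feats <- with_seed(seed, {
    m <- matrix(stats::rnorm(n * n_nodes, 0, noise_sd), n, n_nodes)
    m <- sweep(m, 2, profile, "+")
    if (length(effect_nodes) && delta != 0)
      m[(n_per_group + 1L):n, effect_nodes] <-
        m[(n_per_group + 1L):n, effect_nodes] + delta
    m
  })
  list(features = feats,
       groups = factor(rep(c("A", "B"), each = n_per_group)),
       effect_nodes = effect_nodes)
}

#' Synthetic node-to-ROI label map
#'
#' Partitions `n_nodes` consecutive nodes into `n_rois` contiguous synthetic
#' ROIs of near-equal size (a stand-in for a cortical atlas; no real
#' geometry is implied).
#'
#' @param n_nodes number of nodes.
#' @param n_rois number of ROIs (<= `n_nodes`).
#' @return data.frame with columns `node_id`, `roi_id`, `roi_name`.
#' @export
synthetic_label_map <- function(n_nodes, n_rois = min(148, n_nodes)) {
  stopifnot(n_rois >= 1, n_rois <= n_nodes)
  roi <- as.integer(cut(seq_len(n_nodes), breaks = n_rois, labels = FALSE))
  data.frame(node_id = seq_len(n_nodes), roi_id = roi,
             roi_name = sprintf("synthetic_roi_%03d", roi),
             stringsAsFactors = FALSE)
}
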