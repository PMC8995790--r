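---
title: "Methods: wavelet p-leader log-cumulants, group inference, and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet p-leader log-cumulants, group inference, and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`critmf` quantifies two signatures of scale-free ("critical") dynamics in a
single time series. A signal whose fluctuations have no preferred temporal
scale obeys, over some range of dyadic scales $2^{j}$, the multifractal
scaling relation for its wavelet p-leaders $\ell^{(p)}(j,k)$:
structure functions $S(j,q) = \frac{1}{n_j}\sum_k \ell^{(p)}(j,k)^q$ behave
as $2^{j\,\zeta(q)}$, and the scaling function $\zeta(q)$ admits a
polynomial (log-cumulant) expansion around $q = 0$:

$$\zeta(q) = c_1 q + c_2 \frac{q^2}{2} + \dots$$

* $c_1$ is the **self-similarity** exponent: the location of the apex of
  the singularity spectrum $D(h)$ and a Hurst-type exponent. $c_1 > 0.5$
  means persistent, memory-bearing fluctuations.
* $c_2$ is the **multifractality** parameter: for a concave $\zeta$,
  $c_2 \le 0$, with $c_2 = 0$ monofractal (a single Hölder exponent) and
  more negative $c_2$ meaning a wider spectrum of local regularities. In
  the second-order (log-normal) approximation
  $D(h) = 1 + (h - c_1)^2 / (2 c_2)$, with full support width
  $M = 2\sqrt{-2 c_2}$ (`legendre_spectrum()`).

Estimation follows the wavelet p-leader and bootstrap multifractal recipe:
per-scale cumulants of log-leaders, $C_1(j) = \mathrm{mean}(\ln \ell)$ and
$C_2(j) = \mathrm{var}(\ln \ell)$, are regressed linearly on $j$ over a
scaling range $[j_1, j_2]$ and the slopes divided by $\ln 2$
(`log_cumulants()`). P-leaders aggregate coefficient energy over the
3-neighborhood of each dyadic interval across all finer scales with weight
$2^{j'-j}$; $p = \infty$ recovers classical leaders (supremum), finite $p$
extends validity to negative local regularity. $p = 2$ is the default
(comparable to detrended fluctuation analysis exponents); $p = 4$ is
exposed for sensitivity analyses; both are available in every stage.

# Choices the estimator makes

The estimation chain involves several conventions that the literature
leaves open; `critmf` fixes them as follows.

* **Wavelet**: Daubechies with $N_\psi = 3$ vanishing moments
  (`wavelet_order = 3`), the standard choice in the wavelet-leader
  literature: enough moments to cancel smooth trends up to quadratic, short
  enough support to limit border loss. Orders 1–5 are available.
* **Normalization**: L1 — pyramid coefficients are multiplied by
  $2^{-j/2}$, so that $\zeta(q)$ slopes read directly in the Hurst
  convention ($\zeta(q) = qH$ for fractional Brownian motion).
* **Boundary policy**: any coefficient whose filter support overlaps the
  signal edge is marked invalid, and a leader is kept only if every
  contributing coefficient at every scale of its 3-neighborhood is
  interior. Border effects otherwise masquerade as spurious singularities.
* **Regression weighting**: weighted least squares with weights
  proportional to the number of usable leaders $n_j$ (coarse scales carry
  fewer leaders and more variance); `weighting = "uniform"` is available.
* **Minimum regularity**: finite-$p$ leaders are well-defined when the
  coefficient-based scaling exponent $\eta(p) > 0$. The package estimates
  $\eta(p)$ from the coefficient structure function over the fit range and
  sets a warning flag on failure; it does **not** fractionally integrate
  the signal, since the analysis targets raw (arrhythmic) records.
* **Positive $\hat c_2$**: mathematically a multifractal cannot have
  $c_2 > 0$, but finite-length estimates can land there, and on clinical
  data such values are informative (signals neither multifractal nor
  monofractal). Estimates are therefore reported as-is with a
  `positive_c2` flag — never clipped. `report_positive_c2()` summarizes
  their prevalence per group; `legendre_spectrum()` refuses them.
* **Cumulant orders**: only $c_1$ and $c_2$; higher log-cumulants add
  little information at these record lengths.
* **Degenerate leaders**: exact-zero aggregates (constant segments) are
  dropped and counted; if more than 10% of a fit scale's leaders are
  dropped, estimation aborts with a diagnostic rather than return a value
  dominated by censoring.

# Choosing the scaling range

The fit range $[j_1, j_2]$ must cover the log-linear portion of the power
spectrum. `select_scaling_range()` automates the usual visual procedure:
Welch PSD (Hann window, 50% overlap), candidate windows of at least 3
consecutive dyadic scales mapped to frequency bands through
$f = 3 S_f / (4 \cdot 2^{j})$, a log–log linear fit in each band
(windows with fewer than 8 PSD bins are skipped as unfittable), and the
window with the highest $R^2$ wins. The full diagnostics table is returned
so the choice can be overridden; at $S_f = 600$ Hz, pinning
$(j_1, j_2) = (7, 10)$ reproduces the 3.5–0.4 Hz delta-range configuration
typical of resting-state source analyses. An $R^2$ below 0.9 sets a
warning flag (e.g. white noise has no scaling range to find).

At desk scales the recovery experiments use mid-range scales directly
($j_1 = 4$, $j_2 = 11$ at $n = 2^{16}$; $j_1 = 3$, $j_2 = 8$–$9$ at
$n = 2^{14}$), keeping at least 8 leaders per fit scale.

# Bootstrap confidence intervals

Leaders are strongly dependent in time and across scales, so the CI uses a
circular block bootstrap on the time axis: contiguous blocks of leader
positions are resampled at the coarsest fit scale and the same time blocks
are propagated to finer scales through the dyadic index mapping (one coarse
position covers $2^{j_2-j}$ positions at scale $j$), preserving
within-block alignment across scales. Each block spans
$2 \cdot 2^{j_2-j_1+1}$ positions at the finest fit scale — 4 indices after
contraction to the coarsest scale — and at least 4 blocks are required.
This single-level scheme is a deliberate simplification of double-bootstrap
variants; percentile intervals at $n = 2^{16}$ with 100 replicates cover a
known fBm exponent in at least 80% of signals at nominal 95% (asserted by
the suite), and coverage degrades at shorter record lengths — treat the
intervals as stability diagnostics, not exact frequentist statements.

# Group statistics

`maxstat_permutation()` implements two-tailed, unpaired **pseudo t-tests**
with maximum-statistics correction: the statistic is
$t = (\bar x_A - \bar x_B) / (\sqrt{s_A^2/n_A + s_B^2/n_B} + s_0)$, where
the regularizer $s_0$ — the median across nodes of the per-node
standard-error term, computed once from the observed grouping and held
fixed across permutations — stabilizes nodes with accidentally tiny
variance (the variance-smoothing convention of nonparametric neuroimaging
statistics). Group labels are permuted with sizes preserved, the maximum of
$|t|$ across nodes forms the null, and corrected p-values use the add-one
convention $(1+b)/(m+1)$, so the smallest attainable p is $1/(m+1)$ and
the familywise mask is exact under exchangeability. When
$\binom{n}{n_A} \le$ `n_perm` the assignments are enumerated exhaustively
(exact test, noted in the result). ROI-level tables come from
`roi_average()` (arithmetic mean of member nodes per subject).

Clinical associations use node-wise Pearson correlations with
Benjamini–Hochberg FDR across nodes (`clinical_correlation()`), plus an
uncorrected Spearman variant for monotone robustness checks; subjects with
missing covariates are dropped pairwise. `mediation_check()` reports the
score–dose correlation and its $R^2$ — a purely descriptive quantification
of variance shared with medication, not a causal mediation model.

# Decoding

`decoding_null_threshold()` asks a deliberately simple question per node:
can a one-feature logistic regression separate the groups out-of-sample?
Folds are stratified (each fold's class ratio within one subject of the
global ratio), features standardized by training-fold statistics only, and
the decoding accuracy (DA) is the mean over folds of the test-fold
proportion correct. Probability ties at 0.5 resolve toward the class with
the lower label index. The significance threshold — the "chance level" —
is not 0.5: it is the $1-\alpha$ quantile of the permutation distribution
of the **maximum** DA across nodes, with labels reshuffled and folds
re-derived on every one of the `n_perm` shuffles. Two behaviors are worth
knowing: the threshold grows with the size of the node family (a max-null
property, tested on nested subsets), and the null DA distribution is
centred slightly **below** 0.5 (cross-validation's pessimistic bias under
the permutation null; the suite asserts the mean over 1000 shuffles lies
in [0.45, 0.53]). The
latter is harmless because observed DA is compared against a quantile of
that same null. The IRLS fit caps coefficients under perfect separation
(predictions are already saturated) and falls back to the majority class
for constant training features.

# The synthetic cohort generator

No clinical MEG recordings ship with the package; instead, every stage is
validated against synthetic cohorts whose ground truth is known exactly.

* `simulate_fgn_fbm()` draws exact-covariance fractional Gaussian noise by
  circulant embedding and cumulates to fBm ($c_1 = H$, $c_2 = 0$).
* `simulate_mrw()` builds a multifractal random walk: fGn increments
  modulated by $\exp(\omega)$ with
  $\mathrm{Cov}(\omega_i, \omega_j) = \lambda^2 \ln^+\!\big(L/(|i-j|+1)\big)$,
  horizon $L = n/8$, mean $-\mathrm{Var}(\omega)/2$. Theoretical
  log-cumulants $c_1 = H + \lambda^2/2$, $c_2 = -\lambda^2$; both were
  confirmed by ensemble estimation with the package's own estimator before
  being frozen into test expectations (the suite asserts mean $\hat c_2$
  over 20 seeds at $n = 2^{16}$ within ±0.03 of $-\lambda^2$). The
  horizon and mean
  conventions vary across the literature; fixing them makes the recovery
  targets well-defined. Non-positive-definite embeddings (short signals)
  fall back to eigenvalue clipping, i.e. approximate spectral synthesis,
  with a logged message.
* `simulate_cohort()` assembles a two-group cohort on an abstract 1-D node
  axis $x \in [0,1]$ (a rostro-caudal stand-in; no cortical geometry):
  controls get $H(x)$ rising 0.5→0.9 and $\lambda^2(x)$ rising
  0.001→0.02, so true $c_1$ ascends and true $c_2$ descends front-to-back
  — landing inside the value ranges typical of resting-state source
  estimates. Patients get the same gradients attenuated by factor 0.6
  about their midpoint, $+0.10$ on $H$ over the frontal fifth of nodes,
  and $\lambda^2$ reduced by 0.008 over the posterior fifth
  (multifractality pushed toward 0) — the direction and rough magnitude of
  the group alterations the pipeline is meant to detect. Per-subject
  variation is a global $H$ shift (SD 0.05) plus a multiplicative
  $\lambda^2$ factor (SD 0.15). Clinical scores exist for patients only:
  a negative-symptom score coupled linearly to mean frontal true $c_1$ and
  a positive-symptom score to mean posterior true $c_2$, with noise set so
  the regional correlation is ≈ 0.8; medication dose correlates with the
  negative-symptom score at 0.55 (shared variance ≈ 0.3). Default cohort:
  25 + 25 subjects at 600 Hz — with $2^{14}$ samples and 50 nodes as the
  desk-scale configuration (full-study dimensions of minutes × thousands
  of nodes scale up without code changes).
* `simulate_feature_cohort()` emulates the *output* of the estimation
  stage directly (ground-truth node profile + Gaussian estimator noise,
  SD 0.1, matching the observed dispersion of desk-scale $\hat c_1$).
  Calibration and power studies of the statistics and decoding stages use
  it because they need hundreds of cohorts; under the null the two groups
  are exchangeable by construction, which is the only property familywise
  calibration relies on.

What the generator does **not** emulate: oscillatory (rhythmic)
components, sensor noise and source-reconstruction leakage, spatial
correlation between nodes, non-Gaussian estimator error, or any real
cortical geometry. Passing tests demonstrate the estimators and inference
machinery are correct on processes with known scaling truth — not that any
particular clinical effect exists.

# Reproducibility and problem sizes

Every stochastic routine takes an explicit seed and uses a local RNG
stream (`with_seed`), so the caller's RNG state is never disturbed; cohort
signals get per-subject × per-node seeds derived deterministically from
the master seed. `run_pipeline()` with a fixed `run_config()` produces
byte-identical TSV/JSON outputs across runs — asserted in the suite.

The validation suite runs at deliberate desk scales: recovery ensembles of
20 seeds at $n = 2^{16}$; calibration on 200 (t-map) and 100 (decoding)
null cohorts of 25 + 25 subjects × 50 nodes with 500 and 200 permutations;
power on 50 cohorts with a 1.5-SD effect at 5 of 50 nodes. Observed power
is reported by the suite rather than pinned, since it moves with every
generator constant.

# Known limitations

* The familywise machinery assumes exchangeability under the null;
  covariate-driven group differences (age, sex, medication) are not
  adjusted for.
* The parabolic $D(h)$ is a second-order approximation; strongly
  asymmetric spectra are summarized only through $(c_1, c_2)$.
* The block bootstrap is a single-level approximation (see above);
  its intervals modestly undercover at short record lengths.
* Scale selection by $R^2$ maximization can be fooled by narrowband
  artifacts adjacent to the scaling range — inspect the diagnostics table
  when in doubt.
* P-leader estimates with the minimum-regularity warning set
  ($\eta(p) \le 0$) should be treated as exploratory; the package warns
  but does not correct.
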