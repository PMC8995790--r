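#' Single-signal log-cumulant analysis
#'
#' Convenience wrapper chaining [dwt_coefficients()], [p_leaders()] and
#' [log_cumulants()] (optionally [bootstrap_ci()] and
#' [select_scaling_range()]) for one signal.
#'
#' @param signal a [signal_vector()] or numeric vector.
#' @param p p-leader exponent (2 default, 4 or `Inf`).
#' @param j1,j2 fit range; if either is `NULL` the range is chosen
#'   automatically from the PSD via [select_scaling_range()].
#' @param wavelet_order Daubechies vanishing moments (default 3).
#' @param weighting regression weighting, `"counts"` or `"uniform"`.
#' @param n_boot bootstrap replicates for the CI; 0 disables.
#' @param seed seed for the bootstrap stream.
#' @param sampling_rate used when `signal` is a bare numeric vector.
#' @return a `critmf_logcum` object.
#' @export
analyze_signal <- function(signal, p = 2, j1 = NULL, j2 = NULL,
                           wavelet_order = 3, weighting = "counts",
                           n_boot = 0, seed = NULL, sampling_rate = 1) {
  sig <- as_signal(signal, sampling_rate)
  w <- dwt_coefficients(sig, wavelet_order = wavelet_order)
  if (is.null(j1) || is.null(j2)) {
    rng <- select_scaling_range(sig)
    j1 <- j1 %||% rng$j1
    j2 <- j2 %||% min(rng$j2, w$j_max)
  }
  pl <- p_leaders(w, p = p)
  est <- log_cumulants(pl, j1 = j1, j2 = j2, weighting = weighting)
  if (n_boot > 0)
    est <- bootstrap_ci(pl, j1, j2, n_boot = n_boot, seed = seed,
                        weighting = weighting, estimate = est)
  est
}

#' Per-node log-cumulant maps for a whole cohort
#'
#' Runs the wavelet p-leader log-cumulant estimator on every node of every
#' subject of a synthetic cohort (subjects are materialized one at a time,
#' so memory stays flat in the cohort size).
#'
#' @param cohort a `critmf_cohort` from [simulate_cohort()].
#' @param p,j1,j2,wavelet_order,weighting as in [analyze_signal()]; here
#'   `j1`, `j2` must be given explicitly (one shared range for the cohort).
#' @return list: `c1`, `c2` (subjects-by-nodes matrices), `flags`
#'   (positive-c2 and minimum-regularity counts), `params`.
#' @export
analyze_cohort <- function(cohort, p = 2, j1 = 3, j2 = NULL,
                           wavelet_order = 3, weighting = "counts") {
  stopifnot(inherits(cohort, "critmf_cohort"))
  spec <- cohort$spec
  n <- nrow(cohort$subjects)
  if (is.null(j2)) {
    w0 <- dwt_coefficients(subject_signals(cohort, 1)[1, ],
                           wavelet_order = wavelet_order)
    j2 <- w0$j_max
  }
  c1 <- c2 <- matrix(NA_real_, n, spec$n_nodes)
  pos_c2 <- 0L; min_reg <- 0L
  for (i in seq_len(n)) {
    sigs <- subject_signals(cohort, i)
    for (v in seq_len(spec$n_nodes)) {
      est <- log_cumulants(
        p_leaders(dwt_coefficients(sigs[v, ], wavelet_order = wavelet_order),
                  p = p),
        j1 = j1, j2 = j2, weighting = weighting)
      c1[i, v] <- est$c1
      c2[i, v] <- est$c2
      if (est$flags$positive_c2) pos_c2 <- pos_c2 + 1L
      if (est$flags$min_regularity_warning) min_reg <- min_reg + 1L
    }
  }
  list(c1 = c1, c2 = c2,
       flags = list(n_positive_c2 = pos_c2, n_min_regularity = min_reg),
       params = list(p = p, j1 = j1, j2 = j2, wavelet_order = wavelet_order,
                     weighting = weighting))
}

#' Positive-c2 prevalence report
#'
#' Per group: the count and fraction of subjects whose mean c2 across nodes
#' is positive, plus the per-node frequency of positive c2 values. On a
#' well-resolved multifractal cohort these fractions should be near zero; on
#' a monofractal cohort (true c2 = 0) estimator noise puts them near one
#' half.
#'
#' @param c2_matrix subjects-by-nodes matrix of c2 estimates.
#' @param groups group label per subject.
#' @return list with per-group `n_positive`, `fraction_positive`
#'   (subject-level, from mean c2), and `node_fraction` (per-node positive
#'   frequencies by group).
#' @export
report_positive_c2 <- function(c2_matrix, groups) {
  stopifnot(is.matrix(c2_matrix), length(groups) == nrow(c2_matrix))
  groups <- factor(groups)
  out <- lapply(levels(groups), function(lv) {
    m <- c2_matrix[groups == lv, , drop = FALSE]
    subj_pos <- rowMeans(m) > 0
    list(n_subjects = nrow(m),
         n_positive = sum(subj_pos),
         fraction_positive = mean(subj_pos),
         node_fraction = colMeans(m > 0))
  })
  names(out) <- levels(groups)
  out
}

#' Run configuration for the full pipeline
#'
#' Bundles every tunable of a pipeline run; all values are serialized into
#' the run manifest so a run is self-describing.
#'
#' @param spec a [synthetic_cohort_spec()] (the pipeline's input cohort is
#'   simulated from it; supplying an existing `critmf_cohort` via `cohort`
#'   is also allowed in [run_pipeline()]).
#' @param p p-leader exponent.
#' @param j1,j2 scaling range (`NULL` for automatic selection from the first
#'   subject's first node).
#' @param wavelet_order Daubechies vanishing moments.
#' @param n_perm_stats,n_perm_decoding permutation counts.
#' @param alpha_stats,alpha_decoding,alpha_correlation test levels (defaults
#'   0.001 for the t-maps, 0.05 elsewhere).
#' @param k_folds decoding folds.
#' @param label_map optional node-to-ROI map (data.frame) for ROI-level
#'   tables.
#' @param seed master seed.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return list of class `critmf_run_config`.
#' @export
run_config <- function(spec = synthetic_cohort_spec(), p = 2,
                       j1 = 3, j2 = NULL, wavelet_order = 3,
                       n_perm_stats = 1000, n_perm_decoding = 1000,
                       alpha_stats = 0.001, alpha_decoding = 0.05,
                       alpha_correlation = 0.05, k_folds = 10,
                       label_map = NULL, seed = 1L, out_dir = NULL) {
  stopifnot(alpha_stats > 0, alpha_stats < 1, alpha_decoding > 0,
            alpha_decoding < 1, alpha_correlation > 0, alpha_correlation < 1)
  structure(list(spec = spec, p = p, j1 = j1, j2 = j2,
                 wavelet_order = wavelet_order,
                 n_perm_stats = n_perm_stats,
                 n_perm_decoding = n_perm_decoding,
                 alpha_stats = alpha_stats, alpha_decoding = alpha_decoding,
                 alpha_correlation = alpha_correlation, k_folds = k_folds,
                 label_map = label_map, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "critmf_run_config")
}

#' Full pipeline: simulate, analyze, test, decode, correlate
#'
#' Orchestrates the whole analysis as one reproducible run: cohort
#' simulation (or a user-supplied cohort), per-node log-cumulant maps, group
#' pseudo-t maps with maximum-statistics correction, node-wise decoding with
#' the permutation chance threshold, clinical correlations with FDR, the
#' positive-c2 report, optional ROI averaging, and a JSON-serializable
#' manifest capturing every configurable value and all warnings. Identical
#' configurations (including seeds) reproduce identical results.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-built `critmf_cohort` (skips simulation).
#' @return list of class `critmf_run`: `cohort`, `features` (c1/c2
#'   matrices + flags), `stats` (per-feature `critmf_maxstat`), `decoding`
#'   (per-feature `critmf_decoding`), `correlations`, `mediation`,
#'   `positive_c2`, `roi` (optional ROI-level matrices), `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "critmf_run_config"))
  if (is.null(cohort)) cohort <- simulate_cohort(config$spec)
  stopifnot(inherits(cohort, "critmf_cohort"))
  groups <- cohort$subjects$group
  seed <- config$seed

  feats <- analyze_cohort(cohort, p = config$p, j1 = config$j1,
                          j2 = config$j2,
                          wavelet_order = config$wavelet_order)

  stats_res <- list(
    c1 = maxstat_permutation(feats$c1, groups, n_perm = config$n_perm_stats,
                             alpha = config$alpha_stats,
                             seed = child_seed(seed, 101L)),
    c2 = maxstat_permutation(feats$c2, groups, n_perm = config$n_perm_stats,
                             alpha = config$alpha_stats,
                             seed = child_seed(seed, 102L)))

  dec_res <- list(
    c1 = decoding_null_threshold(feats$c1, groups, k = config$k_folds,
                                 n_perm = config$n_perm_decoding,
                                 alpha = config$alpha_decoding,
                                 seed = child_seed(seed, 201L)),
    c2 = decoding_null_threshold(feats$c2, groups, k = config$k_folds,
                                 n_perm = config$n_perm_decoding,
                                 alpha = config$alpha_decoding,
                                 seed = child_seed(seed, 202L)))

  subj <- cohort$subjects
  cors <- list()
  for (cov in intersect(c("sans", "saps", "medication_mg"), names(subj))) {
    if (sum(is.finite(subj[[cov]])) >= 5) {
      cors[[paste0("c1_", cov)]] <-
        clinical_correlation(feats$c1, subj[[cov]],
                             alpha = config$alpha_correlation)
      cors[[paste0("c2_", cov)]] <-
        clinical_correlation(feats$c2, subj[[cov]],
                             alpha = config$alpha_correlation)
    }
  }
  med <- if (all(c("sans", "medication_mg") %in% names(subj)) &&
             sum(is.finite(subj$sans) & is.finite(subj$medication_mg)) >= 3)
    mediation_check(score = subj$sans, dose = subj$medication_mg) else NULL

  roi <- NULL
  if (!is.null(config$label_map)) {
    roi <- list(c1 = roi_average(feats$c1, config$label_map),
                c2 = roi_average(feats$c2, config$label_map))
  }

  pos <- report_positive_c2(feats$c2, groups)

  manifest <- list(
    package_version = as.character(utils::packageVersion("critmf")),
    seed = seed,
    cohort_spec = unclass(config$spec),
    analysis = feats$params,
    n_perm_stats = config$n_perm_stats,
    n_perm_decoding = config$n_perm_decoding,
    alpha = list(stats = config$alpha_stats,
                 decoding = config$alpha_decoding,
                 correlation = config$alpha_correlation),
    k_folds = config$k_folds,
    s0 = list(c1 = stats_res$c1$s0, c2 = stats_res$c2$s0),
    warnings = list(positive_c2_estimates = feats$flags$n_positive_c2,
                    min_regularity = feats$flags$n_min_regularity,
                    positive_c2_subject_fraction =
                      lapply(pos, `[[`, "fraction_positive")))

  res <- structure(list(cohort = cohort, features = feats,
                        stats = stats_res, decoding = dec_res,
                        correlations = cors, mediation = med,
                        positive_c2 = pos, roi = roi, manifest = manifest),
                   class = "critmf_run")
  if (!is.null(config$out_dir)) write_run_outputs(res, config$out_dir)
  res
}

#' @export
print.critmf_run <- function(x, ...) {
  cat("<critmf_run>\n")
  cat(sprintf("  subjects: %d, nodes: %d\n", nrow(x$features$c1),
              ncol(x$features$c1)))
  cat(sprintf("  t-map significant nodes: c1 %d, c2 %d (alpha = %g)\n",
              sum(x$stats$c1$mask), sum(x$stats$c2$mask), x$stats$c1$alpha))
  cat(sprintf("  decoding significant nodes: c1 %d (max DA %.2f, chance %.2f), c2 %d (max DA %.2f, chance %.2f)\n",
              sum(x$decoding$c1$mask), max(x$decoding$c1$da),
              x$decoding$c1$threshold, sum(x$decoding$c2$mask),
              max(x$decoding$c2$da), x$decoding$c2$threshold))
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the TSV/JSON artifacts of a pipeline run
#'
#' Per-feature node tables (c1/c2 values, t, corrected p, masks, DA),
#' per-subject feature matrices, correlation tables and the JSON run
#' manifest, all as plain text.
#'
#' @param run a `critmf_run`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(run, out_dir) {
  stopifnot(inherits(run, "critmf_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in c("c1", "c2")) {
    node_tab <- data.frame(
      node = seq_along(run$stats[[f]]$t),
      t = run$stats[[f]]$t,
      p_corrected = run$stats[[f]]$p_corrected,
      t_mask = as.integer(run$stats[[f]]$mask),
      da = run$decoding[[f]]$da,
      da_p_corrected = run$decoding[[f]]$p_corrected,
      da_mask = as.integer(run$decoding[[f]]$mask))
    write_tsv(node_tab, file.path(out_dir, paste0("nodes_", f, ".tsv")))
    feat <- as.data.frame(run$features[[f]])
    names(feat) <- sprintf("node_%03d", seq_len(ncol(feat)))
    write_tsv(cbind(run$cohort$subjects[, c("id", "group")], feat),
              file.path(out_dir, paste0("features_", f, ".tsv")))
  }
  for (nm in names(run$correlations))
    write_tsv(as.data.frame(run$correlations[[nm]]),
              file.path(out_dir, paste0("correlation_", nm, ".tsv")))
  write_tsv(run$cohort$subjects, file.path(out_dir, "subjects.tsv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
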