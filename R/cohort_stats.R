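col_vars <- function(m) {
  n <- nrow(m)
  (colSums(m^2) - n * colMeans(m)^2) / (n - 1)
}

#' Average node-level features into ROI-level features
#'
#' Per subject and ROI, the arithmetic mean of the member-node feature
#' values.
#'
#' @param features subjects-by-nodes numeric matrix; columns are nodes in
#'   `node_id` order 1..N unless `colnames` give node ids.
#' @param labels data.frame with columns `node_id`, `roi_id` and optionally
#'   `roi_name` (see [synthetic_label_map()]).
#' @return subjects-by-ROIs matrix with ROI names as column names.
#' @export
roi_average <- function(features, labels) {
  stopifnot(is.matrix(features), all(c("node_id", "roi_id") %in% names(labels)))
  node_ids <- if (!is.null(colnames(features)))
    suppressWarnings(as.integer(colnames(features))) else seq_len(ncol(features))
  pos <- match(node_ids, labels$node_id)
  if (anyNA(pos))
    stop("unmapped node id(s): ", paste(node_ids[is.na(pos)], collapse = ", "))
  roi <- labels$roi_id[pos]
  out <- t(rowsum(t(features), group = roi) / as.vector(table(roi)))
  nm <- if ("roi_name" %in% names(labels))
    labels$roi_name[match(sort(unique(roi)), labels$roi_id)]
  else as.character(sort(unique(roi)))
  colnames(out) <- nm
  out
}

#' Pseudo t statistic for a two-group comparison
#'
#' `t = (meanA - meanB) / (sqrt(varA/nA + varB/nB) + s0)`: the unpaired
#' Welch-type statistic with a variance regularizer `s0` added to the
#' denominator (the variance-smoothing convention of nonparametric
#' neuroimaging statistics). `s0 = 0` recovers the plain Welch form and
#' errors on constant data.
#'
#' @param a,b numeric vectors (one node) or subjects-by-nodes matrices with
#'   matching node columns.
#' @param s0 regularizer, >= 0.
#' @return numeric vector of statistics, one per node.
#' @export
pseudo_t <- function(a, b, s0 = 0) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 1)
  if (!is.matrix(b)) b <- matrix(b, ncol = 1)
  stopifnot(ncol(a) == ncol(b), nrow(a) >= 2, nrow(b) >= 2, s0 >= 0)
  se <- sqrt(col_vars(a) / nrow(a) + col_vars(b) / nrow(b))
  if (s0 == 0 && any(se == 0))
    stop("zero denominator: constant data with s0 = 0")
  drop((colMeans(a) - colMeans(b)) / (se + s0))
}

## |pseudo t| for every column assignment in `idxA` (list of index vectors)
maxstat_t_matrix <- function(X, idxA_list, s0) {
  n <- nrow(X)
  X2 <- X^2
  vapply(idxA_list, function(ia) {
    nA <- length(ia); nB <- n - nA
    sA <- colSums(X[ia, , drop = FALSE]);  sA2 <- colSums(X2[ia, , drop = FALSE])
    mA <- sA / nA
    mB <- (colSums(X) - sA) / nB
    vA <- (sA2 - nA * mA^2) / (nA - 1)
    vB <- (colSums(X2) - sA2 - nB * mB^2) / (nB - 1)
    abs((mA - mB) / (sqrt(pmax(vA, 0) / nA + pmax(vB, 0) / nB) + s0))
  }, numeric(ncol(X)))
}

#' Group comparison with maximum-statistics permutation correction
#'
#' Two-tailed, unpaired pseudo t-tests at every node, familywise-corrected
#' by the permutation distribution of the maximum `|t|` across nodes: group
#' labels are permuted (group sizes preserved), the per-node statistic is
#' recomputed, and the max over nodes recorded per permutation. The
#' regularizer `s0` is fixed once from the observed grouping (median across
#' nodes of the per-node standard-error term) and held constant across
#' permutations. Corrected p-values use the add-one convention
#' `(1 + b) / (n_perm + 1)`. When the number of distinct group assignments
#' does not exceed `n_perm`, the null is enumerated exhaustively and the
#' test is exact.
#'
#' @param features subjects-by-nodes matrix.
#' @param groups length-`nrow(features)` two-level factor (or coercible).
#' @param n_perm number of permutations (>= 100).
#' @param alpha familywise level.
#' @param seed optional integer seed for the permutation stream.
#' @param s0 override for the regularizer; default computed from the data.
#' @return object of class `critmf_maxstat`: `t` (signed observed
#'   statistics), `p_corrected`, `threshold` (the `1 - alpha` quantile of
#'   the null max distribution), `mask` (`p_corrected <= alpha`),
#'   `null_max`, `s0`, `exact`, `n_perm`, `alpha`, `seed`.
#' @export
maxstat_permutation <- function(features, groups, n_perm = 1000,
                                alpha = 0.05, seed = NULL, s0 = NULL) {
  stopifnot(is.matrix(features))
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(groups) == nrow(features))
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- nrow(features)
  idxA <- which(groups == levels(groups)[1])
  nA <- length(idxA)
  if (nA < 2 || n - nA < 2) stop("each group needs >= 2 subjects")

  A <- features[idxA, , drop = FALSE]
  B <- features[-idxA, , drop = FALSE]
  if (is.null(s0))
    s0 <- stats::median(sqrt(col_vars(A) / nrow(A) + col_vars(B) / nrow(B)))
  t_obs <- pseudo_t(A, B, s0 = s0)

  n_distinct <- choose(n, nA)
  exact <- is.finite(n_distinct) && n_distinct <= n_perm
  perms <- if (exact) {
    asplit(utils::combn(n, nA), 2)
  } else {
    with_seed(seed, replicate(n_perm, sample.int(n, nA), simplify = FALSE))
  }
  tmat <- maxstat_t_matrix(features, perms, s0)       # nodes x n_perm
  null_max <- apply(tmat, 2, max)
  m <- length(null_max)
  p_corr <- vapply(abs(t_obs), function(tt) (1 + sum(null_max >= tt)) / (m + 1),
                   numeric(1))
  thr <- sort(null_max)[ceiling((1 - alpha) * m)]
  structure(list(t = t_obs, p_corrected = p_corr, threshold = thr,
                 mask = p_corr <= alpha, null_max = null_max, s0 = s0,
                 exact = exact, n_perm = m, alpha = alpha, seed = seed),
            class = "critmf_maxstat")
}

#' @export
print.critmf_maxstat <- function(x, ...) {
  cat(sprintf("<critmf_maxstat> %d nodes, %d permutations%s, alpha = %g\n",
              length(x$t), x$n_perm, if (x$exact) " (exact)" else "", x$alpha))
  cat(sprintf("  s0 = %.4g, |t| threshold = %.3f, significant nodes: %d\n",
              x$s0, x$threshold, sum(x$mask)))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list: `q` (adjusted p-values, monotone) and `mask` (`q <= alpha`).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, mask = q <= alpha)
}

#' Node-wise correlation of a feature map with a clinical covariate
#'
#' Pearson correlations between each node's feature values and a clinical
#' covariate, with Benjamini-Hochberg FDR control across nodes; or Spearman
#' rank correlations reported uncorrected (exploratory convention). Subjects
#' with a missing covariate are excluded pairwise (count reported).
#'
#' @param features subjects-by-nodes matrix.
#' @param covariate numeric vector, one value per subject; may contain `NA`.
#' @param method `"pearson"` (FDR-corrected) or `"spearman"` (uncorrected).
#' @param alpha level for the FDR mask (Pearson) or raw-p mask (Spearman).
#' @return data.frame of class `critmf_correlation` with per-node `r`, `p`,
#'   `q` (NA for Spearman), `mask`; attributes `method`, `n_used`,
#'   `n_dropped`, `corrected`.
#' @export
clinical_correlation <- function(features, covariate,
                                 method = c("pearson", "spearman"),
                                 alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(is.matrix(features), length(covariate) == nrow(features))
  keep <- is.finite(covariate)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("clinical_correlation: dropped %d subject(s) with missing covariate",
                    n_dropped))
  if (sum(keep) < 5) stop("covariate present for fewer than 5 subjects")
  y <- covariate[keep]
  if (stats::sd(y) == 0) stop("constant covariate")
  X <- features[keep, , drop = FALSE]

  res <- t(apply(X, 2, function(x) {
    ct <- stats::cor.test(x, y, method = method, exact = FALSE)
    c(ct$estimate, ct$p.value)
  }))
  out <- data.frame(node = seq_len(ncol(X)), r = res[, 1], p = res[, 2])
  if (method == "pearson") {
    fdr <- bh_fdr(out$p, alpha)
    out$q <- fdr$q
    out$mask <- fdr$mask
  } else {
    out$q <- NA_real_
    out$mask <- out$p <= alpha
  }
  attr(out, "method") <- method
  attr(out, "corrected") <- method == "pearson"
  attr(out, "n_used") <- sum(keep)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("critmf_correlation", "data.frame")
  out
}

#' Shared variance between a clinical score and medication dose
#'
#' Descriptive mediation check: reports the Pearson correlation between the
#' score and the dose and the R-squared of the score regressed on the dose,
#' quantifying how much of a feature-score association could be shared with
#' medication. No causal claim is made.
#'
#' @param c_feature per-subject feature values (carried through for
#'   reporting; may be NULL).
#' @param score clinical score per subject.
#' @param dose medication dose per subject.
#' @return list: `r_score_dose`, `r_squared`, `n`.
#' @export
mediation_check <- function(c_feature = NULL, score, dose) {
  keep <- is.finite(score) & is.finite(dose)
  score <- score[keep]; dose <- dose[keep]
  if (length(score) < 3) stop("need >= 3 complete score/dose pairs")
  if (stats::sd(score) == 0 || stats::sd(dose) == 0) stop("constant input")
  r <- stats::cor(score, dose)
  list(r_score_dose = r, r_squared = r^2, n = length(score))
}
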