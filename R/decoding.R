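#' Stratified fold assignment
#'
#' Partitions subjects into `k` test folds while keeping each fold's class
#' composition within one subject of the global ratio: within each class,
#' members are shuffled and dealt round-robin onto the folds starting from a
#' random offset. Deterministic for a given seed.
#'
#' @param groups two-level factor (or coercible) of class labels.
#' @param k number of folds.
#' @param seed optional integer seed (local stream).
#' @return integer vector of fold ids in `1..k`, one per subject.
#' @export
stratified_folds <- function(groups, k, seed = NULL) {
  groups <- factor(groups)
  n <- length(groups)
  sizes <- table(groups)
  if (any(sizes < k))
    stop(sprintf("class smaller than k = %d (sizes: %s)", k,
                 paste(sizes, collapse = ", ")))
  folds <- integer(n)
  with_seed(seed, {
    rot <- sample.int(k, 1L) - 1L   # random global rotation
    off <- 0L
    for (lv in sample(levels(groups))) {
      idx <- sample(which(groups == lv))
      # stagger the round-robin start so the classes' overfull folds do not
      # pile up: fold totals stay as equal as possible
      folds[idx] <- ((seq_along(idx) - 1L + off + rot) %% k) + 1L
      off <- off + (length(idx) %% k)
    }
  })
  folds
}

#' Cross-validated decoding accuracy of a single feature
#'
#' Stratified k-fold cross-validation of a two-parameter logistic-regression
#' classifier (intercept + one coefficient) on one feature. The feature is
#' standardized by the training-fold mean and SD only (no leakage); test
#' subjects are classified at the probability threshold 0.5 (an exact tie
#' resolves to the class with the lower label index). A constant training
#' feature falls back to the majority class. The decoding accuracy (DA) is
#' the mean over folds of the test-fold proportion correct.
#'
#' @param feature numeric vector, one value per subject.
#' @param groups two-level factor (or coercible).
#' @param k number of folds (default 10).
#' @param seed optional integer seed controlling the fold assignment.
#' @param folds optional explicit fold assignment (overrides `seed`).
#' @return DA in `[0, 1]`.
#' @export
decode_single_feature <- function(feature, groups, k = 10, seed = NULL,
                                  folds = NULL) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(feature) == length(groups))
  if (is.null(folds)) folds <- stratified_folds(groups, k, seed)
  y <- as.integer(groups) - 1L
  cpp_cv_da(as.numeric(feature), y, as.integer(folds), as.integer(k))
}

#' Node-wise decoding with a permutation-derived chance threshold
#'
#' Computes the cross-validated decoding accuracy at every node, then builds
#' a null distribution by shuffling the class labels `n_perm` times and
#' re-running the full stratified k-fold procedure at every node, recording
#' the maximum DA across nodes per shuffle (maximum statistics across the
#' node family). The familywise "chance level" is the `1 - alpha` quantile
#' of that null max distribution, and a node is flagged when its observed DA
#' exceeds it. Fold assignments are re-derived from the permuted labels on
#' every shuffle, all seeded from the master seed.
#'
#' @param features subjects-by-nodes matrix.
#' @param groups two-level factor (or coercible).
#' @param k folds (default 10).
#' @param n_perm number of label shuffles (>= 100).
#' @param alpha familywise level.
#' @param seed master integer seed.
#' @return object of class `critmf_decoding`: `da` (per-node DA),
#'   `threshold`, `mask` (`da > threshold`), `null_max` (length `n_perm`),
#'   `p_corrected` (add-one max-statistics p per node), `k`, `alpha`,
#'   `seed`.
#' @export
decoding_null_threshold <- function(features, groups, k = 10, n_perm = 1000,
                                    alpha = 0.05, seed = NULL) {
  stopifnot(is.matrix(features))
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(groups) == nrow(features))
  if (n_perm < 100) stop("n_perm must be >= 100")
  y <- as.integer(groups) - 1L
  X <- apply(features, 2, as.numeric)

  folds0 <- stratified_folds(groups, k, seed = child_seed(seed %||% 0L, 0L))
  da <- cpp_decode_matrix(X, y, as.integer(folds0), as.integer(k))

  null_max <- numeric(n_perm)
  base <- seed %||% 0L
  for (b in seq_len(n_perm)) {
    yb <- with_seed(child_seed(base, b, 1L), sample(y))
    fb <- stratified_folds(factor(yb), k, seed = child_seed(base, b, 2L))
    null_max[b] <- max(cpp_decode_matrix(X, yb, as.integer(fb), as.integer(k)))
  }
  thr <- sort(null_max)[ceiling((1 - alpha) * n_perm)]
  p_corr <- vapply(da, function(d) (1 + sum(null_max >= d)) / (n_perm + 1),
                   numeric(1))
  structure(list(da = da, threshold = thr, mask = da > thr,
                 null_max = null_max, p_corrected = p_corr,
                 k = k, n_perm = n_perm, alpha = alpha, seed = seed),
            class = "critmf_decoding")
}

#' @export
print.critmf_decoding <- function(x, ...) {
  cat(sprintf("<critmf_decoding> %d nodes, %d-fold CV, %d permutations\n",
              length(x$da), x$k, x$n_perm))
  cat(sprintf("  chance threshold (alpha = %g): DA = %.3f; significant nodes: %d; max DA = %.3f\n",
              x$alpha, x$threshold, sum(x$mask), max(x$da)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
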