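## Daubechies scaling filters (orthonormal, sum = sqrt(2)), indexed by the
## number of vanishing moments of the associated wavelet. Standard published
## constants; db1 is Haar.
.db_scaling <- list(
  `1` = c(0.70710678118654757, 0.70710678118654757),
  `2` = c(0.48296291314453416, 0.83651630373780794,
          0.22414386804201339, -0.12940952255126037),
  `3` = c(0.33267055295008263, 0.80689150931109255, 0.45987750211849154,
          -0.13501102001025458, -0.085441273882026658, 0.035226291885709533),
  `4` = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.032883011666885197, -0.010597401785069032),
  `5` = c(0.16010239797419293, 0.60382926979718965, 0.72430852843777294,
          0.13842814590132074, -0.24229488706638203, -0.032244869584638375,
          0.077571493840045719, -0.0062414902127982744, -0.012580751999081999,
          0.0033357252854737712)
)

daubechies_filters <- function(vanishing_moments) {
  h <- .db_scaling[[as.character(vanishing_moments)]]
  if (is.null(h))
    stop("wavelet_order must be one of ", paste(names(.db_scaling), collapse = ", "))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)  # quadrature mirror: g_k = (-1)^k h_{L-1-k}
  list(h = h, g = g, length = L)
}

#' Discrete wavelet coefficients across dyadic scales
#'
#' Computes the decimated Daubechies wavelet transform of a signal and returns
#' L1-normalized detail coefficients `d(j, k)` for scales `j = 1 .. j_max`
#' (L1 normalization multiplies the orthonormal pyramid output by `2^(-j/2)`,
#' the convention under which scaling exponents of self-similar processes read
#' directly as Hurst-type exponents). Coefficients whose filter support
#' overlaps the signal edge are marked invalid and excluded from all
#' downstream counts and statistics.
#'
#' @param signal a [signal_vector()] or numeric vector.
#' @param wavelet_order number of vanishing moments of the Daubechies wavelet
#'   (1-5); default 3.
#' @param j_max coarsest scale. Default: deepest scale retaining at least 8
#'   interior coefficients.
#' @param sampling_rate used only when `signal` is a bare numeric vector.
#' @return object of class `critmf_dwt`: per-scale coefficient vectors,
#'   validity masks, interior counts `n_j`, and metadata.
#' @examples
#' w <- dwt_coefficients(rnorm(2^12), wavelet_order = 3)
#' sapply(w$n_valid, identity)
#' @export
dwt_coefficients <- function(signal, wavelet_order = 3, j_max = NULL,
                             sampling_rate = 1) {
  sig <- as_signal(signal, sampling_rate)
  x <- sig$samples
  n <- length(x)
  flt <- daubechies_filters(wavelet_order)
  L <- flt$length

  max_depth <- 0L
  v <- c(1, n)
  repeat {
    v2 <- c(ceiling((v[1] + L - 1) / 2), floor(v[2] / 2))
    if (v2[2] - v2[1] + 1 < 8) break
    max_depth <- max_depth + 1L
    v <- v2
  }
  if (is.null(j_max)) j_max <- max_depth
  if (j_max < 1) stop("signal too short for even one scale with this wavelet")
  if (j_max > max_depth)
    stop(sprintf("signal too short for j_max = %d (max usable depth %d)",
                 j_max, max_depth))

  coef <- vector("list", j_max)
  valid <- vector("list", j_max)
  n_valid <- integer(j_max)
  a <- x
  v_lo <- 1; v_hi <- n
  for (j in seq_len(j_max)) {
    # full convolution c[k] = sum_t f[t] a[k - t + 1]; keep even indices so
    # position k at scale j sits over positions (2k-1, 2k) at scale j-1
    ca <- conv_full(a, flt$h)
    cd <- conv_full(a, flt$g)
    idx <- seq.int(2L, length(ca), by = 2L)
    d <- cd[idx] * 2^(-j / 2)          # L1 normalization
    a <- ca[idx]
    # d_j[i] = c[2i] depends on previous-level positions (2i - L + 1) .. 2i
    i_all <- seq_along(d)
    lo_j <- ceiling((v_lo + L - 1) / 2)
    hi_j <- floor(v_hi / 2)
    ok <- i_all >= lo_j & i_all <= hi_j
    coef[[j]] <- d
    valid[[j]] <- ok
    n_valid[j] <- sum(ok)
    v_lo <- lo_j; v_hi <- hi_j
  }

  structure(list(coefficients = coef, valid = valid, n_valid = n_valid,
                 wavelet_order = wavelet_order, j_max = j_max,
                 n_samples = n, sampling_rate = sig$sampling_rate),
            class = "critmf_dwt")
}

conv_full <- function(a, f) {
  # linear convolution, output length n + L - 1
  n <- length(a); L <- length(f)
  if (n >= 64L) {
    m <- n + L - 1L
    Re(stats::fft(stats::fft(c(a, numeric(m - n))) *
                  stats::fft(c(f, numeric(m - L))), inverse = TRUE)) / m
  } else {
    out <- numeric(n + L - 1L)
    for (t in seq_len(L)) out[t:(t + n - 1L)] <- out[t:(t + n - 1L)] + f[t] * a
    out
  }
}

#' @export
print.critmf_dwt <- function(x, ...) {
  cat(sprintf("<critmf_dwt> db%d, %d scales, %d samples @ %g Hz\n",
              x$wavelet_order, x$j_max, x$n_samples, x$sampling_rate))
  cat("  interior coefficients per scale:",
      paste(x$n_valid, collapse = " "), "\n")
  invisible(x)
}

#' Map a dyadic scale to its representative frequency
#'
#' `f = 3 * Sf / (4 * 2^j)`: the centre frequency attributed to dyadic scale
#' `j` at sampling rate `Sf`. Strictly decreasing in `j` (halving per scale)
#' and linear in `Sf`. At 600 Hz, scales 7 and 10 correspond to 3.5 Hz and
#' 0.4 Hz (to one decimal), the delta-band scaling range typical of
#' resting-state source signals.
#'
#' @param j dyadic scale index (>= 1), vectorized.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @return frequency in Hz.
#' @examples
#' scale_to_frequency(7, 600)   # 3.515625
#' scale_to_frequency(10, 600)  # 0.439...
#' @export
scale_to_frequency <- function(j, sampling_rate) {
  if (any(j < 1)) stop("scale index j must be >= 1")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  3 * sampling_rate / (4 * 2^j)
}
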