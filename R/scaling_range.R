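## Welch-averaged periodogram: Hann-windowed overlapping segments.
welch_psd <- function(x, sampling_rate, n_seg = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(n_seg)) n_seg <- 2^max(6L, floor(log2(n)) - 3L)
  n_seg <- min(n_seg, n)
  step <- max(1L, floor(n_seg * (1 - overlap)))
  starts <- seq.int(1L, n - n_seg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_seg) / (n_seg + 1))
  wnorm <- sum(win^2)
  nf <- floor(n_seg / 2)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + n_seg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(stats::fft(seg))^2 / (wnorm * sampling_rate)
    acc <- acc + sp[2:(nf + 1L)]
  }
  list(freq = (1:nf) * sampling_rate / n_seg, psd = acc / length(starts))
}

#' Select the log-linear scaling range from the power spectral density
#'
#' Computes a Welch PSD, maps candidate windows of consecutive dyadic scales
#' to frequency bands via [scale_to_frequency()], fits `log10 PSD` against
#' `log10 f` inside each band, and returns the window maximizing the
#' coefficient of determination. This automates the visual identification of
#' the log-linear PSD portion that fixes `(j1, j2)`; the full diagnostics
#' table is returned so a user can override the choice (e.g. pin
#' `(j1, j2) = (7, 10)` at 600 Hz).
#'
#' @param signal a [signal_vector()] or numeric vector.
#' @param candidate_min_width minimum number of dyadic scales in a window
#'   (window covers `j1..j2`, width `j2 - j1 + 1`).
#' @param r2_floor windows below this R-squared trigger `low_r2` warning flag.
#' @param j_range optional `c(min, max)` scale indices to consider; default
#'   spans every scale whose band is resolvable in the PSD.
#' @param sampling_rate used when `signal` is a bare numeric vector.
#' @return list: `j1`, `j2`, `slope` (log-log PSD slope in the chosen band),
#'   `r_squared`, `warning_low_r2`, and `diagnostics` (one row per candidate
#'   window).
#' @export
select_scaling_range <- function(signal, candidate_min_width = 3,
                                 r2_floor = 0.9, j_range = NULL,
                                 sampling_rate = 1) {
  sig <- as_signal(signal, sampling_rate)
  ps <- welch_psd(sig$samples, sig$sampling_rate)
  fmin <- min(ps$freq); fmax <- max(ps$freq)
  js <- 1:30
  f_j <- scale_to_frequency(js, sig$sampling_rate)
  avail <- js[f_j >= fmin & f_j <= fmax]
  if (!is.null(j_range)) avail <- avail[avail >= j_range[1] & avail <= j_range[2]]
  if (length(avail) < 4) stop("fewer than 4 dyadic scales resolvable in the PSD")

  rows <- list()
  for (a in avail) for (b in avail) {
    if (b - a + 1 < candidate_min_width || b <= a) next
    lo <- scale_to_frequency(b, sig$sampling_rate)
    hi <- scale_to_frequency(a, sig$sampling_rate)
    sel <- ps$freq >= lo & ps$freq <= hi
    if (sum(sel) < 8) next   # too few bins make R2 meaningless
    lf <- log10(ps$freq[sel]); lp <- log10(ps$psd[sel])
    fit <- stats::lm.fit(cbind(1, lf), lp)
    ssr <- sum(fit$residuals^2)
    sst <- sum((lp - mean(lp))^2)
    rows[[length(rows) + 1L]] <- data.frame(
      j1 = a, j2 = b, f_lo_hz = lo, f_hi_hz = hi, n_bins = sum(sel),
      slope = fit$coefficients[2],
      r_squared = if (sst > 0) 1 - ssr / sst else 0)
  }
  diag <- do.call(rbind, rows)
  rownames(diag) <- NULL
  best <- diag[which.max(diag$r_squared), ]
  list(j1 = best$j1, j2 = best$j2, slope = best$slope,
       r_squared = best$r_squared,
       warning_low_r2 = best$r_squared < r2_floor,
       diagnostics = diag)
}
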