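# Independent brute-force oracles and object factories shared across tests.

# Naive O(n L) DWT by explicit nested loops: d_j[k] = sum_t g[t] a[2k-t+1],
# L1-normalized. Independent of the FFT-based fast path.
naive_dwt <- function(x, wavelet_order, j_max) {
  flt <- critmf:::daubechies_filters(wavelet_order)
  h <- flt$h; g <- flt$g; L <- length(h)
  a <- x
  out <- vector("list", j_max)
  for (j in seq_len(j_max)) {
    n <- length(a)
    nd <- floor((n + L - 1) / 2)
    d <- a2 <- numeric(nd)
    for (k in seq_len(nd)) {
      s1 <- 0; s2 <- 0
      for (t in seq_len(L)) {
        i <- 2L * k - t + 1L
        if (i >= 1L && i <= n) { s1 <- s1 + g[t] * a[i]; s2 <- s2 + h[t] * a[i] }
      }
      d[k] <- s1 * 2^(-j / 2); a2[k] <- s2
    }
    out[[j]] <- d
    a <- a2
  }
  out
}

# Brute-force p = Inf leader at scale j, position k: enumerate every
# coefficient whose dyadic interval lies inside the 3-neighborhood of
# lambda(j, k) at any scale j' <= j.
brute_leader_inf <- function(coef_list, j, k) {
  vals <- numeric(0)
  for (jp in seq_len(j)) {
    r <- 2^(j - jp)
    kk <- ((k - 2) * r + 1):((k + 1) * r)
    kk <- kk[kk >= 1 & kk <= length(coef_list[[jp]])]
    vals <- c(vals, abs(coef_list[[jp]][kk]))
  }
  max(vals)
}

# Brute-force Benjamini-Hochberg step-up: find the largest k with
# p_(k) <= k/m * alpha and reject the k smallest; adjusted p by the
# step-up minimum construction.
bh_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * alpha)
  mask <- logical(m)
  if (length(k)) mask[o[seq_len(max(k))]] <- TRUE
  qs <- pmin(rev(cummin(rev(ps * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- qs
  list(q = q, mask = mask)
}

# Factories for hand-built coefficient / leader containers.
make_dwt <- function(coef_list, wavelet_order = 3, sampling_rate = 1) {
  structure(list(
    coefficients = coef_list,
    valid = lapply(coef_list, function(d) rep(TRUE, length(d))),
    n_valid = lengths(coef_list),
    wavelet_order = wavelet_order, j_max = length(coef_list),
    n_samples = length(coef_list[[1]]) * 2L, sampling_rate = sampling_rate),
    class = "critmf_dwt")
}

make_leaders <- function(values_list, p = 2) {
  structure(list(
    p = p, leaders = values_list,
    valid = lapply(values_list, function(v) rep(TRUE, length(v))),
    n_usable = lengths(values_list),
    n_dropped = integer(length(values_list)),
    coef_structure = rep(NA_real_, length(values_list)),
    j_max = length(values_list), wavelet_order = 3,
    n_samples = length(values_list[[1]]) * 2L, sampling_rate = 1),
    class = "critmf_leaders")
}

# Shared desk-scale estimation settings.
est_c1c2 <- function(x, p = 2, j1 = 3, j2 = 9, ...) {
  est <- log_cumulants(p_leaders(dwt_coefficients(x, ...), p = p),
                       j1 = j1, j2 = j2)
  c(c1 = est$c1, c2 = est$c2)
}
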