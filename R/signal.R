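#' Construct a signal vector
#'
#' Lightweight container for one single-channel time series: the samples and
#' the sampling rate. All multifractal routines accept either this class or a
#' bare numeric vector (then `sampling_rate` defaults to 1 Hz).
#'
#' @param samples numeric vector of finite samples (arbitrary units).
#' @param sampling_rate sampling rate in Hz, > 0.
#' @return an object of class `critmf_signal`.
#' @examples
#' x <- signal_vector(rnorm(1024), sampling_rate = 600)
#' length(x$samples)
#' @export
signal_vector <- function(samples, sampling_rate = 1) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("signal contains non-finite samples")
  if (length(sampling_rate) != 1L || !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  structure(list(samples = samples, sampling_rate = as.numeric(sampling_rate)),
            class = "critmf_signal")
}

#' @export
print.critmf_signal <- function(x, ...) {
  cat(sprintf("<critmf_signal> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

## coerce numeric or critmf_signal to a samples/rate pair
as_signal <- function(x, sampling_rate = 1) {
  if (inherits(x, "critmf_signal")) return(x)
  signal_vector(x, sampling_rate)
}

#' Read a single-channel series from a TSV file (one value per line)
#'
#' @param path file path.
#' @param sampling_rate sampling rate in Hz to attach to the signal.
#' @return a [signal_vector()].
#' @export
read_signal_tsv <- function(path, sampling_rate = 1) {
  signal_vector(scan(path, what = numeric(), quiet = TRUE), sampling_rate)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is restored afterwards. seed = NULL leaves the global stream
## untouched (and advances it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## derive a reproducible child seed < 2^31 from a master seed and stream tags
child_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed %% 2147483647)
  for (t in tags) s <- (s * 48271 + as.double(t) + 1) %% 2147483647
  as.integer(s)
}
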