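# Exact simulation of fractional Gaussian noise (fGn) and fractional
# Brownian motion (fBm) by circulant embedding of the fGn autocovariance.
# These serve as ground truth for validating the spectral Hurst estimator.

#' Simulation specification for fractional Gaussian noise
#'
#' Bundles the parameters of an fGn sample path: the Hurst exponent `hurst`
#' (strictly inside (0,1)), the increment standard deviation `sigma`, the
#' number of samples `length`, the sampling interval in seconds, and the RNG
#' seed that makes the draw reproducible.
#'
#' @param hurst Hurst exponent, in the open interval (0, 1).
#' @param sigma Standard deviation of the increments (arbitrary units, > 0).
#' @param length Number of samples (>= 8).
#' @param sampling_interval Sampling interval in seconds (> 0). Irrelevant to
#'   the generator itself; it only scales the frequency axis downstream.
#' @param seed Integer seed for the random draw.
#' @return An object of class `fgn_spec`.
#' @examples
#' spec <- fgn_spec(hurst = 0.7, length = 512, seed = 1)
#' ts <- simulate_fgn(spec)
#' @export
fgn_spec <- function(hurst, sigma = 1, length = 1024, sampling_interval = 1,
                     seed = 1L) {
  if (!is.numeric(hurst) || length(hurst) != 1L || !is.finite(hurst) ||
      hurst <= 0 || hurst >= 1) {
    stop("`hurst` must be a single number strictly inside (0, 1)")
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  length <- as.integer(length)
  if (is.na(length) || length < 8L) stop("`length` must be an integer >= 8")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0) {
    stop("`sampling_interval` must be > 0")
  }
  structure(
    list(hurst = hurst, sigma = sigma, length = length,
         sampling_interval = sampling_interval, seed = as.integer(seed)),
    class = "fgn_spec"
  )
}

#' Uniformly sampled time series
#'
#' Minimal container for a real-valued signal with a sampling interval; the
#' shape every estimator in the package consumes.
#'
#' @param values Numeric vector of at least 2 finite values.
#' @param sampling_interval Sampling interval in seconds (> 0).
#' @return An object of class `fei_ts` with fields `values` and
#'   `sampling_interval`.
#' @export
time_series <- function(values, sampling_interval) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a time series needs at least 2 samples")
  if (!all(is.finite(values))) stop("time series values must all be finite")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0) {
    stop("`sampling_interval` must be > 0")
  }
  structure(list(values = values, sampling_interval = sampling_interval),
            class = "fei_ts")
}

#' Autocovariance of fractional Gaussian noise
#'
#' Closed-form covariance
#' \deqn{\gamma(k) = \frac{\sigma^2}{2}\left(|k-1|^{2H} - 2|k|^{2H} + |k+1|^{2H}\right)}
#' for lags `k = 0..max_lag`. At H = 0.5 this is white noise
#' (\eqn{\gamma(k) = 0} for k > 0); for H > 0.5 all lags are positively
#' correlated (long-range persistence), for H < 0.5 the lag-1 covariance is
#' negative (anti-persistence).
#'
#' @param hurst Hurst exponent in (0, 1).
#' @param sigma Increment standard deviation (> 0).
#' @param max_lag Largest lag (>= 0).
#' @return Numeric vector of length `max_lag + 1`, `gamma(0)` first.
#' @examples
#' fgn_autocovariance(0.5, 1, 3)   # c(1, 0, 0, 0)
#' @export
fgn_autocovariance <- function(hurst, sigma, max_lag) {
  if (!is.numeric(hurst) || hurst <= 0 || hurst >= 1) {
    stop("`hurst` must be strictly inside (0, 1)")
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  max_lag <- as.integer(max_lag)
  if (is.na(max_lag) || max_lag < 0L) stop("`max_lag` must be >= 0")
  k <- 0:max_lag
  (sigma^2 / 2) * (abs(k - 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                     (k + 1)^(2 * hurst))
}

# Eigenvalues of the circulant embedding of an autocovariance sequence.
# `acov` must cover lags 0..m/2 where m is the embedding size (power of two).
# Exposed internally so the negative-eigenvalue guard is testable.
circulant_embedding_eigenvalues <- function(acov) {
  m <- 2L * (length(acov) - 1L)
  circ <- c(acov, acov[(length(acov) - 1L):2L])
  stopifnot(length(circ) == m)
  Re(stats::fft(circ))
}

# Embedding grid: next power of two >= 2*(n-1), chosen for FFT efficiency
# and exactness of the circulant construction.
embedding_size <- function(n) {
  2^ceiling(log2(max(2L * (n - 1L), 2L)))
}

# Guard on the embedding spectrum: the fGn embedding is nonnegative
# definite in theory, so a materially negative eigenvalue means the
# covariance input is broken; clipping would corrupt ground-truth validity.
check_embedding_eigenvalues <- function(lambda, tol = 1e-8) {
  if (min(lambda) < -tol * max(abs(lambda))) {
    stop("circulant embedding produced a negative eigenvalue (min = ",
         format(min(lambda)), "); double the embedding grid rather than ",
         "clipping the spectrum")
  }
  pmax(lambda, 0)
}

# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards
# so simulation calls are reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Core circulant-embedding sampler: returns an n x n_paths matrix of exact
# fGn sample paths. The embedding of the fGn covariance is nonnegative
# definite in theory; a materially negative eigenvalue indicates a broken
# covariance input and is a hard error (clipping would corrupt ground truth).
fgn_sample_matrix <- function(hurst, sigma, n, n_paths, tol = 1e-8) {
  m <- embedding_size(n)
  acov <- fgn_autocovariance(hurst, sigma, m %/% 2L)
  lambda <- check_embedding_eigenvalues(
    circulant_embedding_eigenvalues(acov), tol)
  half <- m %/% 2L
  # Hermitian-symmetric complex Gaussian spectrum with variance lambda/m
  w <- matrix(0 + 0i, nrow = m, ncol = n_paths)
  w[1L, ] <- sqrt(lambda[1L] / m) * stats::rnorm(n_paths)
  w[half + 1L, ] <- sqrt(lambda[half + 1L] / m) * stats::rnorm(n_paths)
  idx <- 2L:half
  a <- matrix(stats::rnorm(length(idx) * n_paths), length(idx), n_paths)
  b <- matrix(stats::rnorm(length(idx) * n_paths), length(idx), n_paths)
  w[idx, ] <- sqrt(lambda[idx] / (2 * m)) * complex(real = a, imaginary = b)
  w[m:(half + 2L), ] <- Conj(w[idx, ])
  x <- Re(stats::mvfft(w))
  x[seq_len(n), , drop = FALSE]
}

#' Simulate fractional Gaussian noise
#'
#' Draws an exact sample path of fGn with the autocovariance given by
#' [fgn_autocovariance()], using circulant embedding (embedding size: next
#' power of two at least `2 * (length - 1)`). Exact means the finite sample
#' has precisely the target covariance, not an approximation. Deterministic
#' given `spec$seed`. A negative embedding eigenvalue beyond numerical
#' tolerance raises an error instructing to double the embedding grid; it is
#' never silently clipped.
#'
#' @param spec An [fgn_spec()].
#' @return A [time_series()] of length `spec$length`.
#' @export
simulate_fgn <- function(spec) {
  stopifnot(inherits(spec, "fgn_spec"))
  x <- with_seed(spec$seed,
                 fgn_sample_matrix(spec$hurst, spec$sigma, spec$length, 1L))
  time_series(x[, 1L], spec$sampling_interval)
}

#' Simulate fractional Brownian motion
#'
#' The cumulative sum of a simulated fGn path: the first value equals the
#' first increment and `diff()` of the output recovers the fGn path exactly.
#' fBm is non-stationary with stationary increments; its extended Hurst
#' exponent lies in (1, 2) when estimated with the spectral pipeline.
#'
#' @inheritParams simulate_fgn
#' @return A [time_series()] of length `spec$length`.
#' @export
simulate_fbm <- function(spec) {
  incr <- simulate_fgn(spec)
  time_series(cumsum(incr$values), spec$sampling_interval)
}

#' Write a time series to a two-column TSV
#'
#' Plain-text export (`time_s`, `value`) for inspection; no binary format.
#'
#' @param ts A [time_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "fei_ts"))
  df <- data.frame(
    time_s = (seq_along(ts$values) - 1) * ts$sampling_interval,
    value = ts$values
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
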