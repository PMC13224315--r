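# Spectral Hurst estimation: Welch PSD, log-log spectral-index regression,
# H = (1 + beta)/2, extended-Hurst classification, voxelwise maps and ROI
# aggregation.

# Segment length for the Welch scheme: L such that `n_segments` segments at
# the given overlap tile N samples (for 50% overlap and 8 segments this is
# floor(2N/9)); remainder samples at the series end are dropped.
welch_segment_length <- function(n, n_segments, overlap_fraction) {
  floor(n / ((n_segments - 1) * (1 - overlap_fraction) + 1))
}

# Welch PSD of the columns of X (one series per column), shared sampling
# interval. Periodic Hann taper, per-segment mean removal, one-sided density
# normalised so that sum(power * df) ~= signal variance (Parseval, up to
# taper correction). Returns frequencies and a (n_bins x n_series) matrix.
welch_psd_matrix <- function(X, sampling_interval, n_segments = 8L,
                             overlap_fraction = 0.5) {
  n <- nrow(X)
  L <- welch_segment_length(n, n_segments, overlap_fraction)
  if (L < 8L) {
    n_min <- ceiling(8 * ((n_segments - 1) * (1 - overlap_fraction) + 1))
    stop("series too short for ", n_segments, " segments at overlap ",
         overlap_fraction, ": each segment would have ", L,
         " samples (< 8); need N >= ", n_min)
  }
  step <- floor(L * (1 - overlap_fraction))
  fs <- 1 / sampling_interval
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)  # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  acc <- matrix(0, L, ncol(X))
  for (i in 0:(n_segments - 1L)) {
    seg <- X[(i * step + 1L):(i * step + L), , drop = FALSE]
    seg <- sweep(seg, 2L, colMeans(seg))
    acc <- acc + Mod(stats::mvfft(seg * w))^2 * scale
  }
  acc <- acc / n_segments
  half <- L %/% 2L
  one_sided <- acc[1:(half + 1L), , drop = FALSE]
  dbl <- rep(2, half + 1L)
  dbl[1L] <- 1
  if (L %% 2L == 0L) dbl[half + 1L] <- 1
  list(frequencies_hz = (0:half) * fs / L,
       power = one_sided * dbl,
       segment_length = L)
}

#' Welch power spectral density estimate
#'
#' Averages tapered periodograms over `n_segments` overlapping segments
#' (default 8 segments at 50% overlap). Segment length is
#' `floor(N / ((n_segments - 1) * (1 - overlap_fraction) + 1))` so the
#' segments tile the series; trailing remainder samples are dropped. Each
#' segment is mean-centred and tapered with a periodic Hann window; the
#' one-sided density is normalised so that the integral of power over
#' frequency approximates the signal variance.
#'
#' @param series A [time_series()], or a numeric vector together with
#'   `sampling_interval`.
#' @param n_segments Number of segments to average (default 8).
#' @param overlap_fraction Fractional overlap between consecutive segments,
#'   in \[0, 1) (default 0.5).
#' @param sampling_interval Sampling interval in seconds; required when
#'   `series` is a bare numeric vector.
#' @return An object of class `psd_estimate` with fields `frequencies_hz`
#'   (0 to Nyquist), `power`, `n_segments`, `overlap_fraction`,
#'   `window_name` and `segment_length`.
#' @export
welch_psd <- function(series, n_segments = 8L, overlap_fraction = 0.5,
                      sampling_interval = NULL) {
  if (inherits(series, "fei_ts")) {
    values <- series$values
    sampling_interval <- series$sampling_interval
  } else {
    values <- as.numeric(series)
    if (is.null(sampling_interval)) {
      stop("`sampling_interval` is required when `series` is a numeric vector")
    }
  }
  if (!is.numeric(overlap_fraction) || overlap_fraction < 0 ||
      overlap_fraction >= 1) {
    stop("`overlap_fraction` must be in [0, 1)")
  }
  if (n_segments < 1L) stop("`n_segments` must be >= 1")
  if (stats::sd(values) == 0) {
    stop("degenerate input: constant series has no spectral content")
  }
  res <- welch_psd_matrix(matrix(values, ncol = 1L), sampling_interval,
                          n_segments, overlap_fraction)
  structure(
    list(frequencies_hz = res$frequencies_hz,
         power = res$power[, 1L],
         n_segments = as.integer(n_segments),
         overlap_fraction = overlap_fraction,
         window_name = "hann",
         segment_length = res$segment_length),
    class = "psd_estimate"
  )
}

#' Fit the spectral index from a PSD
#'
#' Ordinary least-squares fit of `log10(power)` on `log10(frequency)` over
#' all bins with positive frequency and positive power (the zero-frequency
#' bin is excluded because log 0 is undefined). The spectral index is
#' `beta = -slope`, so a `1/f^beta` spectrum yields `beta > 0`.
#'
#' @param psd A `psd_estimate` from [welch_psd()], or any list with
#'   `frequencies_hz` and `power`.
#' @return A list with `beta`, `intercept` (log10 power at log10 f = 0),
#'   `r_squared` and `n_bins` (frequency bins used).
#' @export
fit_spectral_index <- function(psd) {
  f <- psd$frequencies_hz
  p <- psd$power
  use <- f > 0 & p > 0 & is.finite(p)
  if (sum(use) < 3L) {
    stop("insufficient data: need >= 3 bins with positive frequency and ",
         "positive power, have ", sum(use))
  }
  x <- log10(f[use])
  y <- log10(p[use])
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(beta = -slope, intercept = intercept,
       r_squared = max(0, min(1, r2)), n_bins = sum(use))
}

#' Convert a spectral index to a Hurst exponent
#'
#' The spectral index of a power-law PSD relates to the (extended) Hurst
#' exponent as \eqn{H = (1 + \beta)/2}: white noise (`beta = 0`) gives
#' H = 0.5, and `beta = 1` marks the boundary between the fGn and fBm
#' regimes.
#'
#' @param beta Finite spectral index.
#' @return `(1 + beta) / 2`.
#' @export
beta_to_hurst <- function(beta) {
  if (!is.numeric(beta) || any(!is.finite(beta))) {
    stop("`beta` must be finite")
  }
  (1 + beta) / 2
}

#' Classify a signal by its extended Hurst exponent
#'
#' Under the extended-Hurst convention, 0 < H < 1 indicates stationary
#' fractional Gaussian noise and 1 < H < 2 non-stationary fractional
#' Brownian motion; values outside (0, 2) are out of range. The boundary
#' H = 1 is deterministically assigned to fBm.
#'
#' @param hurst Finite extended Hurst exponent.
#' @return One of `"fGn"`, `"fBm"`, `"out_of_range"`.
#' @export
classify_signal <- function(hurst) {
  if (!is.numeric(hurst) || !is.finite(hurst)) stop("`hurst` must be finite")
  if (hurst > 0 && hurst < 1) "fGn"
  else if (hurst >= 1 && hurst < 2) "fBm"
  else "out_of_range"
}

#' Estimate the Hurst exponent of a single time series
#'
#' Full estimator: Welch PSD, log-log OLS spectral index, `H = (1+beta)/2`,
#' extended-Hurst classification.
#'
#' @inheritParams welch_psd
#' @return An object of class `hurst_fit` with fields `beta`, `hurst`,
#'   `intercept`, `r_squared`, `n_bins` and `signal_class`.
#' @examples
#' ts <- simulate_fgn(fgn_spec(hurst = 0.7, length = 1024, seed = 3))
#' hurst_fit(ts)$hurst
#' @export
hurst_fit <- function(series, n_segments = 8L, overlap_fraction = 0.5,
                      sampling_interval = NULL) {
  psd <- welch_psd(series, n_segments, overlap_fraction, sampling_interval)
  fit <- fit_spectral_index(psd)
  h <- beta_to_hurst(fit$beta)
  structure(
    c(fit[c("beta", "intercept", "r_squared", "n_bins")],
      list(hurst = h, signal_class = classify_signal(h))),
    class = "hurst_fit"
  )
}

#' @export
print.hurst_fit <- function(x, ...) {
  cat(sprintf("Hurst fit: H = %.3f (beta = %.3f, %s), r^2 = %.3f over %d bins\n",
              x$hurst, x$beta, x$signal_class, x$r_squared, x$n_bins))
  invisible(x)
}

#' Voxelwise Hurst map of a 4D volume
#'
#' Applies the spectral Hurst estimator to every voxel time series of a 4D
#' array. Voxels whose series is constant, all-zero or non-finite, and
#' voxels whose spectral fit fails, are marked invalid and carry the
#' sentinel value 0 (which downstream ROI averaging skips). NaN values in
#' the input mark their voxel invalid.
#'
#' @param volume4d 4D numeric array (x, y, z, time) with >= 64 time points.
#' @param sampling_interval Repetition time in seconds.
#' @param n_segments,overlap_fraction Welch parameters, see [welch_psd()].
#' @return An object of class `hurst_map`: list with `hurst` (3D array,
#'   invalid voxels 0), `valid` (3D logical), `n_invalid`, and the Welch
#'   parameters used.
#' @export
hurst_map <- function(volume4d, sampling_interval, n_segments = 8L,
                      overlap_fraction = 0.5) {
  d <- dim(volume4d)
  if (length(d) != 4L) stop("`volume4d` must be a 4D array (x, y, z, time)")
  if (d[4L] < 64L) stop("need >= 64 time points, have ", d[4L])
  nvox <- prod(d[1:3])
  X <- matrix(volume4d, nrow = nvox, ncol = d[4L])  # voxels x time
  v_ok <- apply_voxel_validity(X)
  hmap <- numeric(nvox)
  if (any(v_ok)) {
    psd <- welch_psd_matrix(t(X[v_ok, , drop = FALSE]), sampling_interval,
                            n_segments, overlap_fraction)
    f <- psd$frequencies_hz
    use_f <- f > 0
    lx <- log10(f[use_f])
    P <- psd$power[use_f, , drop = FALSE]
    # vectorised log-log OLS per voxel; bins with zero power invalidate a voxel
    bad_power <- colSums(P <= 0 | !is.finite(P)) > 0
    xc <- lx - mean(lx)
    denom <- sum(xc^2)
    ly <- log10(pmax(P, .Machine$double.xmin))
    slope <- as.numeric(crossprod(xc, ly)) / denom
    h <- beta_to_hurst(-slope)
    h[bad_power | !is.finite(h)] <- 0
    hmap[v_ok] <- h
  }
  valid <- v_ok & hmap != 0
  hmap[!valid] <- 0
  structure(
    list(hurst = array(hmap, dim = d[1:3]),
         valid = array(valid, dim = d[1:3]),
         n_invalid = sum(!valid),
         n_segments = as.integer(n_segments),
         overlap_fraction = overlap_fraction,
         sampling_interval = sampling_interval),
    class = "hurst_map"
  )
}

# Voxels (rows) with a usable time series: finite, non-constant, not all zero.
apply_voxel_validity <- function(X) {
  fin <- rowSums(!is.finite(X)) == 0L
  X[!fin, ] <- 0
  rng <- row_range(X)
  fin & (rng[, 2L] > rng[, 1L])
}

# Row-wise min/max without extra dependencies.
row_range <- function(X) {
  cbind(do.call(pmin, as.data.frame(X)), do.call(pmax, as.data.frame(X)))
}

#' Mean Hurst exponent within a grey-matter/MRS region of interest
#'
#' Averages a Hurst map over the intersection of a grey-matter mask and an
#' MRS-voxel mask, using only voxels with a finite non-zero estimate (0 is
#' the invalid-voxel sentinel).
#'
#' @param map A `hurst_map` (or a bare 3D numeric array of H values).
#' @param gm_mask,mrs_mask Binary 3D arrays on the map's lattice.
#' @return Mean H over valid voxels in the mask intersection.
#' @export
roi_mean_hurst <- function(map, gm_mask, mrs_mask) {
  h <- if (inherits(map, "hurst_map")) map$hurst else map
  gm <- as_binary_mask(gm_mask)
  mrs <- as_binary_mask(mrs_mask)
  if (!identical(dim(h), dim(gm)) || !identical(dim(h), dim(mrs))) {
    stop("masks must share the map's lattice")
  }
  inter <- gm & mrs
  if (!any(inter)) stop("empty ROI: the MRS mask does not intersect grey matter")
  vals <- h[inter]
  vals[!is.finite(vals)] <- 0  # NaN coerced to the invalid sentinel
  vals <- vals[vals != 0]
  if (length(vals) == 0L) {
    stop("undefined ROI: every voxel in the mask intersection is invalid")
  }
  mean(vals)
}

as_binary_mask <- function(x) {
  if (is.logical(x)) return(x)
  array(as.numeric(x) > 0.5, dim = dim(x))
}
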