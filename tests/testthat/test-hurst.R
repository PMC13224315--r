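# Welch PSD, spectral-index fit, Hurst conversion, maps and ROI means.

test_that("Welch PSD satisfies Parseval on white noise", {
  set.seed(1)
  x <- rnorm(4096)
  psd <- welch_psd(x, sampling_interval = 1)
  df <- diff(psd$frequencies_hz[1:2])
  expect_equal(sum(psd$power) * df, var(x), tolerance = 0.05)
  expect_equal(psd$frequencies_hz[1], 0)
  expect_equal(max(psd$frequencies_hz), 0.5, tolerance = 1e-12)
  expect_true(all(psd$power >= 0))
})

test_that("Welch PSD localises a pure sinusoid at its frequency", {
  # brute-force DFT oracle: the peak bin must be the one nearest 0.1 Hz
  t <- 0:2047
  x <- sin(2 * pi * 0.1 * t)
  psd <- welch_psd(x, sampling_interval = 1)
  f_peak <- psd$frequencies_hz[which.max(psd$power)]
  expect_equal(f_peak, psd$frequencies_hz[
    which.min(abs(psd$frequencies_hz - 0.1))])
  expect_lt(abs(f_peak - 0.1), diff(psd$frequencies_hz[1:2]))
})

test_that("one-segment Welch equals a directly computed tapered periodogram", {
  set.seed(7)
  x <- rnorm(512)
  psd <- welch_psd(x, n_segments = 1, sampling_interval = 1)
  L <- psd$segment_length
  expect_equal(L, 512)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)
  seg <- (x - mean(x)) * w
  p <- Mod(fft(seg))^2 / sum(w^2)     # fs = 1
  half <- L / 2
  direct <- p[1:(half + 1)] * c(1, rep(2, half - 1), 1)
  expect_equal(psd$power, direct, tolerance = 1e-12)
})

test_that("segment sizing and degenerate inputs error informatively", {
  expect_error(welch_psd(rnorm(30), sampling_interval = 1), "need N >= 36")
  expect_error(welch_psd(rep(3, 500), sampling_interval = 1), "degenerate")
  expect_error(welch_psd(rnorm(100)), "sampling_interval")
  expect_error(welch_psd(rnorm(100), overlap_fraction = 1,
                         sampling_interval = 1), "overlap")
})

test_that("spectral-index fit recovers exact power laws", {
  f <- seq(0.01, 0.33, by = 0.01)
  fit <- fit_spectral_index(list(frequencies_hz = f, power = f^(-1)))
  expect_equal(fit$beta, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_bins, length(f))
  flat <- fit_spectral_index(list(frequencies_hz = f, power = rep(2.5, length(f))))
  expect_equal(flat$beta, 0, tolerance = 1e-12)
  # zero-frequency bin is excluded, not log-transformed
  with_zero <- fit_spectral_index(list(frequencies_hz = c(0, f),
                                       power = c(10, f^(-1))))
  expect_equal(with_zero$beta, 1, tolerance = 1e-12)
  expect_error(fit_spectral_index(list(frequencies_hz = f[1:2],
                                       power = f[1:2])), "insufficient")
})

test_that("fGn spectra have slope near 2H - 1 (H = 0.7, Monte-Carlo)", {
  betas <- vapply(1:100, function(i) {
    ts <- simulate_fgn(fgn_spec(0.7, length = 1024, seed = 300 + i))
    fit_spectral_index(welch_psd(ts))$beta
  }, numeric(1))
  expect_equal(mean(betas), 2 * 0.7 - 1, tolerance = 0.1)
})

test_that("beta-to-H conversion and signal classification follow H=(1+beta)/2", {
  expect_equal(beta_to_hurst(0), 0.5)
  expect_equal(beta_to_hurst(1), 1)
  expect_equal(beta_to_hurst(-0.2), 0.4)
  expect_error(beta_to_hurst(NaN), "finite")
  expect_identical(classify_signal(0.7), "fGn")
  expect_identical(classify_signal(1.3), "fBm")
  expect_identical(classify_signal(2.5), "out_of_range")
  expect_identical(classify_signal(1), "fBm")  # deterministic boundary rule
  expect_identical(classify_signal(-0.1), "out_of_range")
})

test_that("hurst_fit stores H = (1+beta)/2 exactly and a consistent class", {
  for (seed in 1:5) {
    ts <- simulate_fgn(fgn_spec(0.75, length = 512, seed = seed))
    fit <- hurst_fit(ts)
    expect_identical(fit$hurst, (1 + fit$beta) / 2)
    expect_identical(fit$signal_class, classify_signal(fit$hurst))
    expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  }
})

test_that("white-noise phantom maps average to H = 0.5", {
  set.seed(10)
  vol <- array(rnorm(6 * 6 * 6 * 480), c(6, 6, 6, 480))
  map <- hurst_map(vol, sampling_interval = 1.5)
  expect_true(all(map$valid))
  expect_equal(mean(map$hurst), 0.5, tolerance = 0.03)
})

test_that("tissue phantoms preserve the GM > WM > CSF Hurst ordering", {
  dims <- c(6, 6, 6)
  n <- 480
  make_block <- function(h, seed) {
    paths <- fractalEI:::with_seed(seed,
      fractalEI:::fgn_sample_matrix(h, 1, n, prod(dims)))
    array(t(paths), c(dims, n))
  }
  gm <- hurst_map(make_block(0.9, 1), 1.5)
  wm <- hurst_map(make_block(0.7, 2), 1.5)
  csf <- hurst_map(make_block(0.5, 3), 1.5)
  m <- c(gm = mean(gm$hurst), wm = mean(wm$hurst), csf = mean(csf$hurst))
  expect_true(m["gm"] > m["wm"] && m["wm"] > m["csf"])
})

test_that("degenerate voxels carry the invalid sentinel 0", {
  vol <- array(0, c(3, 3, 3, 64))
  map <- hurst_map(vol, 1)
  expect_true(all(map$hurst == 0))
  expect_true(all(!map$valid))
  expect_equal(map$n_invalid, 27)
  # mixed: one live voxel among constants
  vol[1, 1, 1, ] <- rnorm(64)
  map2 <- hurst_map(vol, 1)
  expect_true(map2$valid[1, 1, 1])
  expect_equal(sum(map2$valid), 1)
  expect_error(hurst_map(array(0, c(3, 3, 64)), 1), "4D")
  expect_error(hurst_map(array(0, c(3, 3, 3, 32)), 1), "64")
})

test_that("ROI mean uses only non-zero voxels in the mask intersection", {
  h <- array(0, c(2, 2, 1))
  h[1, 1, 1] <- 0.8
  h[2, 1, 1] <- 1.0
  h[1, 2, 1] <- 0          # invalid sentinel, must be skipped
  gm <- array(TRUE, c(2, 2, 1))
  mrs <- array(c(TRUE, TRUE, TRUE, FALSE), c(2, 2, 1))
  expect_equal(roi_mean_hurst(h, gm, mrs), 0.9)
  # uniform map: identity
  hu <- array(0.73, c(2, 2, 1))
  expect_equal(roi_mean_hurst(hu, gm, mrs), 0.73)
  # disjoint masks
  gm0 <- array(FALSE, c(2, 2, 1))
  expect_error(roi_mean_hurst(h, gm0, mrs), "empty ROI")
  # all-invalid intersection
  hz <- array(0, c(2, 2, 1))
  expect_error(roi_mean_hurst(hz, gm, mrs), "undefined ROI")
  expect_error(roi_mean_hurst(h, array(TRUE, c(3, 3, 1)), mrs), "lattice")
})
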