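# Shared fixtures, built in code.

# Mean estimated H over `reps` independent fGn paths with true exponent `h`.
mean_estimated_hurst <- function(h, n = 1024L, reps = 100L, seed0 = 1L,
                                 cumulative = FALSE) {
  ests <- vapply(seq_len(reps), function(i) {
    spec <- fgn_spec(hurst = h, length = n, seed = seed0 + i)
    ts <- if (cumulative) simulate_fbm(spec) else simulate_fgn(spec)
    hurst_fit(ts)$hurst
  }, numeric(1))
  mean(ests)
}

# Small 3x3x3 mask pair with known overlap counts |A| = |B| = 8, |A^B| = 6.
dice_fixture <- function() {
  a <- array(FALSE, c(3, 3, 3))
  b <- array(FALSE, c(3, 3, 3))
  a[1:8] <- TRUE
  b[3:10] <- TRUE
  list(a = a, b = b)
}

# Minimal QC records table: one row per subject x condition.
qc_records <- function(subject_id, mean_fd, fwhm_slaser = 7, fwhm_mega = 7) {
  data.frame(subject_id = rep(subject_id, each = 2),
             condition = rep(c("rest", "movie"), length(subject_id)),
             mean_fd_mm = mean_fd,
             fwhm_slaser = fwhm_slaser,
             fwhm_mega = fwhm_mega,
             stringsAsFactors = FALSE)
}

# Cohort with zero random-intercept variance, for the OLS-equivalence check.
flat_cohort <- function(n_subjects = 30L, seed = 42L) {
  spec <- cohort_spec(n_subjects = n_subjects, subject_intercept_sd = 0,
                      residual_sd = 0.05, beta_ei = 0.05, seed = seed)
  generate_cohort_table(spec)
}
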