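# E:I ratio, paired tests, correlations, the mixed model and its
# diagnostics, and simulate-refit power.

test_that("E:I ratio is Glx over GABA+", {
  expect_equal(ei_ratio(10, 5), 2)
  expect_equal(ei_ratio(9.84, 5.48), 9.84 / 5.48)
  expect_equal(ei_ratio(3.7, 3.7), 1)
  expect_equal(ei_ratio(c(10, 9), c(5, 3)), c(2, 3))
  expect_error(ei_ratio(-1, 5), "positive")
  expect_error(ei_ratio(10, 0), "positive")
})

test_that("paired contrast matches the closed-form t-test on 3 pairs", {
  rest <- c(1, 2, 3)
  movie <- c(2, 3, 4) + c(0.01, -0.01, 0)
  out <- paired_condition_test(rest, movie)
  d <- movie - rest
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-abs(t_hand), 2), tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$cohens_d, mean(d) / sd(d), tolerance = 1e-12)
  # independent oracle: stats::t.test
  tt <- t.test(movie, rest, paired = TRUE)
  expect_equal(out$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(out$p, tt$p.value, tolerance = 1e-12)
  expect_equal(out$ci95, as.numeric(tt$conf.int), tolerance = 1e-12)
})

test_that("paired contrast is invariant to consistent subject reordering", {
  set.seed(6)
  rest <- rnorm(10)
  movie <- rest + 0.07 + rnorm(10, 0, 0.05)
  a <- paired_condition_test(rest, movie)
  perm <- sample(10)
  b <- paired_condition_test(rest[perm], movie[perm])
  expect_equal(a, b)
})

test_that("a constant paired shift surfaces the degenerate-variance error", {
  rest <- c(0.9, 1.0, 1.1, 1.2)
  expect_error(paired_condition_test(rest, rest + 0.07), "degenerate")
  expect_error(paired_condition_test(1:2, 2:3 + 0.1), "at least 3")
})

test_that("Pearson correlation matches the direct formula and cor.test", {
  x <- c(1.2, 2.5, 3.1, 4.8, 5.0)
  y <- c(2.0, 2.2, 3.9, 4.1, 5.5)
  out <- pearson_corr(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(out$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(out$p, ct$p.value, tolerance = 1e-12)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  expect_error(pearson_corr(x, rep(1, 5)), "degenerate")
})

test_that("mixed-model fit matches OLS when the intercept variance is zero", {
  tab <- flat_cohort(n_subjects = 30, seed = 42)
  fit <- fit_lmm(tab)
  tab$condition <- factor(tab$condition, levels = c("movie", "rest"))
  ols <- lm(hurst ~ ei + condition + mean_fd_mm + fwhm_slaser + fwhm_mega +
              freq_shift_slaser + freq_shift_mega, data = tab)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-4)
  expect_lt(fit$random_intercept_var, 1e-3)
})

test_that("fixed effects are recovered within 2 SE on a large cohort", {
  spec <- cohort_spec(n_subjects = 200, hurst_intercept = 1.3,
                      beta_rest = -0.07, beta_ei = 0.07, seed = 7)
  fit <- fit_lmm(generate_cohort_table(spec))
  co <- fit$coefficients
  truth <- c("(Intercept)" = 1.3, ei = 0.07, conditionrest = -0.07)
  for (term in names(truth)) {
    row <- co[co$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 2 * row$std_error)
  }
  expect_lte(fit$r2_marginal, fit$r2_conditional)
  expect_lte(fit$r2_conditional, 1)
})

test_that("balanced subject replication leaves point estimates unchanged", {
  tab <- generate_cohort_table(cohort_spec(n_subjects = 12, seed = 3))
  dup <- tab
  dup$subject_id <- paste0(dup$subject_id, "_copy")
  # exact invariance holds under ML; REML's df correction shifts the
  # variance components (and hence the GLS estimates) slightly
  fit1 <- fit_lmm(tab, REML = FALSE)
  fit2 <- fit_lmm(rbind(tab, dup), REML = FALSE)
  expect_equal(fit2$coefficients$estimate, fit1$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(fit2$n_subjects, 2 * fit1$n_subjects)
  reml2 <- fit_lmm(rbind(tab, dup))
  expect_equal(reml2$coefficients$estimate, fit1$coefficients$estimate,
               tolerance = 0.05)
})

test_that("rank-deficient designs name the collinear columns", {
  tab <- generate_cohort_table(cohort_spec(n_subjects = 12, seed = 5))
  tab$fwhm_mega <- tab$fwhm_slaser
  expect_error(fit_lmm(tab), "collinear.*fwhm_mega")
})

test_that("Nakagawa R2 components behave at the limits", {
  # intercept-only model: no fixed-effect variance
  tab <- generate_cohort_table(cohort_spec(n_subjects = 15, seed = 9))
  null_fit <- fit_lmm(tab, predictors = character(0))
  expect_equal(null_fit$r2_marginal, 0, tolerance = 1e-10)
  expect_gte(null_fit$r2_conditional, null_fit$r2_marginal)
  # known variance partition: fixed ~0.2, intercept 0.5, residual 0.3
  set.seed(11)
  n <- 1500
  subj <- rep(sprintf("s%03d", 1:n), each = 2)
  cond <- rep(c("rest", "movie"), n)
  x <- rnorm(2 * n, 0, 1)
  u <- rep(rnorm(n, 0, sqrt(0.5)), each = 2)
  hurst <- 1 + sqrt(0.2) * x + u + rnorm(2 * n, 0, sqrt(0.3))
  tab2 <- data.frame(subject_id = subj, condition = cond, hurst = hurst,
                     ei = x, mean_fd_mm = 0.1, fwhm_slaser = 7,
                     fwhm_mega = 7, freq_shift_slaser = 0,
                     freq_shift_mega = 0)
  fit2 <- fit_lmm(tab2, predictors = "ei")
  expect_lt(abs(fit2$r2_marginal - 0.2), 0.03)
  expect_lt(abs(fit2$r2_conditional - 0.7), 0.03)
})

test_that("VIFs match the closed form and car::vif", {
  # two correlated predictors with r = 0.8 give VIF = 1/(1-0.64)
  set.seed(13)
  n <- 4000
  z <- rnorm(n)
  x1 <- z
  x2 <- 0.8 * z + sqrt(1 - 0.64) * rnorm(n)
  tab <- data.frame(subject_id = sprintf("s%d", rep(1:(n / 2), each = 2)),
                    condition = rep(c("rest", "movie"), n / 2),
                    hurst = rnorm(n), ei = x1, mean_fd_mm = x2,
                    fwhm_slaser = rnorm(n), fwhm_mega = rnorm(n),
                    freq_shift_slaser = 0, freq_shift_mega = 0)
  v <- vif(tab, predictors = c("ei", "mean_fd_mm"))
  r <- cor(x1, x2)
  expect_equal(unname(v["ei"]), 1 / (1 - r^2), tolerance = 1e-10)
  expect_equal(unname(v["mean_fd_mm"]), 1 / (1 - r^2), tolerance = 1e-10)
  expect_true(abs(v[["ei"]] - 1 / (1 - 0.64)) < 0.15)
  # independent cross-check against car on the full predictor set
  tab2 <- generate_cohort_table(cohort_spec(n_subjects = 40, seed = 17))
  v2 <- vif(tab2)
  fit <- lm(hurst ~ ei + condition + mean_fd_mm + fwhm_slaser + fwhm_mega +
              freq_shift_slaser + freq_shift_mega,
            data = transform(tab2, condition = factor(condition,
                                                      c("movie", "rest"))))
  expect_equal(unname(v2), unname(car::vif(fit)), tolerance = 1e-8)
  expect_true(all(v2 >= 1))
})

test_that("orthogonal predictors have VIF 1 and duplicates are infinite", {
  tab <- data.frame(subject_id = rep(sprintf("s%d", 1:8), each = 2),
                    condition = rep(c("rest", "movie"), 8),
                    hurst = rnorm(16),
                    a = rep(c(-1, 1), 8), b = rep(c(-1, -1, 1, 1), 4))
  v <- vif(tab, predictors = c("a", "b"))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-12)
  tab$c <- tab$a
  w <- capture_warnings(v2 <- vif(tab, predictors = c("a", "b", "c")))
  expect_true(any(grepl("collinearity", w)))
  expect_true(any(is.infinite(v2)))
})

test_that("power simulation is seeded, bounded and effect-responsive", {
  gen <- cohort_spec(n_subjects = 18, seed = 1)
  p1 <- power_simulation(gen, 0.3, n_sims = 40, seed = 21)
  p2 <- power_simulation(gen, 0.3, n_sims = 40, seed = 21)
  expect_identical(unclass(p1), unclass(p2))
  expect_gte(p1$power, p1$ci95[1])
  expect_lte(p1$power, p1$ci95[2])
  # a very large effect is detected essentially always
  expect_gt(p1$power, 0.8)
  expect_equal(p1$n_simulations + p1$n_failed, 40)
})
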