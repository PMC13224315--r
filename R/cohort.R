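# Subject-level statistics: E:I ratio, paired condition contrasts, Pearson
# correlations, the random-intercept linear mixed-effects model with
# Nakagawa R^2 and VIF diagnostics, and simulate-refit power.

# Fixed-effect predictors of the full model, in reporting order. Condition
# is coded with movie as the reference level so the reported coefficient is
# the rest-vs-movie contrast ("Condition [Rest]").
LMM_PREDICTORS <- c("ei", "condition", "mean_fd_mm", "fwhm_slaser",
                    "fwhm_mega", "freq_shift_slaser", "freq_shift_mega")
CONDITION_LEVELS <- c("movie", "rest")

#' Excitation-inhibition ratio
#'
#' E:I operationalised as the ratio of Glx (glutamate + glutamine, from
#' sLASER) to GABA+ (GABA + macromolecules, from MEGA-PRESS), both in mM.
#'
#' @param glx_mM,gaba_mM Positive metabolite concentrations (vectorised).
#' @return `glx_mM / gaba_mM`.
#' @export
ei_ratio <- function(glx_mM, gaba_mM) {
  if (any(!is.finite(glx_mM)) || any(glx_mM <= 0)) {
    stop("`glx_mM` must be positive")
  }
  if (any(!is.finite(gaba_mM)) || any(gaba_mM <= 0)) {
    stop("`gaba_mM` must be positive")
  }
  glx_mM / gaba_mM
}

#' Paired condition contrast (paired t-test with Cohen's d)
#'
#' Two-sided paired Student's t-test on `movie - rest`, with the paired
#' Cohen's d defined as mean(difference) / sd(difference).
#'
#' @param rest,movie Numeric vectors of equal length >= 3, paired by
#'   subject.
#' @return List with `mean_diff`, `ci95` (length-2), `t`, `df`, `p`,
#'   `cohens_d`.
#' @export
paired_condition_test <- function(rest, movie) {
  if (length(rest) != length(movie)) stop("`rest` and `movie` must be paired")
  n <- length(rest)
  if (n < 3L) stop("need at least 3 pairs")
  d <- movie - rest
  s <- stats::sd(d)
  # relative guard: a constant shift leaves only floating-point residue
  if (s <= 1e-12 * max(abs(d), 1)) {
    stop("degenerate input: zero variance of paired differences ",
         "(mean difference ", format(mean(d)), ")")
  }
  se <- s / sqrt(n)
  tval <- mean(d) / se
  df <- n - 1L
  crit <- stats::qt(0.975, df)
  list(mean_diff = mean(d),
       ci95 = c(mean(d) - crit * se, mean(d) + crit * se),
       t = tval, df = df,
       p = 2 * stats::pt(-abs(tval), df),
       cohens_d = mean(d) / s)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; p from the t transform
#' `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom.
#'
#' @param x,y Finite numeric vectors of equal length >= 3.
#' @return List with `r` and `p`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) return(list(r = sign(r), p = 0))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), n - 2))
}

# Validate and prepare a cohort table for modelling: condition coded with
# movie as reference, complete cases on the model columns.
prepare_cohort_table <- function(table, predictors) {
  req <- unique(c("subject_id", "condition", "hurst", predictors))
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols) > 0L) {
    stop("cohort table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- as.data.frame(table)
  tab$condition <- factor(tab$condition, levels = CONDITION_LEVELS)
  if (any(is.na(tab$condition))) {
    stop("`condition` must be one of: ", paste(CONDITION_LEVELS, collapse = ", "))
  }
  tab <- tab[stats::complete.cases(tab[, req]), , drop = FALSE]
  tab
}

#' Fit the random-intercept linear mixed-effects model
#'
#' REML fit of
#' `hurst ~ ei + condition + mean_fd_mm + fwhm_slaser + fwhm_mega +
#'  freq_shift_slaser + freq_shift_mega + (1 | subject_id)`
#' (or a reduced fixed-effect set via `predictors`). Condition is coded with
#' movie as the reference level, so the reported coefficient is the Rest
#' contrast. Fixed-effect t-tests and 95% CIs use the residual-df
#' approximation `df = n_obs - n_fixed - n_subjects + 1`, adequate for the
#' balanced two-condition design; the convention is recorded in the result.
#'
#' @param table Data frame with one row per subject x condition and columns
#'   `subject_id`, `condition`, `hurst` plus the predictor columns.
#' @param predictors Character vector of fixed-effect columns (default: the
#'   full model). `character(0)` fits the intercept-only null model.
#' @param REML Use restricted maximum likelihood (default TRUE). Maximum
#'   likelihood (`FALSE`) makes fixed-effect estimates exactly invariant to
#'   balanced replication of subjects; REML's degrees-of-freedom correction
#'   perturbs them slightly.
#' @return An object of class `lmm_result`: `coefficients` data frame
#'   (term, estimate, std_error, t, df, p, ci95_low, ci95_high), variance
#'   components, `r2_marginal`, `r2_conditional`, `n_obs`, `n_subjects`,
#'   the fitted `lme4` model, and `df_method`.
#' @export
fit_lmm <- function(table, predictors = LMM_PREDICTORS, REML = TRUE) {
  tab <- prepare_cohort_table(table, predictors)
  n_subjects <- length(unique(tab$subject_id))
  if (n_subjects < 6L || any(table(tab$subject_id) < 2L)) {
    stop("need >= 6 subjects with complete records for both conditions")
  }
  rhs <- if (length(predictors) == 0L) "1" else paste(predictors, collapse = " + ")
  fixed_formula <- stats::as.formula(paste("hurst ~", rhs))
  X <- stats::model.matrix(fixed_formula, tab)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient fixed-effect design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  form <- stats::as.formula(paste("hurst ~", rhs, "+ (1 | subject_id)"))
  fit <- lme4::lmer(form, data = tab, REML = REML,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  p_fixed <- length(beta)
  n_obs <- nrow(tab)
  df <- n_obs - p_fixed - n_subjects + 1L
  if (df < 1L) stop("non-positive residual degrees of freedom")
  tval <- beta / se
  crit <- stats::qt(0.975, df)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_int <- vc$vcov[vc$grp == "subject_id"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  coefs <- data.frame(
    term = names(beta),
    estimate = unname(beta),
    std_error = unname(se),
    t = unname(tval),
    df = df,
    p = unname(2 * stats::pt(-abs(tval), df)),
    ci95_low = unname(beta - crit * se),
    ci95_high = unname(beta + crit * se),
    stringsAsFactors = FALSE
  )
  res <- structure(
    list(coefficients = coefs,
         random_intercept_var = var_int,
         residual_var = var_res,
         n_obs = n_obs,
         n_subjects = n_subjects,
         predictors = predictors,
         df_method = "n_obs - n_fixed - n_subjects + 1",
         model = fit),
    class = "lmm_result"
  )
  r2 <- r2_nakagawa(res)
  res$r2_marginal <- r2[["r2_marginal"]]
  res$r2_conditional <- r2[["r2_conditional"]]
  res
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Linear mixed model: %d obs, %d subjects\n", x$n_obs, x$n_subjects))
  print(x$coefficients, digits = 3, row.names = FALSE)
  cat(sprintf("Random intercept var %.4g, residual var %.4g\n",
              x$random_intercept_var, x$residual_var))
  cat(sprintf("R2 marginal %.3f, conditional %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Nakagawa-Schielzeth variance decomposition for a random-intercept
#' Gaussian model: marginal R^2 is the variance of the fixed-effect
#' predictions over the total (fixed + intercept + residual) variance; the
#' conditional R^2 adds the random-intercept variance to the numerator.
#'
#' @param fit An `lmm_result` from [fit_lmm()].
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "lmm_result"))
  model <- fit$model
  X <- lme4::getME(model, "X")
  pred_fixed <- as.numeric(X %*% lme4::fixef(model))
  var_fixed <- stats::var(pred_fixed)
  total <- var_fixed + fit$random_intercept_var + fit$residual_var
  if (total <= 0) stop("degenerate fit: zero total variance")
  c(r2_marginal = var_fixed / total,
    r2_conditional = (var_fixed + fit$random_intercept_var) / total)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' `j` on the remaining predictors (fixed-effects design only; the condition
#' factor enters as its 0/1 indicator). Perfect collinearity is reported as
#' `Inf` with a warning.
#'
#' @param table Cohort data frame.
#' @param predictors Predictor columns (default: the full model's).
#' @return Named numeric vector of VIFs, all >= 1.
#' @export
vif <- function(table, predictors = LMM_PREDICTORS) {
  if (length(predictors) < 2L) stop("need at least 2 predictors")
  tab <- prepare_cohort_table(table, predictors)
  if (nrow(tab) < length(predictors) + 2L) {
    stop("need at least predictors + 2 complete rows")
  }
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(predictors, collapse = " + "))), tab)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  out <- numeric(ncol(X))
  names(out) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    res <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- if (tot > 0) 1 - sum(res^2) / tot else 1
    if (r2 >= 1 - 1e-12) {
      warning("perfect collinearity for predictor ", colnames(X)[j])
      out[j] <- Inf
    } else {
      out[j] <- 1 / (1 - r2)
    }
  }
  out
}

#' Simulate-refit power for the E:I effect
#'
#' Repeatedly simulates cohorts from the generative model with the E:I
#' coefficient set to `effect_size`, refits the full mixed model, and
#' records whether the E:I coefficient's two-sided p-value falls below
#' `alpha`. Power is the fraction of significant replicates with an exact
#' (Clopper-Pearson) binomial 95% CI. Replicates whose refit fails are
#' excluded and counted. Deterministic given `seed`.
#'
#' @param generative A [cohort_spec()] describing the generative model
#'   (its `beta_ei` is overridden by `effect_size`).
#' @param effect_size E:I fixed-effect coefficient used for simulation
#'   (increase of H per unit increase of E:I).
#' @param n_subjects Number of subjects per simulated cohort (default:
#'   the spec's).
#' @param n_sims Number of simulate-refit replicates (default 1000).
#' @param alpha Two-sided significance level (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `power_result`: `effect_size_beta`,
#'   `n_simulations` (successful refits), `n_failed`, `alpha`, `power`,
#'   `ci95`.
#' @export
power_simulation <- function(generative, effect_size, n_subjects = NULL,
                             n_sims = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(generative, "cohort_spec"))
  if (n_sims < 1L) stop("`n_sims` must be >= 1")
  spec <- generative
  spec$beta_ei <- effect_size
  if (!is.null(n_subjects)) spec$n_subjects <- as.integer(n_subjects)
  sub_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max - 1L, n_sims))
  hits <- 0L
  failed <- 0L
  for (i in seq_len(n_sims)) {
    spec$seed <- sub_seeds[i]
    tab <- generate_cohort_table(spec)
    fit <- tryCatch(fit_lmm(tab), error = function(e) NULL)
    if (is.null(fit)) {
      failed <- failed + 1L
      next
    }
    p <- fit$coefficients$p[fit$coefficients$term == "ei"]
    if (length(p) == 1L && is.finite(p) && p < alpha) hits <- hits + 1L
  }
  n_ok <- n_sims - failed
  if (n_ok < 1L) stop("all power replicates failed to fit")
  ci <- as.numeric(stats::binom.test(hits, n_ok)$conf.int)
  structure(
    list(effect_size_beta = effect_size,
         n_simulations = n_ok,
         n_failed = failed,
         alpha = alpha,
         power = hits / n_ok,
         ci95 = ci),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Power at beta = %.3g: %.1f%% (95%% CI %.1f-%.1f%%, %d sims, %d failed)\n",
              x$effect_size_beta, 100 * x$power, 100 * x$ci95[1],
              100 * x$ci95[2], x$n_simulations, x$n_failed))
  invisible(x)
}
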