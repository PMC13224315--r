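# Multi-echo BOLD T2* mapping and optimal echo combination.
#
# Per voxel, signal across echo times follows a monoexponential decay
# S(TE) = S0 * exp(-TE / T2*). The fit is initialised from the exact
# log-linear solution and refined by damped Gauss-Newton; echoes with
# non-positive signal are dropped so each voxel uses the maximum number of
# reliable echoes.

T2STAR_MIN_MS <- 1
T2STAR_MAX_MS <- 500

#' Multi-echo BOLD series container
#'
#' @param echo_volumes List of 4D arrays, one per echo, sharing lattice and
#'   frame count.
#' @param te_ms Increasing positive echo times in milliseconds, one per echo.
#' @return An object of class `multi_echo_series`.
#' @export
multi_echo_series <- function(echo_volumes, te_ms) {
  if (!is.list(echo_volumes) || length(echo_volumes) < 2L) {
    stop("need at least 2 echoes")
  }
  if (length(te_ms) != length(echo_volumes)) {
    stop("`te_ms` must have one entry per echo volume")
  }
  if (any(te_ms <= 0) || any(diff(te_ms) <= 0)) {
    stop("`te_ms` must be positive and strictly increasing")
  }
  dims <- lapply(echo_volumes, dim)
  if (!all(vapply(dims, function(d) identical(d, dims[[1L]]), logical(1L)))) {
    stop("all echo volumes must share lattice and frame count")
  }
  if (length(dims[[1L]]) != 4L) stop("echo volumes must be 4D arrays")
  structure(list(echo_volumes = echo_volumes, te_ms = as.numeric(te_ms)),
            class = "multi_echo_series")
}

# Exact log-linear solution of the decay model for one voxel (or closed form
# for exactly two echoes). Returns c(s0, t2star_ms) or NAs when the decay is
# non-physical (non-negative slope).
loglinear_decay_fit <- function(signal, te_ms) {
  y <- log(signal)
  xc <- te_ms - mean(te_ms)
  slope <- sum(xc * y) / sum(xc^2)
  if (slope >= 0) return(c(NA_real_, NA_real_))
  t2 <- -1 / slope
  s0 <- exp(mean(y) - slope * mean(te_ms))
  c(s0, t2)
}

#' Fit a monoexponential T2* decay to one voxel's echo signals
#'
#' Minimises the sum of squared residuals of `S(TE) = S0 * exp(-TE/T2*)`,
#' initialised from the exact log-linear regression solution and refined by
#' damped Gauss-Newton (the refinement never increases the SSE relative to
#' the initialisation). Echoes with non-positive signal are dropped so the
#' fit uses the maximum number of reliable echoes; with exactly two reliable
#' echoes the closed-form solution is returned. Fitted T2* outside the
#' physiological window (1, 500) ms marks the voxel invalid.
#'
#' @param signal_by_echo Signal values, one per echo.
#' @param te_ms Echo times in milliseconds.
#' @return List with `s0`, `t2star_ms` (both `NA` on fit failure), `n_used`
#'   (reliable echoes used) and `sse`.
#' @examples
#' fit_monoexponential(100 * exp(-c(12.2, 35.352, 58.504) / 40),
#'                     c(12.2, 35.352, 58.504))
#' @export
fit_monoexponential <- function(signal_by_echo, te_ms) {
  if (length(signal_by_echo) != length(te_ms)) {
    stop("`signal_by_echo` and `te_ms` must have the same length")
  }
  reliable <- is.finite(signal_by_echo) & signal_by_echo > 0
  failed <- list(s0 = NA_real_, t2star_ms = NA_real_,
                 n_used = sum(reliable), sse = NA_real_)
  if (sum(reliable) < 2L) return(failed)
  s <- signal_by_echo[reliable]
  te <- te_ms[reliable]
  init <- loglinear_decay_fit(s, te)
  if (!is.finite(init[2L])) return(failed)
  if (length(s) == 2L) {
    fit <- init  # exact for two points
  } else {
    fit <- gauss_newton_decay(s, te, init)
  }
  t2 <- fit[2L]
  if (!is.finite(t2) || t2 <= T2STAR_MIN_MS || t2 >= T2STAR_MAX_MS) {
    return(failed)
  }
  resid <- fit[1L] * exp(-te / t2) - s
  list(s0 = fit[1L], t2star_ms = t2, n_used = length(s),
       sse = sum(resid^2))
}

# Damped Gauss-Newton refinement of (S0, R = 1/T2*) for one voxel; keeps the
# best SSE seen, so the result is never worse than the initialisation.
gauss_newton_decay <- function(s, te, init, max_iter = 50L, tol = 1e-8) {
  s0 <- init[1L]
  r <- 1 / init[2L]
  sse <- function(s0, r) sum((s0 * exp(-te * r) - s)^2)
  best <- c(s0, r)
  best_sse <- sse(s0, r)
  for (it in seq_len(max_iter)) {
    m <- exp(-te * best[2L])
    resid <- best[1L] * m - s
    j1 <- m
    j2 <- -best[1L] * te * m
    a11 <- sum(j1 * j1); a12 <- sum(j1 * j2); a22 <- sum(j2 * j2)
    g1 <- sum(j1 * resid); g2 <- sum(j2 * resid)
    det <- a11 * a22 - a12^2
    if (!is.finite(det) || abs(det) < 1e-300) break
    d1 <- (a22 * g1 - a12 * g2) / det
    d2 <- (a11 * g2 - a12 * g1) / det
    step <- 1
    improved <- FALSE
    for (halve in 1:20) {
      cand <- c(best[1L] - step * d1, best[2L] - step * d2)
      if (cand[1L] > 0 && cand[2L] > 0) {
        cand_sse <- sse(cand[1L], cand[2L])
        if (is.finite(cand_sse) && cand_sse < best_sse) {
          rel <- (best_sse - cand_sse) / max(best_sse, .Machine$double.xmin)
          best <- cand
          best_sse <- cand_sse
          improved <- TRUE
          if (rel < tol) return(c(best[1L], 1 / best[2L]))
          break
        }
      }
      step <- step / 2
    }
    if (!improved) break
  }
  c(best[1L], 1 / best[2L])
}

#' Voxelwise T2* map from a multi-echo series
#'
#' Fits the monoexponential decay to the temporal mean signal of each echo,
#' voxel by voxel. Voxels whose fit fails or whose T2* falls outside
#' (1, 500) ms are invalid (`NA` in the maps).
#'
#' @param series A [multi_echo_series()].
#' @return An object of class `t2star_map`: list with 3D arrays `t2star_ms`
#'   and `s0`, a logical `valid` array, and `te_ms`.
#' @export
t2star_map <- function(series) {
  stopifnot(inherits(series, "multi_echo_series"))
  d <- dim(series$echo_volumes[[1L]])
  nvox <- prod(d[1:3])
  te <- series$te_ms
  # temporal mean per voxel per echo: nvox x n_echo
  S <- vapply(series$echo_volumes,
              function(v) rowMeans(matrix(v, nrow = nvox)),
              numeric(nvox))
  t2 <- rep(NA_real_, nvox)
  s0 <- rep(NA_real_, nvox)
  ok <- rowSums(!is.finite(S) | S <= 0) == 0L
  if (any(ok)) {
    fits <- vectorised_decay_fit(S[ok, , drop = FALSE], te)
    t2[ok] <- fits$t2star_ms
    s0[ok] <- fits$s0
  }
  # voxels with a dropped echo still get a per-voxel fit on reliable echoes
  partial <- which(!ok & rowSums(is.finite(S) & S > 0) >= 2L)
  for (i in partial) {
    f <- fit_monoexponential(S[i, ], te)
    t2[i] <- f$t2star_ms
    s0[i] <- f$s0
  }
  bad <- !is.finite(t2) | t2 <= T2STAR_MIN_MS | t2 >= T2STAR_MAX_MS
  t2[bad] <- NA_real_
  s0[bad] <- NA_real_
  structure(
    list(t2star_ms = array(t2, d[1:3]), s0 = array(s0, d[1:3]),
         valid = array(!bad, d[1:3]), te_ms = te),
    class = "t2star_map"
  )
}

# Log-linear fit plus damped Gauss-Newton, vectorised over voxels (rows of
# S, all echoes positive). Used for whole-volume maps where a per-voxel
# solver would dominate runtime.
vectorised_decay_fit <- function(S, te, max_iter = 25L, tol = 1e-8) {
  nv <- nrow(S)
  Y <- log(S)
  xc <- te - mean(te)
  slope <- as.numeric(Y %*% xc) / sum(xc^2)
  s0 <- exp(rowMeans(Y) - slope * mean(te))
  r <- -slope                      # 1/T2*; non-physical fits masked below
  live <- slope < 0
  r[!live] <- NA_real_
  best_sse <- rep(NA_real_, nv)
  if (any(live)) {
    M0 <- exp(-outer(r[live], te))
    best_sse[live] <- rowSums((s0[live] * M0 - S[live, , drop = FALSE])^2)
  }
  if (any(live)) {
    idx <- which(live)
    b_s0 <- s0[idx]; b_r <- r[idx]; b_sse <- best_sse[idx]
    Si <- S[idx, , drop = FALSE]
    for (it in seq_len(max_iter)) {
      M <- exp(-outer(b_r, te))
      resid <- b_s0 * M - Si
      J2 <- -b_s0 * M * rep(te, each = length(b_r))
      a11 <- rowSums(M * M)
      a12 <- rowSums(M * J2)
      a22 <- rowSums(J2 * J2)
      g1 <- rowSums(M * resid)
      g2 <- rowSums(J2 * resid)
      det <- a11 * a22 - a12^2
      det[abs(det) < 1e-300] <- NA_real_
      d1 <- (a22 * g1 - a12 * g2) / det
      d2 <- (a11 * g2 - a12 * g1) / det
      step <- rep(1, length(b_r))
      active <- is.finite(d1) & is.finite(d2)
      improved <- rep(FALSE, length(b_r))
      for (halve in 1:12) {
        c_s0 <- b_s0 - step * d1
        c_r <- b_r - step * d2
        feas <- active & c_s0 > 0 & c_r > 0
        if (!any(feas)) break
        c_sse <- rep(Inf, length(b_r))
        Mi <- exp(-outer(c_r[feas], te))
        c_sse[feas] <- rowSums((c_s0[feas] * Mi - Si[feas, , drop = FALSE])^2)
        take <- feas & is.finite(c_sse) & c_sse < b_sse
        if (any(take)) {
          b_s0[take] <- c_s0[take]
          b_r[take] <- c_r[take]
          b_sse[take] <- c_sse[take]
          improved <- improved | take
          active <- active & !take
        }
        if (!any(active)) break
        step <- step / 2
      }
      if (!any(improved)) break
      rel <- max((best_sse[idx] - b_sse) / pmax(best_sse[idx], 1e-300),
                 na.rm = TRUE)
      best_sse[idx] <- b_sse
      if (rel < tol) break
    }
    s0[idx] <- b_s0
    r[idx] <- b_r
  }
  list(s0 = s0, t2star_ms = 1 / r)
}

#' Optimally combine multi-echo BOLD using a T2* map
#'
#' Weighted sum across echoes with contrast-to-noise weights
#' `w_i` proportional to `TE_i * exp(-TE_i / T2*)`, normalised to sum to 1
#' per voxel. Voxels with an invalid T2* fall back to the unweighted echo
#' mean; their count is recorded in the `n_fallback` attribute.
#'
#' @param series A [multi_echo_series()].
#' @param t2star A `t2star_map` on the same lattice.
#' @return A 4D array of the combined series, with attribute `n_fallback`.
#' @export
optimal_combine <- function(series, t2star) {
  stopifnot(inherits(series, "multi_echo_series"),
            inherits(t2star, "t2star_map"))
  d <- dim(series$echo_volumes[[1L]])
  if (!identical(dim(t2star$t2star_ms), d[1:3])) {
    stop("T2* map lattice does not match the echo volumes")
  }
  te <- series$te_ms
  ne <- length(te)
  nvox <- prod(d[1:3])
  t2 <- as.numeric(t2star$t2star_ms)
  valid <- is.finite(t2)
  W <- matrix(1 / ne, nvox, ne)
  if (any(valid)) {
    wv <- outer(1 / t2[valid], te, function(invt2, te) te * exp(-te * invt2))
    W[valid, ] <- wv / rowSums(wv)
  }
  combined <- matrix(0, nvox, d[4L])
  for (i in seq_len(ne)) {
    combined <- combined + W[, i] * matrix(series$echo_volumes[[i]], nrow = nvox)
  }
  out <- array(combined, dim = d)
  attr(out, "n_fallback") <- sum(!valid)
  attr(out, "weights_formula") <- "w_i ~ TE_i * exp(-TE_i/T2*)"
  out
}

#' Combination weights for one voxel
#'
#' Exposes the per-voxel echo weights used by [optimal_combine()]:
#' `w_i = TE_i exp(-TE_i/T2*) / sum_j TE_j exp(-TE_j/T2*)`.
#'
#' @param te_ms Echo times (ms).
#' @param t2star_ms T2* (ms); `NA` gives equal weights.
#' @return Numeric weights summing to 1.
#' @export
combination_weights <- function(te_ms, t2star_ms) {
  if (!is.finite(t2star_ms)) return(rep(1 / length(te_ms), length(te_ms)))
  w <- te_ms * exp(-te_ms / t2star_ms)
  w / sum(w)
}
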