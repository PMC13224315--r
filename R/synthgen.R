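# Synthetic study generator: cohort tables with the study's metabolite,
# QC and condition-effect structure, and imaging phantoms with
# tissue-specific fractal signals, multi-echo decay, MRS voxel masks and
# motion traces. Every downstream stage can be exercised on these without
# any acquired data.

#' Generative specification for a synthetic cohort table
#'
#' Defaults emulate the study conditions: 18 subjects measured at rest and
#' during movie watching; Glx 9.84 +/- 1.06 (rest) and 10.04 +/- 0.79
#' (movie) mM; GABA+ 5.48 +/- 0.77 and 5.23 +/- 0.71 mM; a condition effect
#' on the ROI Hurst exponent of -0.07 at rest relative to movie; and a null
#' E:I effect (`beta_ei = 0`), the study's finding - a nonzero value is the
#' knob for power experiments. Within-subject correlation of metabolites is
#' induced by a shared subject-level offset whose SD is
#' `subject_metab_frac` of the between-subject SD. QC covariates are drawn
#' from plausible uniform ranges wide enough to exercise the exclusion
#' rules.
#'
#' @param n_subjects Number of subjects (>= 2; default 18).
#' @param glx_mean,glx_sd,gaba_mean,gaba_sd Named numeric vectors
#'   (`rest`, `movie`) of metabolite means and SDs in mM.
#' @param hurst_intercept Baseline ROI H in the movie condition at
#'   `beta_ei = 0` (default 1.05).
#' @param beta_rest Condition effect on H at rest relative to movie
#'   (default -0.07).
#' @param beta_ei Effect of E:I on H (default 0).
#' @param subject_intercept_sd SD of the subject random intercept on H
#'   (default 0.1).
#' @param residual_sd Residual SD of H (default 0.05).
#' @param subject_metab_frac Fraction of each metabolite's SD attributed to
#'   a shared subject-level offset (default 0.5).
#' @param fd_range,fwhm_range Uniform ranges for mean FD (mm) and water
#'   FWHM draws.
#' @param freq_shift_sd SD of the zero-mean normal frequency-shift draws
#'   (Hz).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 18L,
                        glx_mean = c(rest = 9.84, movie = 10.04),
                        glx_sd = c(rest = 1.06, movie = 0.79),
                        gaba_mean = c(rest = 5.48, movie = 5.23),
                        gaba_sd = c(rest = 0.77, movie = 0.71),
                        hurst_intercept = 1.05,
                        beta_rest = -0.07,
                        beta_ei = 0,
                        subject_intercept_sd = 0.1,
                        residual_sd = 0.05,
                        subject_metab_frac = 0.5,
                        fd_range = c(0.05, 0.20),
                        fwhm_range = c(6, 11),
                        freq_shift_sd = 1,
                        seed = 1L) {
  problems <- character(0)
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    problems <- c(problems, "n_subjects must be >= 2")
  }
  for (nm in c("glx_sd", "gaba_sd")) {
    v <- get(nm)
    if (any(v < 0)) problems <- c(problems, paste(nm, "must be >= 0"))
  }
  for (nm in c("glx_mean", "gaba_mean", "glx_sd", "gaba_sd")) {
    v <- get(nm)
    if (!all(c("rest", "movie") %in% names(v))) {
      problems <- c(problems, paste(nm, "needs named entries rest and movie"))
    }
  }
  if (subject_intercept_sd < 0) problems <- c(problems, "subject_intercept_sd must be >= 0")
  if (residual_sd < 0) problems <- c(problems, "residual_sd must be >= 0")
  if (subject_metab_frac < 0 || subject_metab_frac > 1) {
    problems <- c(problems, "subject_metab_frac must be in [0, 1]")
  }
  if (length(problems) > 0L) {
    stop("invalid cohort spec: ", paste(problems, collapse = "; "))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         conditions = c("rest", "movie"),
         glx_mean = glx_mean, glx_sd = glx_sd,
         gaba_mean = gaba_mean, gaba_sd = gaba_sd,
         hurst_intercept = hurst_intercept,
         beta_rest = beta_rest, beta_ei = beta_ei,
         subject_intercept_sd = subject_intercept_sd,
         residual_sd = residual_sd,
         subject_metab_frac = subject_metab_frac,
         fd_range = fd_range, fwhm_range = fwhm_range,
         freq_shift_sd = freq_shift_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Draw from N(mean, sd) truncated at 0 by resampling (concentrations are
# positive); sd = 0 returns the mean.
rnorm_positive <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a synthetic subject x condition cohort table
#'
#' Per subject: a random intercept on H and shared metabolite offsets are
#' drawn; per condition: metabolites are drawn from the condition's normal
#' distribution (truncated at 0), E:I computed as Glx/GABA+, QC covariates
#' drawn, and
#' `H = intercept + beta_rest * 1[rest] + beta_ei * EI + subject + residual`.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per subject x condition and columns
#'   `subject_id`, `condition`, `hurst`, `glx_mM`, `gaba_mM`, `ei`,
#'   `mean_fd_mm`, `fwhm_slaser`, `fwhm_mega`, `freq_shift_slaser`,
#'   `freq_shift_mega`.
#' @export
generate_cohort_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    ids <- sprintf("sub-%02d", seq_len(n))
    u <- stats::rnorm(n, 0, spec$subject_intercept_sd)
    z_glx <- stats::rnorm(n)
    z_gaba <- stats::rnorm(n)
    rows <- vector("list", 2L * n)
    k <- 0L
    for (cond in spec$conditions) {
      sd_glx_b <- spec$subject_metab_frac * spec$glx_sd[[cond]]
      sd_glx_w <- sqrt(spec$glx_sd[[cond]]^2 - sd_glx_b^2)
      sd_gaba_b <- spec$subject_metab_frac * spec$gaba_sd[[cond]]
      sd_gaba_w <- sqrt(spec$gaba_sd[[cond]]^2 - sd_gaba_b^2)
      glx <- rnorm_positive(n, spec$glx_mean[[cond]] + sd_glx_b * z_glx,
                            sd_glx_w)
      gaba <- rnorm_positive(n, spec$gaba_mean[[cond]] + sd_gaba_b * z_gaba,
                             sd_gaba_w)
      ei <- ei_ratio(glx, gaba)
      h <- spec$hurst_intercept + spec$beta_rest * (cond == "rest") +
        spec$beta_ei * ei + u + stats::rnorm(n, 0, spec$residual_sd)
      for (i in seq_len(n)) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject_id = ids[i], condition = cond, hurst = h[i],
          glx_mM = glx[i], gaba_mM = gaba[i], ei = ei[i],
          mean_fd_mm = stats::runif(1, spec$fd_range[1], spec$fd_range[2]),
          fwhm_slaser = stats::runif(1, spec$fwhm_range[1], spec$fwhm_range[2]),
          fwhm_mega = stats::runif(1, spec$fwhm_range[1], spec$fwhm_range[2]),
          freq_shift_slaser = stats::rnorm(1, 0, spec$freq_shift_sd),
          freq_shift_mega = stats::rnorm(1, 0, spec$freq_shift_sd),
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    out[order(out$subject_id, out$condition), , drop = FALSE]
  })
}

#' Specification for a synthetic imaging phantom subject
#'
#' A cubic "brain" partitioned into concentric tissue compartments (outer
#' grey-matter shell, white-matter layer, central CSF core) whose voxel
#' signals are fractional Gaussian noise with tissue-specific Hurst
#' exponents (defaults GM 0.9 > WM 0.7 > CSF 0.5, mirroring the H contrast
#' of real tissue) riding on tissue-specific baselines. Echo volumes decay
#' with tissue T2*; an MRS voxel mask is a jittered cube in the posterior
#' grey-matter shell; motion is a random walk on the six rigid-body
#' parameters.
#'
#' @param dim Grid dimensions (3 integers, default 16^3).
#' @param n_frames Number of time points (default 480, >= 64).
#' @param sampling_interval Repetition time in seconds (default 1.5).
#' @param te_ms Echo times in ms (default `c(12.2, 35.352, 58.504)`).
#' @param tissue_hurst Named per-tissue target H (`gm`, `wm`, `csf`).
#' @param tissue_t2star_ms Named per-tissue T2* in ms.
#' @param tissue_s0 Named per-tissue baseline signal.
#' @param signal_sd SD of the fractal signal component (default 10).
#' @param noise_sd SD of additive white thermal noise per echo (default 0).
#' @param mrs_center MRS voxel centre (3 integers; default posterior
#'   grey-matter placement).
#' @param mrs_size Side length of the cubic MRS voxel (default 6).
#' @param mrs_jitter Maximum absolute integer jitter applied per axis to
#'   the MRS voxel centre (default 1).
#' @param motion_amplitude SD of the per-frame random-walk motion step
#'   (mm for translations; divided by 50 for rotations in radians;
#'   default 0.02).
#' @param seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(16L, 16L, 16L),
                         n_frames = 480L,
                         sampling_interval = 1.5,
                         te_ms = c(12.2, 35.352, 58.504),
                         tissue_hurst = c(gm = 0.9, wm = 0.7, csf = 0.5),
                         tissue_t2star_ms = c(gm = 40, wm = 50, csf = 120),
                         tissue_s0 = c(gm = 1000, wm = 900, csf = 600),
                         signal_sd = 10,
                         noise_sd = 0,
                         mrs_center = NULL,
                         mrs_size = 6L,
                         mrs_jitter = 1L,
                         motion_amplitude = 0.02,
                         seed = 1L) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 4L)) stop("`dim` must be 3 integers >= 4")
  n_frames <- as.integer(n_frames)
  if (n_frames < 64L) stop("`n_frames` must be >= 64")
  tissues <- c("gm", "wm", "csf")
  for (nm in c("tissue_hurst", "tissue_t2star_ms", "tissue_s0")) {
    v <- get(nm)
    if (!all(tissues %in% names(v))) {
      stop("`", nm, "` needs named entries gm, wm, csf")
    }
  }
  if (any(tissue_hurst <= 0 | tissue_hurst >= 1)) {
    stop("tissue Hurst exponents must lie in (0, 1)")
  }
  if (is.null(mrs_center)) {
    mrs_center <- c(dim[1L] %/% 2L, max(mrs_size %/% 2L + 1L, 3L), dim[3L] %/% 2L)
  }
  structure(
    list(dim = dim, n_frames = n_frames,
         sampling_interval = sampling_interval, te_ms = as.numeric(te_ms),
         tissue_hurst = tissue_hurst, tissue_t2star_ms = tissue_t2star_ms,
         tissue_s0 = tissue_s0, signal_sd = signal_sd, noise_sd = noise_sd,
         mrs_center = as.integer(mrs_center), mrs_size = as.integer(mrs_size),
         mrs_jitter = as.integer(mrs_jitter),
         motion_amplitude = motion_amplitude, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Concentric tissue labelling by normalised Chebyshev distance from the
# grid centre: outer shell GM, middle WM, core CSF.
phantom_tissue_labels <- function(dim) {
  centre <- (dim + 1) / 2
  half <- dim / 2
  idx <- expand.grid(x = seq_len(dim[1L]), y = seq_len(dim[2L]),
                     z = seq_len(dim[3L]))
  d <- pmax(abs(idx$x - centre[1L]) / half[1L],
            abs(idx$y - centre[2L]) / half[2L],
            abs(idx$z - centre[3L]) / half[3L])
  lab <- ifelse(d > 2 / 3, "gm", ifelse(d > 1 / 3, "wm", "csf"))
  array(lab, dim = dim)
}

#' Generate one synthetic phantom subject
#'
#' Builds the multi-echo 4D volumes, tissue masks, MRS voxel mask and
#' motion trace described by a [phantom_spec()]. Echo `i`'s signal is the
#' voxel's fractal base signal scaled by `exp(-TE_i / T2*_tissue)` plus
#' optional white noise. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param gm_hurst Optional override of the grey-matter target H (used to
#'   impose condition effects or subject variability).
#' @return List with `series` (a [multi_echo_series()]), `tissue_labels`
#'   (3D character array), `masks` (list `gm`, `wm`, `csf` of logical
#'   arrays), `mrs_mask`, `motion` (data frame), `spec`, and
#'   `gm_hurst_used`.
#' @export
generate_phantom_subject <- function(spec, gm_hurst = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  hurst <- spec$tissue_hurst
  if (!is.null(gm_hurst)) hurst[["gm"]] <- gm_hurst
  if (any(hurst <= 0 | hurst >= 1)) stop("tissue H must stay inside (0, 1)")
  labels <- phantom_tissue_labels(spec$dim)
  nvox <- prod(spec$dim)
  with_seed(spec$seed, {
    base <- matrix(0, nvox, spec$n_frames)
    for (tis in c("gm", "wm", "csf")) {
      vox <- which(labels == tis)
      if (length(vox) == 0L) next
      paths <- fgn_sample_matrix(hurst[[tis]], spec$signal_sd,
                                 spec$n_frames, length(vox))
      base[vox, ] <- spec$tissue_s0[[tis]] + t(paths)
    }
    decay <- exp(-outer(spec$te_ms,
                        1 / spec$tissue_t2star_ms[labels[seq_len(nvox)]]))
    echoes <- vector("list", length(spec$te_ms))
    for (i in seq_along(spec$te_ms)) {
      sig <- base * decay[i, ]
      if (spec$noise_sd > 0) {
        sig <- sig + matrix(stats::rnorm(length(sig), 0, spec$noise_sd),
                            nrow = nvox)
      }
      echoes[[i]] <- array(sig, dim = c(spec$dim, spec$n_frames))
    }
    jitter <- if (spec$mrs_jitter > 0) {
      sample(seq(-spec$mrs_jitter, spec$mrs_jitter), 3L, replace = TRUE)
    } else c(0L, 0L, 0L)
    centre <- spec$mrs_center + jitter
    half_lo <- (spec$mrs_size - 1L) %/% 2L
    half_hi <- spec$mrs_size %/% 2L
    lo <- centre - half_lo
    hi <- centre + half_hi
    if (any(lo < 1L) || any(hi > spec$dim)) {
      stop("MRS voxel placement outside the grid after jitter (centre ",
           paste(centre, collapse = ","), ")")
    }
    mrs_mask <- array(FALSE, spec$dim)
    mrs_mask[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <- TRUE
    amp <- spec$motion_amplitude
    motion <- data.frame(
      trans_x = cumsum(stats::rnorm(spec$n_frames, 0, amp)),
      trans_y = cumsum(stats::rnorm(spec$n_frames, 0, amp)),
      trans_z = cumsum(stats::rnorm(spec$n_frames, 0, amp)),
      rot_x = cumsum(stats::rnorm(spec$n_frames, 0, amp / 50)),
      rot_y = cumsum(stats::rnorm(spec$n_frames, 0, amp / 50)),
      rot_z = cumsum(stats::rnorm(spec$n_frames, 0, amp / 50))
    )
    list(series = multi_echo_series(echoes, spec$te_ms),
         tissue_labels = labels,
         masks = list(gm = labels == "gm", wm = labels == "wm",
                      csf = labels == "csf"),
         mrs_mask = mrs_mask,
         motion = motion,
         spec = spec,
         gm_hurst_used = hurst[["gm"]])
  })
}

#' Write a synthetic study to a BIDS-flavoured directory layout
#'
#' Generates phantoms for every subject and condition, writes per-echo 4D
#' NIfTIs (`sub-XX/func/sub-XX_task-<cond>_echo-N_bold.nii.gz`), a tissue
#' segmentation (`anat/sub-XX_dseg.nii.gz`, 1 = GM, 2 = WM, 3 = CSF), an
#' MRS voxel mask, motion TSVs, an echo-time JSON, a cohort-level
#' metabolite/QC table (`participants.tsv`) and the serialized generative
#' specs. Condition effects on H are imposed on the grey-matter target H:
#' at rest, GM H is shifted by `condition_effect`; each subject additionally
#' receives a subject-level GM H offset with SD `subject_sd`.
#'
#' @param root Output directory (created if needed).
#' @param cohort A [cohort_spec()] for the metabolite/QC table.
#' @param phantom A [phantom_spec()] template (per subject x condition
#'   seeds are derived from it).
#' @param condition_effect Shift of GM H at rest relative to movie
#'   (default: the cohort spec's `beta_rest`).
#' @param subject_sd SD of the per-subject GM H offset (default 0.02).
#' @return `root`, invisibly; side effect: files on disk.
#' @export
simulate_study <- function(root, cohort = cohort_spec(),
                           phantom = phantom_spec(),
                           condition_effect = cohort$beta_rest,
                           subject_sd = 0.02) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  tab <- generate_cohort_table(cohort)
  ids <- unique(tab$subject_id)
  subj_offsets <- with_seed(cohort$seed + 10000L,
                            stats::rnorm(length(ids), 0, subject_sd))
  gm_base <- phantom$tissue_hurst[["gm"]]
  for (si in seq_along(ids)) {
    id <- ids[si]
    for (ci in seq_along(cohort$conditions)) {
      cond <- cohort$conditions[ci]
      p <- phantom
      p$seed <- phantom$seed + 1000L * si + ci
      gm_h <- gm_base + subj_offsets[si] +
        if (cond == "rest") condition_effect else 0
      gm_h <- min(max(gm_h, 0.05), 0.95)
      ph <- generate_phantom_subject(p, gm_hurst = gm_h)
      write_phantom_subject(ph, root, id, cond)
    }
  }
  # cohort-level metabolite/QC table: imaging-derived quantities (H, FD)
  # are recomputed by the pipeline, not stored here
  participants <- tab[, c("subject_id", "condition", "glx_mM", "gaba_mM",
                          "fwhm_slaser", "fwhm_mega", "freq_shift_slaser",
                          "freq_shift_mega")]
  utils::write.table(participants, file.path(root, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  specs <- list(cohort = unclass(cohort), phantom = unclass(phantom),
                condition_effect = condition_effect, subject_sd = subject_sd)
  yaml::write_yaml(specs, file.path(root, "generative_spec.yaml"))
  invisible(root)
}

#' Write one phantom subject to disk
#'
#' @param phantom Output of [generate_phantom_subject()].
#' @param root Study root directory.
#' @param subject_id Subject label (e.g. `"sub-01"`).
#' @param condition Condition label (`"rest"` or `"movie"`).
#' @return The subject directory, invisibly.
#' @export
write_phantom_subject <- function(phantom, root, subject_id, condition) {
  spec <- phantom$spec
  func_dir <- file.path(root, subject_id, "func")
  anat_dir <- file.path(root, subject_id, "anat")
  dir.create(func_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(anat_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(spec$te_ms)) {
    path <- file.path(func_dir, sprintf("%s_task-%s_echo-%d_bold.nii.gz",
                                        subject_id, condition, i))
    write_nifti_volume(phantom$series$echo_volumes[[i]], path,
                       pixdim = c(rep(1, 3), spec$sampling_interval))
  }
  jsonlite::write_json(
    list(EchoTimesMs = spec$te_ms,
         RepetitionTimeSeconds = spec$sampling_interval),
    file.path(func_dir, sprintf("%s_task-%s_bold.json", subject_id, condition)),
    auto_unbox = TRUE, digits = NA)
  utils::write.table(
    phantom$motion,
    file.path(func_dir, sprintf("%s_task-%s_motion.tsv", subject_id, condition)),
    sep = "\t", quote = FALSE, row.names = FALSE)
  dseg <- array(match(phantom$tissue_labels, c("gm", "wm", "csf")),
                dim = spec$dim)
  dseg_path <- file.path(anat_dir, paste0(subject_id, "_dseg.nii.gz"))
  if (!file.exists(dseg_path)) {
    write_nifti_volume(dseg, dseg_path)
    write_nifti_volume(phantom$mrs_mask + 0,
                       file.path(root, subject_id,
                                 paste0(subject_id, "_mrs_mask.nii.gz")))
  }
  invisible(file.path(root, subject_id))
}
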