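# Orchestration: ties the stages into the end-to-end analysis -
# multi-echo combination, voxelwise Hurst maps, ROI aggregation, QC
# exclusions, cohort assembly, mixed-model statistics and optional power.

#' Run configuration
#'
#' @param root Study root directory (the layout written by
#'   [simulate_study()]).
#' @param out_dir Output directory for the report, logs and derived maps.
#' @param n_segments,overlap_fraction Welch parameters.
#' @param fd_threshold,fwhm_threshold Exclusion thresholds, see
#'   [apply_exclusions()].
#' @param include_ei Include the E:I term in the mixed model (default TRUE).
#' @param power_betas Optional numeric vector of E:I effect sizes for the
#'   power stage (`NULL` skips it).
#' @param n_power_sims Simulate-refit replicates per effect size.
#' @param write_maps Write per-subject Hurst maps as NIfTI (default FALSE).
#' @param seed Master seed; per-stage substreams are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(root, out_dir = file.path(root, "derivatives"),
                       n_segments = 8L, overlap_fraction = 0.5,
                       fd_threshold = 0.15, fwhm_threshold = 10,
                       include_ei = TRUE, power_betas = NULL,
                       n_power_sims = 200L, write_maps = FALSE, seed = 1L) {
  if (!dir.exists(root)) stop("study root does not exist: ", root)
  structure(
    list(root = root, out_dir = out_dir, n_segments = as.integer(n_segments),
         overlap_fraction = overlap_fraction, fd_threshold = fd_threshold,
         fwhm_threshold = fwhm_threshold, include_ei = include_ei,
         power_betas = power_betas, n_power_sims = as.integer(n_power_sims),
         write_maps = write_maps, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read or write a run configuration as YAML
#'
#' The configuration round-trips through serialization unchanged.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

# Append one line-delimited JSON log entry.
log_stage <- function(log_path, stage, ...) {
  entry <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             list(...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
      file = log_path, append = TRUE, sep = "")
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) multi-echo T2* fit and optimal combination per
#' subject and condition; (2) voxelwise Hurst map and grey-matter/MRS ROI
#' mean; (3) framewise displacement and QC exclusions; (4) cohort table
#' assembly (metabolites from `participants.tsv`, E:I = Glx/GABA+);
#' (5) paired condition tests, Pearson correlations, the mixed model with
#' Nakagawa R^2 and VIFs, plus the MRS-mask consensus Dice; (6) optional
#' simulate-refit power. Every stage's parameters are logged as
#' line-delimited JSON; the report is written as `report.json` under
#' `out_dir` and contains no timestamps, so re-running an identical
#' configuration reproduces it byte for byte.
#'
#' @param config A [run_config()].
#' @return The run report (list), invisibly also written to JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline_log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  subjects <- sort(basename(Sys.glob(file.path(config$root, "sub-*"))))
  if (length(subjects) == 0L) stop("no subjects found under ", config$root)
  participants <- utils::read.table(file.path(config$root, "participants.tsv"),
                                    header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  conditions <- unique(participants$condition)
  log_stage(log_path, "discover", n_subjects = length(subjects),
            conditions = conditions)

  rows <- list()
  mrs_masks <- list()
  for (id in subjects) {
    stage_ctx <- id
    mrs_path <- file.path(config$root, id, paste0(id, "_mrs_mask.nii.gz"))
    dseg_path <- file.path(config$root, id, "anat", paste0(id, "_dseg.nii.gz"))
    res <- tryCatch({
      mrs_mask <- read_mask_nifti(mrs_path)
      dseg <- RNifti::readNifti(dseg_path)
      gm_mask <- array(round(as.numeric(dseg)) == 1, dim = dim(dseg))
      mrs_masks[[id]] <- mrs_mask
      for (cond in conditions) {
        stage_ctx <- paste(id, cond)
        func_dir <- file.path(config$root, id, "func")
        echo_paths <- sort(Sys.glob(file.path(
          func_dir, sprintf("%s_task-%s_echo-*_bold.nii.gz", id, cond))))
        meta <- jsonlite::read_json(file.path(
          func_dir, sprintf("%s_task-%s_bold.json", id, cond)),
          simplifyVector = TRUE)
        echoes <- lapply(echo_paths, function(p) read_bold_nifti(p)$data)
        series <- multi_echo_series(echoes, meta$EchoTimesMs)
        t2map <- t2star_map(series)
        combined <- optimal_combine(series, t2map)
        log_stage(log_path, "multiecho", subject = id, condition = cond,
                  n_echoes = length(echoes),
                  n_t2star_fallback = attr(combined, "n_fallback"))
        hmap <- hurst_map(combined, meta$RepetitionTimeSeconds,
                          config$n_segments, config$overlap_fraction)
        roi_h <- roi_mean_hurst(hmap, gm_mask, mrs_mask)
        if (isTRUE(config$write_maps)) {
          write_hurst_map(hmap, file.path(
            config$out_dir, sprintf("%s_task-%s_hurst.nii.gz", id, cond)))
        }
        log_stage(log_path, "hurst", subject = id, condition = cond,
                  roi_mean_hurst = roi_h, n_invalid = hmap$n_invalid)
        motion <- read_motion_tsv(file.path(
          func_dir, sprintf("%s_task-%s_motion.tsv", id, cond)))
        fd <- framewise_displacement(motion)
        log_stage(log_path, "motion", subject = id, condition = cond,
                  mean_fd_mm = fd$mean_fd_mm)
        prow <- participants[participants$subject_id == id &
                               participants$condition == cond, ]
        if (nrow(prow) != 1L) stop("participants.tsv row missing")
        rows[[paste(id, cond)]] <- data.frame(
          subject_id = id, condition = cond, hurst = roi_h,
          glx_mM = prow$glx_mM, gaba_mM = prow$gaba_mM,
          ei = ei_ratio(prow$glx_mM, prow$gaba_mM),
          mean_fd_mm = fd$mean_fd_mm,
          fwhm_slaser = prow$fwhm_slaser, fwhm_mega = prow$fwhm_mega,
          freq_shift_slaser = prow$freq_shift_slaser,
          freq_shift_mega = prow$freq_shift_mega,
          stringsAsFactors = FALSE
        )
      }
      NULL
    }, error = function(e) e)
    if (inherits(res, "error")) {
      stop("pipeline stage failed for ", stage_ctx, ": ",
           conditionMessage(res))
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  utils::write.table(cohort, file.path(config$out_dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  excl <- apply_exclusions(cohort, config$fd_threshold, config$fwhm_threshold)
  log_stage(log_path, "exclusions", retained = length(excl$retained),
            excluded = nrow(excl$excluded))
  jsonlite::write_json(
    list(retained = excl$retained, excluded = excl$excluded),
    file.path(config$out_dir, "exclusions.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  retained <- cohort[cohort$subject_id %in% excl$retained, ]

  cons <- consensus_mask(mrs_masks)
  log_stage(log_path, "consensus", mean_dice = cons$mean_dice)

  report <- list(
    config = unclass(config)[c("n_segments", "overlap_fraction",
                               "fd_threshold", "fwhm_threshold",
                               "include_ei", "seed")],
    n_subjects_input = length(subjects),
    retained_subjects = excl$retained,
    excluded_subjects = excl$excluded,
    mrs_mask_consensus_dice = cons$mean_dice
  )

  n_retained <- length(excl$retained)
  if (n_retained < 6L) {
    report$model <- list(status = "insufficient data",
                         n_retained = n_retained)
    log_stage(log_path, "model", status = "insufficient data")
  } else {
    wide <- merge(
      retained[retained$condition == "rest",
               c("subject_id", "hurst", "glx_mM", "gaba_mM", "ei")],
      retained[retained$condition == "movie",
               c("subject_id", "hurst", "glx_mM", "gaba_mM", "ei")],
      by = "subject_id", suffixes = c("_rest", "_movie"))
    paired <- lapply(c(hurst = "hurst", glx = "glx_mM", gaba = "gaba_mM",
                       ei = "ei"), function(v) {
      paired_condition_test(wide[[paste0(v, "_rest")]],
                            wide[[paste0(v, "_movie")]])
    })
    correlations <- list()
    for (cond in conditions) {
      sub <- retained[retained$condition == cond, ]
      correlations[[cond]] <- lapply(
        c(glx = "glx_mM", gaba = "gaba_mM", ei = "ei"),
        function(v) pearson_corr(sub$hurst, sub[[v]]))
    }
    predictors <- if (config$include_ei) LMM_PREDICTORS
                  else setdiff(LMM_PREDICTORS, "ei")
    # the residual-df convention needs n_obs - n_fixed - n_subjects + 1 >= 1;
    # for small cohorts fall back to the core scientific terms
    df_full <- nrow(retained) - (length(predictors) + 1L) - n_retained + 1L
    if (df_full < 1L) {
      predictors <- intersect(predictors, c("ei", "condition"))
      log_stage(log_path, "model_reduced",
                reason = "insufficient residual df for QC covariates",
                predictors = predictors)
    }
    fit <- fit_lmm(retained, predictors)
    vifs <- if (length(predictors) >= 2L) vif(retained, predictors) else NULL
    log_stage(log_path, "model", n_obs = fit$n_obs,
              r2_marginal = fit$r2_marginal,
              r2_conditional = fit$r2_conditional)
    report$paired_tests <- paired
    report$correlations <- correlations
    report$model <- list(
      status = "ok",
      coefficients = fit$coefficients,
      random_intercept_var = fit$random_intercept_var,
      residual_var = fit$residual_var,
      r2_marginal = fit$r2_marginal,
      r2_conditional = fit$r2_conditional,
      n_obs = fit$n_obs, n_subjects = fit$n_subjects,
      df_method = fit$df_method)
    report$model$predictors <- predictors
    if (!is.null(vifs)) report$vif <- as.list(vifs)
    if (!is.null(config$power_betas)) {
      gen <- cohort_spec(n_subjects = fit$n_subjects, seed = config$seed)
      power <- lapply(config$power_betas, function(b) {
        pr <- power_simulation(gen, b, n_sims = config$n_power_sims,
                               seed = config$seed + round(1000 * b))
        unclass(pr)
      })
      names(power) <- paste0("beta_", config$power_betas)
      report$power <- power
      log_stage(log_path, "power", betas = config$power_betas)
    }
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_stage(log_path, "done")
  invisible(report)
}

#' Validate a run report against the expected schema
#'
#' Checks the presence and basic types of the keys every complete run
#' report carries; returns invisibly `TRUE` or stops with the missing keys.
#'
#' @param report A report list from [run_pipeline()] (or parsed from its
#'   JSON).
#' @return `TRUE`, invisibly.
#' @export
validate_run_report <- function(report) {
  required <- c("config", "n_subjects_input", "retained_subjects",
                "excluded_subjects", "mrs_mask_consensus_dice", "model")
  missing_keys <- setdiff(required, names(report))
  if (length(missing_keys) > 0L) {
    stop("report is missing keys: ", paste(missing_keys, collapse = ", "))
  }
  if (!is.numeric(report$mrs_mask_consensus_dice)) {
    stop("mrs_mask_consensus_dice must be numeric")
  }
  status <- report$model$status
  if (is.null(status) || !status %in% c("ok", "insufficient data")) {
    stop("model status must be 'ok' or 'insufficient data'")
  }
  if (identical(status, "ok")) {
    model_keys <- c("coefficients", "r2_marginal", "r2_conditional",
                    "n_obs", "n_subjects")
    missing_model <- setdiff(model_keys, names(report$model))
    if (length(missing_model) > 0L) {
      stop("model report is missing keys: ",
           paste(missing_model, collapse = ", "))
    }
  }
  invisible(TRUE)
}
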