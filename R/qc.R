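# Quality control: framewise displacement from rigid-body motion
# parameters, FD/FWHM exclusion rules, Dice overlap, and majority-vote
# consensus masks.

MOTION_COLUMNS <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style FD: per frame, the sum of absolute backward differences of
#' the three translations (mm) plus the three rotations (radians) converted
#' to arc length on a sphere of `head_radius_mm`. The first frame has FD 0;
#' the mean is taken over frames 2..N.
#'
#' @param trace Data frame with columns `trans_x`, `trans_y`, `trans_z`
#'   (mm) and `rot_x`, `rot_y`, `rot_z` (radians), one row per frame.
#' @param head_radius_mm Assumed head radius for the rotation-to-mm
#'   conversion (default 50 mm).
#' @return List with `fd` (per-frame values, first 0) and `mean_fd_mm`.
#' @export
framewise_displacement <- function(trace, head_radius_mm = 50) {
  missing_cols <- setdiff(MOTION_COLUMNS, names(trace))
  if (length(missing_cols) > 0L) {
    stop("motion trace is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(trace[, MOTION_COLUMNS])
  if (nrow(m) < 2L) stop("degenerate motion trace: need at least 2 frames")
  if (!all(is.finite(m))) stop("motion parameters must be finite")
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd_mm = mean(fd[-1L]))
}

#' Read a motion-parameter TSV
#'
#' Six-column TSV with validated column names (`trans_*` in mm, `rot_*` in
#' radians).
#'
#' @param path File path.
#' @return Data frame with the six motion columns.
#' @export
read_motion_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  missing_cols <- setdiff(MOTION_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("motion TSV ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df[, MOTION_COLUMNS]
}

#' Apply the motion and spectral-quality exclusion rules
#'
#' A subject is excluded if the mean framewise displacement of ANY condition
#' exceeds `fd_threshold`, or if the water-peak FWHM of ANY of their MRS
#' scans exceeds `fwhm_threshold`. Both thresholds are strict inequalities
#' (a value exactly at the threshold is retained). A subject can carry both
#' reason codes.
#'
#' @param records Data frame with one row per subject x condition and
#'   columns `subject_id`, `condition`, `mean_fd_mm`, `fwhm_slaser`,
#'   `fwhm_mega`.
#' @param fd_threshold Mean-FD exclusion threshold in mm (default 0.15).
#' @param fwhm_threshold Water FWHM exclusion threshold (default 10;
#'   interpreted as Hz by spectroscopy convention).
#' @param conditions Conditions every subject must have a record for
#'   (default `c("rest", "movie")`).
#' @return List with `retained` (subject ids) and `excluded` (data frame
#'   `subject_id`, `reason` in `{"FD", "FWHM"}`, `value` = offending value).
#' @export
apply_exclusions <- function(records, fd_threshold = 0.15,
                             fwhm_threshold = 10,
                             conditions = c("rest", "movie")) {
  req <- c("subject_id", "condition", "mean_fd_mm", "fwhm_slaser", "fwhm_mega")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L) {
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  has_cond <- vapply(split(records$condition, records$subject_id),
                     function(x) all(conditions %in% x), logical(1L))
  incomplete <- names(has_cond)[!has_cond]
  if (length(incomplete) > 0L) {
    stop("incomplete subjects (missing condition records): ",
         paste(incomplete, collapse = ", "))
  }
  subjects <- unique(records$subject_id)
  excluded <- data.frame(subject_id = character(0), reason = character(0),
                         value = numeric(0), stringsAsFactors = FALSE)
  for (s in subjects) {
    rows <- records[records$subject_id == s, ]
    if (any(rows$mean_fd_mm > fd_threshold)) {
      excluded <- rbind(excluded, data.frame(
        subject_id = s, reason = "FD", value = max(rows$mean_fd_mm)))
    }
    fwhm <- c(rows$fwhm_slaser, rows$fwhm_mega)
    if (any(fwhm > fwhm_threshold)) {
      excluded <- rbind(excluded, data.frame(
        subject_id = s, reason = "FWHM", value = max(fwhm)))
    }
  }
  list(retained = setdiff(subjects, excluded$subject_id),
       excluded = excluded)
}

#' Dice overlap coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks are identical by
#' convention and score 1 (flagged with a warning as degenerate).
#'
#' @param a,b Binary arrays on the same lattice.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- as_binary_mask(a)
  b <- as_binary_mask(b)
  if (!identical(dim(a), dim(b))) stop("masks must share a lattice")
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0L) {
    warning("both masks are empty; Dice defined as 1 by convention")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Majority-vote consensus mask and mean Dice agreement
#'
#' A voxel enters the consensus iff it is present in strictly more than half
#' of the input masks (ties at exactly half are excluded). The mean Dice is
#' the average of [dice()] between each input mask and the consensus; it
#' summarises inter-subject consistency of MRS voxel placement.
#'
#' @param masks List of >= 2 binary arrays on a common lattice.
#' @return List with `consensus` (logical array) and `mean_dice`.
#' @export
consensus_mask <- function(masks) {
  if (!is.list(masks) || length(masks) < 2L) stop("need at least 2 masks")
  masks <- lapply(masks, as_binary_mask)
  d <- dim(masks[[1L]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), logical(1L)))) {
    stop("all masks must share a lattice")
  }
  votes <- Reduce(`+`, masks)
  consensus <- array(votes > length(masks) / 2, dim = d)
  mean_dice <- mean(vapply(masks, dice, numeric(1L), b = consensus))
  list(consensus = consensus, mean_dice = mean_dice)
}
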