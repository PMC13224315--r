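# NIfTI input/output helpers (RNifti-backed).

#' Read a 4D BOLD NIfTI
#'
#' @param path File path.
#' @return List with `data` (4D array), `tr` (repetition time in seconds,
#'   from the header's fourth pixdim) and the `RNifti` image for header
#'   reuse.
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop(path, " is not a 4D volume")
  tr <- RNifti::pixdim(img)[4L]
  list(data = array(as.numeric(img), dim = d), tr = tr, image = img)
}

#' Read a binary mask NIfTI
#'
#' Values are binarized at > 0.5.
#'
#' @param path File path.
#' @return Logical 3D array.
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0.5, dim = dim(img))
}

# Write a numeric array as float32 NIfTI with the given pixdim.
write_nifti_volume <- function(data, path, pixdim = NULL) {
  img <- RNifti::asNifti(data, internal = FALSE)
  if (!is.null(pixdim)) RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a Hurst map as NIfTI with a JSON sidecar
#'
#' The map is written as a 3D float32 volume (invalid voxels carry the
#' sentinel 0); the sidecar records the Welch parameters and fit
#' provenance so downstream aggregation is reproducible.
#'
#' @param map A `hurst_map` from [hurst_map()].
#' @param path Output `.nii.gz` path; the sidecar is written next to it
#'   with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_hurst_map <- function(map, path) {
  stopifnot(inherits(map, "hurst_map"))
  write_nifti_volume(map$hurst, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(estimator = "welch_psd_loglog_ols",
         n_segments = map$n_segments,
         overlap_fraction = map$overlap_fraction,
         window = "hann",
         detrend = "segment_mean",
         fit_range = "all positive-frequency bins up to Nyquist",
         hurst_equation = "H = (1 + beta) / 2",
         sampling_interval_s = map$sampling_interval,
         n_invalid_voxels = map$n_invalid),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
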