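#' Load a NIfTI volume as a list of 2D transverse slices
#'
#' Reads a 3D NIfTI volume (via the RNifti package) and slices it in the
#' transverse direction (along the third axis), optionally min-max
#' normalizing each slice to `[0,1]`.
#'
#' @param path .nii or .nii.gz file.
#' @param normalize per-slice min-max normalization (default TRUE).
#' @return list of H x W matrices.
#' @export
read_nifti_slices <- function(path, normalize = TRUE) {
  check_that(requireNamespace("RNifti", quietly = TRUE),
             "axialseg_invalid_argument",
             "the RNifti package is required to read NIfTI files")
  vol <- RNifti::readNifti(path)
  arr <- as.array(vol)
  check_that(length(dim(arr)) == 3L, "axialseg_invalid_argument",
             "expected a 3D volume")
  lapply(seq_len(dim(arr)[3]), function(k) {
    sl <- arr[, , k]
    if (normalize) sl <- normalize_intensity(sl)
    sl
  })
}
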