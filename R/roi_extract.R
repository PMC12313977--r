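#' Mean gray-matter value within a binary ROI mask
#'
#' Computes the arithmetic mean of a 3-D gray-matter map over the voxels
#' where a binary mask equals 1. This supplies a per-subject scalar
#' mediator (e.g. mean modulated gray-matter value in a ventral-striatum
#' mask) from pre-aligned images. No resampling or registration is
#' performed: map and mask must already live on the identical voxel grid,
#' and a grid or orientation mismatch is an error rather than a silent
#' interpolation.
#'
#' @param gmv A 3-D numeric array, an `RNifti` image, or a path to a
#'   NIfTI-1 file (`.nii` / `.nii.gz`).
#' @param mask Same accepted forms; values must be 0/1 (or logical) with at
#'   least one voxel set.
#' @param affine_tol Maximum allowed elementwise difference between the two
#'   affines when both images carry one (default 1e-4).
#' @return The scalar mean of `gmv` over `mask == 1`.
#' @examples
#' vol <- array(seq_len(8), dim = c(2, 2, 2))
#' msk <- array(0, dim = c(2, 2, 2)); msk[1, , ] <- 1
#' roi_mean(vol, msk)
#' @export
roi_mean <- function(gmv, mask, affine_tol = 1e-4) {
  gmv <- load_volume(gmv, "gmv")
  mask <- load_volume(mask, "mask")
  if (!identical(dim(gmv$data), dim(mask$data))) {
    stop(sprintf("grid mismatch: map is %s, mask is %s; no resampling is performed",
                 paste(dim(gmv$data), collapse = "x"),
                 paste(dim(mask$data), collapse = "x")), call. = FALSE)
  }
  if (!is.null(gmv$affine) && !is.null(mask$affine)) {
    if (max(abs(gmv$affine - mask$affine)) > affine_tol) {
      stop("affine mismatch between map and mask; images must be pre-aligned",
           call. = FALSE)
    }
  }
  mvals <- as.numeric(mask$data)
  if (anyNA(mvals) || !all(mvals %in% c(0, 1))) {
    stop("mask must be binary (0/1)", call. = FALSE)
  }
  if (sum(mvals) == 0) stop("mask is empty", call. = FALSE)
  mean(as.numeric(gmv$data)[mvals == 1])
}

load_volume <- function(x, what) {
  if (is.character(x)) {
    if (length(x) != 1L || !file.exists(x)) {
      stop(sprintf("%s file not found: %s", what, x), call. = FALSE)
    }
    img <- RNifti::readNifti(x)
    return(list(data = as.array(img), affine = unclass(RNifti::xform(img))))
  }
  if (inherits(x, "niftiImage")) {
    return(list(data = as.array(x), affine = unclass(RNifti::xform(x))))
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    return(list(data = x, affine = NULL))
  }
  stop(sprintf("%s must be a 3-D array, a niftiImage, or a NIfTI file path", what),
       call. = FALSE)
}
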