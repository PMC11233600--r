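#' Annotated CT volume
#'
#' The unit of data every image stage consumes: a 3D grid of intensities in
#' Hounsfield units, a per-axis voxel spacing in millimetres, a physical
#' origin, and an aligned binary region-of-interest (ROI) mask.
#'
#' Voxel `(i, j, k)` (1-based) has its centre at
#' `origin + (c(i, j, k) - 1) * spacing` in millimetres.
#'
#' @param intensities 3D numeric array of intensities (HU).
#' @param spacing Numeric length-3, voxel size in mm per axis; all positive.
#' @param mask 3D logical (or 0/1) array, same shape as `intensities`.
#' @param origin Numeric length-3 physical offset in mm.
#' @return An object of class `annotated_volume`.
#' @export
annotated_volume <- function(intensities, spacing, mask,
                             origin = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array")
  if (!identical(dim(intensities), dim(mask)))
    stop("mask shape must equal intensity shape")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("mask contains NA")
  structure(
    list(intensities = intensities, spacing = spacing,
         origin = as.numeric(origin), mask = mask),
    class = "annotated_volume"
  )
}

#' @export
print.annotated_volume <- function(x, ...) {
  cat("<annotated_volume> ", paste(dim(x$intensities), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm, ", sum(x$mask), " mask voxels\n", sep = "")
  invisible(x)
}

#' @export
dim.annotated_volume <- function(x) dim(x$intensities)

is_annotated_volume <- function(x) inherits(x, "annotated_volume")

#' Physical coordinates of voxel centres
#'
#' @param vol An `annotated_volume`.
#' @param which Optional logical array or integer indices selecting voxels;
#'   default all voxels.
#' @return Matrix with one row per voxel and columns x, y, z in mm.
#' @keywords internal
voxel_centers <- function(vol, which = NULL) {
  d <- dim(vol$intensities)
  if (is.null(which)) which <- seq_len(prod(d))
  if (is.logical(which)) which <- which(which)
  ijk <- arrayInd(which, d)
  sweep(sweep(ijk - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Read an annotated volume from NIfTI image/mask files
#'
#' @param image_path Path to the intensity NIfTI file.
#' @param mask_path Path to the binary mask NIfTI file.
#' @return An `annotated_volume`.
#' @export
read_annotated_volume <- function(image_path, mask_path) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  sp <- RNifti::pixdim(img)[1:3]
  annotated_volume(array(as.numeric(img), dim = dim(img)[1:3]),
                   spacing = sp,
                   mask = array(as.numeric(msk) > 0.5, dim = dim(msk)[1:3]))
}

#' Write an annotated volume as a NIfTI image/mask pair
#'
#' @param vol An `annotated_volume`.
#' @param image_path Destination for the intensity image (`.nii` / `.nii.gz`).
#' @param mask_path Destination for the mask image.
#' @return Invisibly, `c(image_path, mask_path)`.
#' @export
write_annotated_volume <- function(vol, image_path, mask_path) {
  img <- RNifti::asNifti(vol$intensities, pixdim = vol$spacing)
  msk <- RNifti::asNifti(array(as.integer(vol$mask), dim = dim(vol$mask)),
                         pixdim = vol$spacing)
  RNifti::writeNifti(img, image_path)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(image_path, mask_path))
}
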