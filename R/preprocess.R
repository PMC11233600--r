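#' Clip volume intensities to a fixed HU window
#'
#' Limits intensities to `[lo, hi]` to damp the influence of extreme values
#' and scanner outliers; the mask is untouched. The operation is total and
#' idempotent.
#'
#' @param vol An [annotated_volume()].
#' @param lo,hi Window bounds in HU; `lo < hi`. Defaults -800 / 800.
#' @return The clipped volume.
#' @export
clip_intensities <- function(vol, lo = -800, hi = 800) {
  stopifnot(is_annotated_volume(vol))
  if (!(lo < hi)) stopf("clip bounds require lo < hi (got %g, %g)", lo, hi)
  vol$intensities[] <- pmin(hi, pmax(lo, vol$intensities))
  vol
}

#' Resample a volume to isotropic voxel spacing
#'
#' Fixed-resolution spatial normalization: the volume is resampled onto a
#' grid with the target spacing on every axis, preserving the physical
#' extent to within one output voxel per axis. Intensities are interpolated
#' tri-linearly; the mask is resampled with nearest-neighbour interpolation
#' and re-binarized at 0.5 (both interpolation orders are configurable).
#'
#' @param vol An [annotated_volume()].
#' @param target Target spacing in mm, scalar or length-3. Default 1 mm.
#' @param intensity_interp `"trilinear"` (default) or `"nearest"`.
#' @param mask_interp `"nearest"` (default) or `"trilinear"` (re-binarized
#'   at 0.5).
#' @param sample_id Optional label used in error messages.
#' @return The resampled [annotated_volume()].
#' @export
resample_isotropic <- function(vol, target = 1,
                               intensity_interp = c("trilinear", "nearest"),
                               mask_interp = c("nearest", "trilinear"),
                               sample_id = NULL) {
  stopifnot(is_annotated_volume(vol))
  intensity_interp <- match.arg(intensity_interp)
  mask_interp <- match.arg(mask_interp)
  target <- as.numeric(target)
  if (length(target) == 1L) target <- rep(target, 3L)
  if (any(target <= 0)) stopf("target spacing must be positive")
  din <- dim(vol$intensities)
  out_shape <- pmax(1L, as.integer(round(din * vol$spacing / target)))
  img <- resample_grid(vol$intensities, vol$spacing, out_shape, target,
                       nearest = intensity_interp == "nearest")
  msk <- resample_grid(vol$mask + 0, vol$spacing, out_shape, target,
                       nearest = mask_interp == "nearest") >= 0.5
  if (sum(vol$mask) > 0 && sum(msk) == 0)
    stopf("mask of sample %s became empty after resampling",
          sample_id %||% "<unnamed>")
  out <- annotated_volume(img, target, msk, origin = vol$origin)
  out
}

# Trilinear / nearest resampling of a 3D array between voxel-centre grids
# that share the physical position of voxel (1,1,1). Output voxel i sits at
# (i-1)*target mm; it is mapped to fractional input index and interpolated,
# clamping at the borders.
resample_grid <- function(arr, spacing_in, out_shape, spacing_out,
                          nearest = FALSE) {
  din <- dim(arr)
  ax <- lapply(1:3, function(a) {
    x <- (seq_len(out_shape[a]) - 1) * spacing_out[a] / spacing_in[a] + 1
    pmin(pmax(x, 1), din[a])
  })
  if (nearest) {
    # round half up: round() ties-to-even makes alternate source voxels
    # cover 3 vs 1 output voxels on integer spacing ratios, biasing the
    # resampled mask volume
    i1 <- lapply(1:3, function(a)
      pmin(as.integer(floor(ax[[a]] + 0.5)), din[a]))
    return(array(arr[as.matrix(expand.grid(i1[[1]], i1[[2]], i1[[3]]))],
                 dim = out_shape))
  }
  lo <- lapply(1:3, function(a) pmin(as.integer(floor(ax[[a]])), din[a] - 1L))
  lo <- lapply(1:3, function(a) pmax(lo[[a]], 1L))
  fr <- lapply(1:3, function(a) ax[[a]] - lo[[a]])
  g <- function(ix, iy, iz) {
    array(arr[as.matrix(expand.grid(ix, iy, iz))], dim = out_shape)
  }
  x0 <- lo[[1]]; x1 <- pmin(lo[[1]] + 1L, din[1])
  y0 <- lo[[2]]; y1 <- pmin(lo[[2]] + 1L, din[2])
  z0 <- lo[[3]]; z1 <- pmin(lo[[3]] + 1L, din[3])
  fx <- array(rep(fr[[1]], times = out_shape[2] * out_shape[3]), out_shape)
  fy <- array(rep(rep(fr[[2]], each = out_shape[1]), times = out_shape[3]),
              out_shape)
  fz <- array(rep(fr[[3]], each = out_shape[1] * out_shape[2]), out_shape)
  (1 - fz) * ((1 - fy) * ((1 - fx) * g(x0, y0, z0) + fx * g(x1, y0, z0)) +
              fy       * ((1 - fx) * g(x0, y1, z0) + fx * g(x1, y1, z0))) +
  fz       * ((1 - fy) * ((1 - fx) * g(x0, y0, z1) + fx * g(x1, y0, z1)) +
              fy       * ((1 - fx) * g(x0, y1, z1) + fx * g(x1, y1, z1)))
}

#' Standard preprocessing: clip then resample
#'
#' Applies the fixed two-step standardization — HU clipping first, isotropic
#' resampling second — and records the parameters used.
#'
#' @inheritParams clip_intensities
#' @inheritParams resample_isotropic
#' @return The preprocessed volume with a `preprocess` attribute holding the
#'   parameters (suitable for a JSON sidecar).
#' @export
preprocess_volume <- function(vol, lo = -800, hi = 800, target = 1,
                              sample_id = NULL) {
  out <- resample_isotropic(clip_intensities(vol, lo, hi), target,
                            sample_id = sample_id)
  attr(out, "preprocess") <- list(clip = c(lo = lo, hi = hi),
                                  target_spacing_mm = target,
                                  order = c("clip", "resample"))
  out
}
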