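#' Gray-level discretization specification
#'
#' Texture (and first-order entropy/uniformity) features require the ROI
#' intensities binned into discrete gray levels. Two standard modes are
#' supported: fixed bin width (default 25 HU, anchored at the ROI minimum)
#' and fixed bin count (equal-width bins spanning the ROI range).
#'
#' @param mode `"fixed_bin_width"` or `"fixed_bin_count"`.
#' @param bin_width_hu Bin width in HU (fixed-width mode).
#' @param n_bins Number of bins (fixed-count mode).
#' @return A `discretization` list.
#' @export
discretization <- function(mode = c("fixed_bin_width", "fixed_bin_count"),
                           bin_width_hu = 25, n_bins = 32L) {
  mode <- match.arg(mode)
  if (mode == "fixed_bin_width" && bin_width_hu <= 0)
    stopf("bin_width_hu must be positive")
  if (mode == "fixed_bin_count" && n_bins < 1L)
    stopf("n_bins must be positive")
  structure(list(mode = mode, bin_width_hu = bin_width_hu,
                 n_bins = as.integer(n_bins)),
            class = "discretization")
}

#' Discretize ROI intensities into gray levels
#'
#' @param values Numeric vector of ROI intensities.
#' @param disc A [discretization()].
#' @return Integer vector of gray levels starting at 1.
#' @export
discretize_values <- function(values, disc = discretization()) {
  stopifnot(inherits(disc, "discretization"))
  if (disc$mode == "fixed_bin_width") {
    lev <- floor((values - min(values)) / disc$bin_width_hu) + 1
  } else {
    rg <- max(values) - min(values)
    if (rg == 0) return(rep(1L, length(values)))
    w <- rg / disc$n_bins
    lev <- pmin(disc$n_bins, floor((values - min(values)) / w) + 1)
  }
  as.integer(lev)
}

.firstorder_feature_names <- c(
  "energy", "total_energy", "entropy", "minimum", "p10", "p90", "maximum",
  "mean", "median", "iqr", "range", "mad", "rmad", "rms", "skewness",
  "kurtosis", "variance", "uniformity")

#' First-order intensity features of a region
#'
#' The 18 IBSI-style first-order descriptors of the ROI intensity
#' distribution. Entropy (bits) and uniformity are computed on the
#' discretized gray levels; everything else on the raw intensities.
#' Population variance is used; skewness and kurtosis are the standardized
#' third and fourth moments (kurtosis not excess-corrected), both defined
#' as 0 for a constant region by convention.
#'
#' @param vol An [annotated_volume()] (or 3D array when `mask` given as
#'   array of the same shape).
#' @param mask Optional 3D logical array overriding `vol$mask` (used for
#'   shells and habitats).
#' @param disc A [discretization()].
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(vol, mask = NULL, disc = discretization()) {
  if (is_annotated_volume(vol)) {
    arr <- vol$intensities
    spacing <- vol$spacing
    if (is.null(mask)) mask <- vol$mask
  } else {
    arr <- vol
    spacing <- attr(vol, "spacing") %||% c(1, 1, 1)
    if (is.null(mask)) stopf("mask required when vol is a bare array")
  }
  v <- arr[array(as.logical(mask), dim = dim(arr))]
  if (length(v) == 0L) stopf("first_order_features: empty region")
  n <- length(v)
  m <- mean(v)
  va <- mean((v - m)^2)
  s <- sqrt(va)
  q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  lev <- discretize_values(v, disc)
  p <- tabulate(lev)
  p <- p[p > 0] / n
  inner <- v[v >= q[1] & v <= q[5]]
  out <- c(
    energy = sum(v^2),
    total_energy = sum(v^2) * prod(spacing),
    entropy = -sum(p * log2(p)),
    minimum = min(v),
    p10 = q[1], p90 = q[5],
    maximum = max(v),
    mean = m,
    median = q[3],
    iqr = q[4] - q[2],
    range = max(v) - min(v),
    mad = mean(abs(v - m)),
    rmad = if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    rms = sqrt(mean(v^2)),
    skewness = if (va > 0) mean((v - m)^3) / s^3 else 0,
    kurtosis = if (va > 0) mean((v - m)^4) / va^2 else 0,
    variance = va,
    uniformity = sum(p^2))
  names(out) <- .firstorder_feature_names
  out
}
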