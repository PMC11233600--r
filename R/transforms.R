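# 1D convolution along one axis of a 3D array with reflect padding.
# `kern` must have odd length; taps are centred.
conv_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  h <- (length(kern) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  m <- matrix(x, nrow = dp[1])
  n <- dp[1]
  # reflect padding (edge mirrored without repeating the border sample
  # when n > 1; degenerate axes replicate)
  refl <- function(i) {
    i <- abs(i - 1L) + 1L
    i <- ifelse(i > n, 2L * n - i, i)
    pmin(pmax(i, 1L), n)
  }
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(kern)) {
    src <- refl(seq_len(n) + (t - h - 1L))
    out <- out + kern[t] * m[src, , drop = FALSE]
  }
  y <- array(out, dim = dp)
  aperm(y, order(perm))
}

apply_separable <- function(arr, kernels) {
  for (a in 1:3) arr <- conv_axis(arr, kernels[[a]], a)
  arr
}

# Scale-normalized Laplacian-of-Gaussian response, sigma in mm,
# anisotropy-aware (kernels sampled at physical voxel coordinates).
log_filter <- function(arr, spacing, sigma) {
  gk <- list(); g2k <- list()
  for (a in 1:3) {
    h <- max(1L, ceiling(4 * sigma / spacing[a]))
    x <- (-h:h) * spacing[a]
    g <- exp(-x^2 / (2 * sigma^2))
    g <- g / sum(g)
    g2 <- (x^2 / sigma^4 - 1 / sigma^2) * exp(-x^2 / (2 * sigma^2)) * spacing[a]
    g2 <- g2 - mean(g2)   # exact zero response on constants
    gk[[a]] <- g; g2k[[a]] <- g2
  }
  res <- array(0, dim = dim(arr))
  for (a in 1:3) {
    kernels <- gk
    kernels[[a]] <- g2k[[a]]
    res <- res + apply_separable(arr, kernels)
  }
  sigma^2 * res
}

# Single-level undecimated (stationary) Haar sub-band: per axis, low-pass
# (v[i]+v[i+1])/sqrt(2) or high-pass (v[i]-v[i+1])/sqrt(2), edge replicated.
haar_axis <- function(arr, axis, high) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  m <- matrix(x, nrow = dp[1])
  nxt <- pmin(seq_len(dp[1]) + 1L, dp[1])
  out <- if (high) (m - m[nxt, , drop = FALSE]) / sqrt(2)
         else      (m + m[nxt, , drop = FALSE]) / sqrt(2)
  aperm(array(out, dim = dp), order(perm))
}

haar_subband <- function(arr, code) {
  stopifnot(nchar(code) == 3L)
  for (a in 1:3) {
    arr <- haar_axis(arr, a, substr(code, a, a) == "H")
  }
  arr
}

.wavelet_codes <- apply(expand.grid(c("L", "H"), c("L", "H"), c("L", "H")),
                        1, function(r) paste0(r[1], r[2], r[3]))

#' Image transform bank
#'
#' The transformed copies of a volume on which first-order and texture
#' features are re-extracted: the original image, scale-normalized
#' Laplacian-of-Gaussian responses at the configured sigmas (mm), and the 8
#' single-level undecimated 3D Haar wavelet sub-bands (LLL..HHH). All
#' outputs share the input grid, spacing and mask, so provenance tags are
#' the only difference downstream.
#'
#' A LoG sigma exceeding the ROI physical extent is skipped with a warning.
#'
#' @param vol A preprocessed [annotated_volume()].
#' @param log_sigmas_mm LoG sigmas in mm (default 1 and 2); `NULL` for none.
#' @param wavelet Include the 8 Haar sub-bands (default `TRUE`).
#' @return Named list of [annotated_volume()]s; names are the transform
#'   tags (`original`, `log_sigma_1` ..., `wavelet_LLL` ...).
#' @export
transform_bank <- function(vol, log_sigmas_mm = c(1, 2), wavelet = TRUE) {
  stopifnot(is_annotated_volume(vol))
  out <- list(original = vol)
  if (length(log_sigmas_mm)) {
    ext <- apply(arrayInd(which(vol$mask), dim(vol$mask)), 2, range)
    roi_extent <- max((ext[2, ] - ext[1, ] + 1) * vol$spacing)
    for (s in log_sigmas_mm) {
      if (s > roi_extent) {
        warnf("LoG sigma %g mm exceeds ROI extent (%g mm); skipped",
              s, roi_extent)
        next
      }
      v <- vol
      v$intensities <- log_filter(vol$intensities, vol$spacing, s)
      out[[sprintf("log_sigma_%g", s)]] <- v
    }
  }
  if (wavelet) {
    for (code in .wavelet_codes) {
      v <- vol
      v$intensities <- haar_subband(vol$intensities, code)
      out[[paste0("wavelet_", code)]] <- v
    }
  }
  out
}
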