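#' Morphological dilation of an ROI in physical units
#'
#' Dilates a binary mask by a Euclidean ball of radius `radius_mm`, aware of
#' anisotropic voxel spacing: the output is the set of voxels whose centres
#' lie within `radius_mm` of some input-voxel centre. Always a superset of
#' the input. If the dilation reaches the grid boundary a warning reports
#' how many voxels were clipped away.
#'
#' @param mask 3D logical array.
#' @param spacing_mm Numeric length-3 voxel size in mm.
#' @param radius_mm Dilation radius in mm (> 0).
#' @return 3D logical array.
#' @export
dilate_roi <- function(mask, spacing_mm, radius_mm) {
  stopifnot(length(dim(mask)) == 3L, length(spacing_mm) == 3L)
  if (radius_mm <= 0) stopf("radius_mm must be positive")
  mask <- array(as.logical(mask), dim = dim(mask))
  off <- ball_offsets(spacing_mm, radius_mm)
  pad <- apply(abs(off), 2, max)
  d <- dim(mask)
  dp <- d + 2L * pad
  padded <- array(FALSE, dp)
  padded[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
         pad[3] + seq_len(d[3])] <- mask
  out <- array(FALSE, dp)
  src <- which(padded)
  ijk <- arrayInd(src, dp)
  for (r in seq_len(nrow(off))) {
    tgt <- cbind(ijk[, 1] + off[r, 1], ijk[, 2] + off[r, 2],
                 ijk[, 3] + off[r, 3])
    out[tgt] <- TRUE
  }
  crop <- out[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
              pad[3] + seq_len(d[3]), drop = FALSE]
  dim(crop) <- d
  clipped <- sum(out) - sum(crop)
  if (clipped > 0)
    warnf("dilation reached the grid boundary; %d voxels clipped", clipped)
  crop
}

# Integer offsets whose physical displacement is within radius_mm.
ball_offsets <- function(spacing_mm, radius_mm) {
  nmax <- floor(radius_mm / spacing_mm)
  g <- expand.grid(x = -nmax[1]:nmax[1], y = -nmax[2]:nmax[2],
                   z = -nmax[3]:nmax[3])
  keep <- (g$x * spacing_mm[1])^2 + (g$y * spacing_mm[2])^2 +
    (g$z * spacing_mm[3])^2 <= radius_mm^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

#' Peritumoral shell around an ROI
#'
#' The dilated ROI minus the ROI itself: the surrounding-tissue region at a
#' given radial distance, disjoint from the tumor by construction.
#'
#' @inheritParams dilate_roi
#' @return 3D logical array.
#' @export
peritumoral_shell <- function(mask, spacing_mm, radius_mm) {
  dil <- dilate_roi(mask, spacing_mm, radius_mm)
  shell <- dil & !mask
  if (!any(shell))
    stopf("peritumoral shell at %g mm is empty (mask fills the grid)",
          radius_mm)
  shell
}

.local_channel_names <- c("mean", "median", "minimum", "maximum", "range",
                          "variance", "stddev", "skewness", "kurtosis",
                          "energy", "entropy", "uniformity", "cv")

#' Per-voxel local feature map for habitat clustering
#'
#' For every in-tumor voxel, 13 statistics of its 3x3x3 neighbourhood:
#' mean, median (lower median for even neighbourhood sizes), minimum,
#' maximum, range, variance, standard deviation, skewness, kurtosis,
#' energy (sum of squares), histogram entropy (fixed bin width, default 25
#' HU, bits), uniformity (sum of squared bin probabilities) and coefficient
#' of variation. Neighbourhoods are truncated to in-grid voxels at the
#' image boundary and, by default, restricted to the VOI (local features
#' describe tumor tissue, not the surrounding parenchyma; set
#' `mask_restrict = FALSE` for full-grid neighbourhoods).
#'
#' Conventions on degenerate neighbourhoods: a constant neighbourhood has
#' variance, stddev, skewness, kurtosis and entropy 0 and uniformity 1; the
#' coefficient of variation is 0 when the neighbourhood mean is 0.
#'
#' @param vol A preprocessed [annotated_volume()] with a nonempty mask.
#' @param bin_width_hu Histogram bin width for the entropy/uniformity
#'   channels, in HU.
#' @param mask_restrict Restrict neighbourhoods to in-mask voxels
#'   (default `TRUE`).
#' @return An object of class `local_feature_map`: list with `channels`
#'   (matrix, one row per in-tumor voxel, 13 named columns), `voxels`
#'   (linear indices of the in-tumor voxels), `dim` and `spacing`.
#' @export
local_feature_map <- function(vol, bin_width_hu = 25, mask_restrict = TRUE) {
  stopifnot(is_annotated_volume(vol))
  if (!any(vol$mask)) stopf("tumor mask is empty")
  d <- dim(vol$intensities)
  idx <- which(vol$mask)
  ijk <- arrayInd(idx, d)
  n <- length(idx)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- matrix(NA_real_, n, nrow(offs))
  for (r in seq_len(nrow(offs))) {
    ti <- ijk[, 1] + offs[r, 1]
    tj <- ijk[, 2] + offs[r, 2]
    tk <- ijk[, 3] + offs[r, 3]
    ok <- ti >= 1 & ti <= d[1] & tj >= 1 & tj <= d[2] & tk >= 1 & tk <= d[3]
    lin <- (tk[ok] - 1) * d[1] * d[2] + (tj[ok] - 1) * d[1] + ti[ok]
    val <- vol$intensities[lin]
    if (mask_restrict) val[!vol$mask[lin]] <- NA_real_
    nb[ok, r] <- val
  }
  lower_median <- function(v) sort(v)[ceiling(length(v) / 2)]
  ch <- matrix(NA_real_, n, 13L,
               dimnames = list(NULL, .local_channel_names))
  for (i in seq_len(n)) {
    v <- nb[i, ]
    v <- v[!is.na(v)]
    m <- mean(v)
    va <- mean((v - m)^2)
    s <- sqrt(va)
    ch[i, 1] <- m
    ch[i, 2] <- lower_median(v)
    ch[i, 3] <- min(v)
    ch[i, 4] <- max(v)
    ch[i, 5] <- max(v) - min(v)
    ch[i, 6] <- va
    ch[i, 7] <- s
    ch[i, 8] <- if (va > 0) mean((v - m)^3) / s^3 else 0
    ch[i, 9] <- if (va > 0) mean((v - m)^4) / va^2 else 0
    ch[i, 10] <- sum(v^2)
    p <- tabulate(floor(v / bin_width_hu) - min(floor(v / bin_width_hu)) + 1)
    p <- p[p > 0] / length(v)
    ch[i, 11] <- -sum(p * log2(p))
    ch[i, 12] <- sum(p^2)
    ch[i, 13] <- if (abs(m) > 1e-12) s / m else 0
  }
  structure(list(channels = ch, voxels = idx, dim = d,
                 spacing = vol$spacing, bin_width_hu = bin_width_hu),
            class = "local_feature_map")
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, then
# proportional to squared distance to the nearest chosen centre; centres
# are kept pairwise distinct (requires > k unique rows).
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
  for (j in seq_len(k - 1L)) {
    cand <- which(d2 > 1e-12)
    if (length(cand) == 0L) stopf("fewer than k distinct feature vectors")
    i <- if (length(cand) == 1L) cand else
      sample(cand, 1L, prob = d2[cand])
    centers[j + 1L, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1L, ], "-")^2))
  }
  centers
}

#' Habitat subregions by K-means on local features
#'
#' Z-scores the selected local-feature channels within the tumor, clusters
#' the per-voxel feature vectors with K-means (k-means++ seeding, 10
#' restarts, Lloyd iterations, tolerance via convergence of Lloyd steps),
#' and relabels clusters in increasing order of their mean local-intensity
#' channel so the numbering is deterministic. Empty clusters are permitted
#' and reported via the `"empty_clusters"` attribute.
#'
#' By default clustering uses the location channels (`mean`, `median`):
#' dispersion-type channels (range, variance, entropy, ...) take extreme
#' values on the one-voxel interface layer between tissue classes and on
#' truncated boundary neighbourhoods, so after z-scoring they dominate the
#' K-means objective and the optimum separates interface voxels from
#' interior voxels instead of separating tissue classes — piecewise-
#' constant planted partitions then become unrecoverable even without
#' noise. Pass `channels = NULL` to cluster on all 13 channels.
#'
#' @param map A [local_feature_map()].
#' @param k Number of habitats (default 3).
#' @param seed RNG seed for the seeding/restarts.
#' @param nstart Number of k-means++ restarts.
#' @param iter_max Maximum Lloyd iterations per restart.
#' @param channels Channel names used for clustering; `NULL` for all 13.
#' @return Integer 3D array: 0 outside the tumor, habitat label 1..k inside.
#' @export
kmeans_habitats <- function(map, k = 3L, seed = NULL, nstart = 10L,
                            iter_max = 100L,
                            channels = c("mean", "median")) {
  stopifnot(inherits(map, "local_feature_map"))
  n <- nrow(map$channels)
  if (n < k) stopf("tumor has %d voxels, fewer than k = %d", n, k)
  if (is.null(channels)) channels <- colnames(map$channels)
  channels <- match.arg(channels, colnames(map$channels), several.ok = TRUE)
  x <- scale(map$channels[, channels, drop = FALSE])
  x[, attr(x, "scaled:scale") == 0 | !is.finite(attr(x, "scaled:scale"))] <- 0
  x[!is.finite(x)] <- 0
  ux <- unique(x)
  if (nrow(ux) <= k) {
    # at most k distinct feature vectors: each gets its own cluster
    cl <- list(cluster = match(apply(x, 1, paste, collapse = "\r"),
                               apply(ux, 1, paste, collapse = "\r")))
  } else {
    cl <- with_seed(seed, {
      best <- NULL
      for (s in seq_len(nstart)) {
        centers <- kmeanspp_centers(x, k)
        fit <- suppressWarnings(tryCatch(
          stats::kmeans(x, centers = centers, iter.max = iter_max,
                        algorithm = "Lloyd"),
          error = function(e) NULL))
        if (is.null(fit)) next
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      if (is.null(best)) stopf("k-means failed on all restarts")
      best
    })
  }
  # deterministic renumbering by increasing cluster-mean local intensity
  mu <- tapply(map$channels[, "mean"], cl$cluster, mean)
  present <- as.integer(names(mu))
  ord <- present[order(mu)]
  relab <- integer(k)
  relab[ord] <- seq_along(ord)
  lab <- relab[cl$cluster]
  out <- array(0L, dim = map$dim)
  out[map$voxels] <- lab
  empty <- setdiff(seq_len(k), unique(lab))
  attr(out, "empty_clusters") <- empty
  out
}

#' Construct the full region set for one sample
#'
#' Tumor mask, peritumoral shells at the configured radii, and habitat
#' labels from K-means on the 13-channel local feature map.
#'
#' @param vol A preprocessed [annotated_volume()].
#' @param shell_radii_mm Peritumoral dilation radii in mm (default 1, 3, 5).
#' @param k Number of habitats.
#' @param seed RNG seed for habitat clustering.
#' @param bin_width_hu Entropy bin width for the local feature map.
#' @param channels Channels used for habitat clustering (see
#'   [kmeans_habitats()]).
#' @return An object of class `region_set`: list with `tumor_mask`, `shells`
#'   (named list `peri1`, `peri3`, ... of logical arrays), `habitat_labels`
#'   (integer array) and `spacing`.
#' @export
region_set <- function(vol, shell_radii_mm = c(1, 3, 5), k = 3L,
                       seed = NULL, bin_width_hu = 25,
                       channels = c("mean", "median")) {
  stopifnot(is_annotated_volume(vol))
  shells <- lapply(shell_radii_mm, function(r)
    peritumoral_shell(vol$mask, vol$spacing, r))
  names(shells) <- paste0("peri", shell_radii_mm)
  map <- local_feature_map(vol, bin_width_hu = bin_width_hu)
  hab <- kmeans_habitats(map, k = k, seed = seed, channels = channels)
  structure(list(tumor_mask = vol$mask, shells = shells,
                 habitat_labels = hab, spacing = vol$spacing,
                 shell_radii_mm = shell_radii_mm, k = k),
            class = "region_set")
}

#' Write a region set as integer NIfTI label maps
#'
#' @param rs A [region_set()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_region_set <- function(rs, dir, prefix = "sample") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(arr, name) {
    p <- file.path(dir, paste0(prefix, "_", name, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(arr), dim = dim(arr)),
                                       pixdim = rs$spacing), p)
    p
  }
  paths <- c(paths, wr(rs$tumor_mask, "tumor"))
  for (nm in names(rs$shells)) paths <- c(paths, wr(rs$shells[[nm]], nm))
  paths <- c(paths, wr(rs$habitat_labels, "habitats"))
  invisible(paths)
}
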