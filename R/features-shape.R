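# 6-tetrahedra decomposition of the unit cube, all sharing diagonal v0-v6.
# Cube vertex offsets, in the order used by cell corner extraction.
.cube_verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                     c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
.cube_tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                    c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

# Per-cell corner values of a padded scalar field (pad width 1; cells are
# the dual lattice between voxel centres).
cell_corners <- function(field) {
  dp <- dim(field)
  nc <- dp - 1L
  lapply(1:8, function(v) {
    o <- .cube_verts[v, ]
    field[o[1] + seq_len(nc[1]), o[2] + seq_len(nc[2]),
          o[3] + seq_len(nc[3]), drop = FALSE]
  })
}

pad_field <- function(arr, fill = 0) {
  d <- dim(arr)
  P <- array(fill, d + 2L)
  P[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- arr
  P
}

# Area and enclosed volume of the `iso` level set of a scalar field by
# marching tetrahedra with linear edge interpolation, vectorized over
# cells by inside-pattern. The field is zero-padded, so the surface is
# closed; the inside volume is assembled geometrically per tetrahedron
# (corner sub-tets, wedges, full tets) plus the fully-inside cells, and
# the area is the summed triangle area of the same surface — so area and
# volume describe the same polyhedral solid, which bounds sphericity by 1
# (isoperimetric inequality).
mesh_measures_field <- function(field, spacing, iso = 0.5) {
  P <- pad_field(field)
  cv <- cell_corners(P)
  nin <- Reduce(`+`, lapply(cv, function(a) (a > iso) + 0L))
  mixed <- which(nin > 0L & nin < 8L)
  cellvol <- prod(spacing)
  nc <- dim(P) - 1L
  area <- 0
  volume <- 0
  if (!length(mixed)) return(c(area = 0, volume = sum(nin == 8L) * cellvol))
  base <- (arrayInd(mixed, nc) - 1L) %*% diag(spacing)
  fvals <- vapply(cv, function(a) a[mixed], numeric(length(mixed)))
  if (is.null(dim(fvals))) fvals <- matrix(fvals, nrow = 1L)
  vert_pos <- function(rows, v) {
    base[rows, , drop = FALSE] +
      matrix(.cube_verts[v, ] * spacing, length(rows), 3, byrow = TRUE)
  }
  cross_pt <- function(rows, va, vb, fa, fb) {
    A <- vert_pos(rows, va); B <- vert_pos(rows, vb)
    A + (B - A) * ((iso - fa) / (fb - fa))
  }
  for (t in 1:6) {
    vid <- .cube_tets[t, ]
    tf <- fvals[, vid, drop = FALSE]
    ti <- tf > iso
    cnt <- rowSums(ti)
    # fully-inside tetrahedra of mixed cells: closed-form volume
    volume <- volume + sum(cnt == 4L) * cellvol / 6
    for (apex_in in c(TRUE, FALSE)) {
      rows <- which(if (apex_in) cnt == 1L else cnt == 3L)
      if (!length(rows)) next
      flag <- if (apex_in) ti[rows, , drop = FALSE]
              else !ti[rows, , drop = FALSE]
      apex <- max.col(flag, ties.method = "first")
      for (ap in unique(apex)) {
        rr <- rows[apex == ap]
        rest <- setdiff(1:4, ap)
        fa <- tf[rr, ap]
        p1 <- cross_pt(rr, vid[ap], vid[rest[1]], fa, tf[rr, rest[1]])
        p2 <- cross_pt(rr, vid[ap], vid[rest[2]], fa, tf[rr, rest[2]])
        p3 <- cross_pt(rr, vid[ap], vid[rest[3]], fa, tf[rr, rest[3]])
        # corner sub-tetrahedron at the apex: apex + three crossings
        A <- vert_pos(rr, vid[ap])
        det <- (p1[, 1] - A[, 1]) * ((p2[, 2] - A[, 2]) * (p3[, 3] - A[, 3]) -
                                      (p2[, 3] - A[, 3]) * (p3[, 2] - A[, 2])) -
               (p1[, 2] - A[, 2]) * ((p2[, 1] - A[, 1]) * (p3[, 3] - A[, 3]) -
                                      (p2[, 3] - A[, 3]) * (p3[, 1] - A[, 1])) +
               (p1[, 3] - A[, 3]) * ((p2[, 1] - A[, 1]) * (p3[, 2] - A[, 2]) -
                                      (p2[, 2] - A[, 2]) * (p3[, 1] - A[, 1]))
        corner <- sum(abs(det)) / 6
        volume <- volume + if (apex_in) corner else
          length(rr) * cellvol / 6 - corner
        u <- p2 - p1; w <- p3 - p1
        area <- area + sum(0.5 * sqrt(
          (u[, 2] * w[, 3] - u[, 3] * w[, 2])^2 +
          (u[, 3] * w[, 1] - u[, 1] * w[, 3])^2 +
          (u[, 1] * w[, 2] - u[, 2] * w[, 1])^2))
      }
    }
    rows <- which(cnt == 2L)
    if (length(rows)) {
      pat <- ti[rows, 1] * 1L + ti[rows, 2] * 2L + ti[rows, 3] * 4L +
        ti[rows, 4] * 8L
      for (pp in unique(pat)) {
        rr <- rows[pat == pp]
        inn <- which(bitwAnd(pp, c(1L, 2L, 4L, 8L)) > 0L)
        out <- setdiff(1:4, inn)
        Ain <- vert_pos(rr, vid[inn[1]])
        Bin <- vert_pos(rr, vid[inn[2]])
        q1 <- cross_pt(rr, vid[inn[1]], vid[out[1]], tf[rr, inn[1]],
                       tf[rr, out[1]])
        q2 <- cross_pt(rr, vid[inn[1]], vid[out[2]], tf[rr, inn[1]],
                       tf[rr, out[2]])
        q3 <- cross_pt(rr, vid[inn[2]], vid[out[2]], tf[rr, inn[2]],
                       tf[rr, out[2]])
        q4 <- cross_pt(rr, vid[inn[2]], vid[out[1]], tf[rr, inn[2]],
                       tf[rr, out[1]])
        u <- q2 - q1; w <- q3 - q1
        area <- area + sum(0.5 * sqrt(
          (u[, 2] * w[, 3] - u[, 3] * w[, 2])^2 +
          (u[, 3] * w[, 1] - u[, 1] * w[, 3])^2 +
          (u[, 1] * w[, 2] - u[, 2] * w[, 1])^2))
        u <- q3 - q1; w <- q4 - q1
        area <- area + sum(0.5 * sqrt(
          (u[, 2] * w[, 3] - u[, 3] * w[, 2])^2 +
          (u[, 3] * w[, 1] - u[, 1] * w[, 3])^2 +
          (u[, 1] * w[, 2] - u[, 2] * w[, 1])^2))
        # wedge volume: decompose (Ain, Bin, q1..q4) into three
        # tetrahedra sharing the quad diagonal q1-q3
        tet_vol <- function(P1, P2, P3, P4) {
          a <- P2 - P1; b <- P3 - P1; cc <- P4 - P1
          abs(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
              a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
              a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
        }
        volume <- volume +
          sum(tet_vol(Ain, q1, q2, q3)) +
          sum(tet_vol(Ain, q1, q3, q4)) +
          sum(tet_vol(Ain, q4, q3, Bin))
      }
    }
  }
  volume <- volume + sum(nin == 8L) * cellvol
  c(area = area, volume = volume)
}

# 3x3x3 box smoothing of a binary mask (zero-padded), used to place the
# iso-surface at sub-voxel positions before meshing; without it the
# all-midpoint staircase mesh overestimates curved surface areas.
box_smooth_mask <- function(mask) {
  arr <- pad_field(mask + 0)
  k <- c(1, 1, 1) / 3
  for (a in 1:3) arr <- conv_axis(arr, k, a)
  d <- dim(mask)
  out <- arr[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3]),
             drop = FALSE]
  array(out, dim = d)
}

# Surface mesh area and enclosed volume of a binary mask, both measured on
# the marching-tetrahedra mesh of the box-smoothed indicator field (or of
# the raw binary field with midpoint crossings when `smooth = FALSE`). The
# smoothed field must still cross 0.5 somewhere; tiny masks that smooth
# away fall back to the binary mesh.
mesh_area_volume <- function(mask, spacing, smooth = TRUE) {
  if (smooth) {
    sm <- box_smooth_mask(mask)
    if (max(sm) > 0.5) return(mesh_measures_field(sm, spacing, iso = 0.5))
  }
  mesh_measures_field(mask + 0, spacing, iso = 0.5)
}

# Boundary voxels: in-mask voxels with an out-of-mask (or out-of-grid)
# face neighbour.
boundary_voxels <- function(mask) {
  d <- dim(mask)
  P <- array(FALSE, d + 2L)
  P[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- mask
  inner <- mask
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    inner <- inner & P[1L + o[1] + seq_len(d[1]), 1L + o[2] + seq_len(d[2]),
                       1L + o[3] + seq_len(d[3])]
  }
  mask & !inner
}

# Largest pairwise distance within a coordinate matrix, chunked to bound
# memory.
max_pairwise_dist <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2L) return(0)
  best <- 0
  chunk <- 512L
  sq <- rowSums(xyz^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    cross <- xyz[s:e, , drop = FALSE] %*% t(xyz)
    d2 <- outer(sq[s:e], rep(1, n)) + outer(rep(1, e - s + 1L), sq) - 2 * cross
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

.shape_feature_names <- c("mesh_volume", "voxel_volume", "surface_area",
                          "surface_volume_ratio", "sphericity",
                          "max_3d_diameter", "max_2d_diameter_slice",
                          "max_2d_diameter_column", "max_2d_diameter_row",
                          "major_axis_length", "minor_axis_length",
                          "least_axis_length", "elongation", "flatness")

#' Shape (geometry) features of a region mask
#'
#' The 14 IBSI-style shape descriptors, intensity-independent: mesh volume
#' and surface area (marching tetrahedra at the 0.5 iso-level), voxel-count
#' volume, surface-to-volume ratio, sphericity, maximum 3D diameter and the
#' three maximum in-plane 2D diameters (between boundary-voxel centres),
#' and the PCA axis lengths (4 sqrt of the eigenvalues of the physical
#' voxel-centre covariance) with elongation and flatness.
#'
#' A single-voxel (or otherwise axis-degenerate) mask yields zero axis
#' lengths with elongation and flatness set to 1 by convention, and the
#' result carries attribute `degenerate = TRUE`.
#'
#' @param mask 3D logical array, nonempty.
#' @param spacing Numeric length-3 voxel size in mm.
#' @return Named numeric vector of 14 features (mm-based units).
#' @export
shape_features <- function(mask, spacing) {
  stopifnot(length(dim(mask)) == 3L)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stopf("shape_features: empty mask")
  av <- mesh_area_volume(mask, spacing)
  A <- av[["area"]]; V <- av[["volume"]]
  vox_vol <- sum(mask) * prod(spacing)
  bnd <- boundary_voxels(mask)
  ijk <- arrayInd(which(bnd), dim(mask))
  xyz <- (ijk - 1L) %*% diag(spacing)
  d3 <- max_pairwise_dist(xyz)
  plane_max <- function(split_axis, keep_axes) {
    groups <- split(seq_len(nrow(xyz)), ijk[, split_axis])
    max(vapply(groups, function(g)
      max_pairwise_dist(xyz[g, keep_axes, drop = FALSE]), 0))
  }
  d2_slice <- plane_max(3L, c(1L, 2L))   # axial plane
  d2_col <- plane_max(1L, c(2L, 3L))
  d2_row <- plane_max(2L, c(1L, 3L))
  all_xyz <- (arrayInd(which(mask), dim(mask)) - 1L) %*% diag(spacing)
  degenerate <- nrow(all_xyz) < 2L
  if (degenerate) {
    ev <- c(0, 0, 0)
  } else {
    ev <- sort(eigen(stats::cov(all_xyz), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  }
  axis_len <- 4 * sqrt(ev)
  if (ev[1] > 0) {
    elong <- sqrt(ev[2] / ev[1]); flat <- sqrt(ev[3] / ev[1])
  } else {
    degenerate <- TRUE
    elong <- 1; flat <- 1
  }
  sph <- if (A > 0) pi^(1 / 3) * (6 * V)^(2 / 3) / A else 0
  out <- c(V, vox_vol, A, if (V > 0) A / V else 0, sph,
           d3, d2_slice, d2_col, d2_row,
           axis_len[1], axis_len[2], axis_len[3], elong, flat)
  names(out) <- .shape_feature_names
  attr(out, "degenerate") <- degenerate
  out
}
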