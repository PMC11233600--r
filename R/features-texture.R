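# The 13 unique 3D directions (one per symmetric pair of the 26-neighbourhood).
.directions13 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
})

# Neighbour linear indices for voxels `ijk` at integer offset `off`;
# returns validity flags and linear indices (only valid entries meaningful).
neighbor_index <- function(d, ijk, off) {
  ti <- ijk[, 1] + off[1]; tj <- ijk[, 2] + off[2]; tk <- ijk[, 3] + off[3]
  ok <- ti >= 1 & ti <= d[1] & tj >= 1 & tj <= d[2] & tk >= 1 & tk <= d[3]
  lin <- (tk - 1) * d[1] * d[2] + (tj - 1) * d[1] + ti
  list(ok = ok, lin = lin)
}

# Discretized level array: integer levels at mask voxels, NA elsewhere.
level_array <- function(arr, mask, disc) {
  lev <- array(NA_integer_, dim = dim(arr))
  lev[mask] <- discretize_values(arr[mask], disc)
  lev
}

## ---- GLCM --------------------------------------------------------------

glcm_matrix <- function(lev, d, idx, ijk, off, ng) {
  nb <- neighbor_index(d, ijk, off)
  li <- lev[idx]
  lj <- rep(NA_integer_, length(idx))
  lj[nb$ok] <- lev[nb$lin[nb$ok]]
  ok <- !is.na(lj)
  if (!any(ok)) return(NULL)
  P <- matrix(0, ng, ng)
  cnt <- tabulate((li[ok] - 1L) * ng + lj[ok], nbins = ng * ng)
  P <- matrix(cnt, ng, ng, byrow = TRUE)
  P + t(P)   # symmetric
}

.glcm_feature_names <- c(
  "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_average",
  "difference_entropy", "difference_variance", "joint_energy",
  "joint_entropy", "imc1", "imc2", "idm", "idmn", "id", "idn",
  "inverse_variance", "maximum_probability", "sum_average", "sum_entropy",
  "sum_squares", "mcc")

glcm_features_from_matrix <- function(P) {
  p <- P / sum(P)
  ng <- nrow(p)
  I <- row(p); J <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px)); sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  # diagonal-band and anti-diagonal-band distributions
  kdiff <- 0:(ng - 1)
  pxmy <- vapply(kdiff, function(k) sum(p[abs(I - J) == k]), 0)
  ksum <- 2:(2 * ng)
  pxpy <- vapply(ksum, function(k) sum(p[(I + J) == k]), 0)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  HX <- ent(px); HY <- ent(py); HXY <- ent(p)
  ppij <- outer(px, py)
  pos <- p > 0
  HXY1 <- -sum(p[pos] * log2(pmax(ppij[pos], .Machine$double.xmin)))
  qpos <- ppij > 0
  HXY2 <- -sum(ppij[qpos] * log2(ppij[qpos]))
  da <- sum(kdiff * pxmy)
  corr <- if (sx > 0 && sy > 0) (sum(I * J * p) - mux * muy) / (sx * sy) else 1
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  offdiag <- I != J
  # MCC: second largest eigenvalue of Q(i,j) = sum_k p(i,k)p(j,k)/(px(i)py(k))
  lv <- which(px > 0)
  mcc <- 1
  if (length(lv) > 1) {
    A <- sweep(p[lv, lv, drop = FALSE], 1, px[lv], "/")
    B <- sweep(p[lv, lv, drop = FALSE], 2, py[lv], "/")
    Q <- A %*% t(B)
    evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(pmax(0, evq[2]))
  }
  c(autocorrelation = sum(I * J * p),
    joint_average = mux,
    cluster_prominence = sum((I + J - mux - muy)^4 * p),
    cluster_shade = sum((I + J - mux - muy)^3 * p),
    cluster_tendency = sum((I + J - mux - muy)^2 * p),
    contrast = sum((I - J)^2 * p),
    correlation = corr,
    difference_average = da,
    difference_entropy = ent(pxmy),
    difference_variance = sum((kdiff - da)^2 * pxmy),
    joint_energy = sum(p^2),
    joint_entropy = HXY,
    imc1 = imc1,
    imc2 = imc2,
    idm = sum(p / (1 + (I - J)^2)),
    idmn = sum(p / (1 + ((I - J) / ng)^2)),
    id = sum(p / (1 + abs(I - J))),
    idn = sum(p / (1 + abs(I - J) / ng)),
    inverse_variance = sum(p[offdiag] / (I[offdiag] - J[offdiag])^2),
    maximum_probability = max(p),
    sum_average = sum(ksum * pxpy),
    sum_entropy = ent(pxpy),
    sum_squares = sum((I - mux)^2 * p),
    mcc = mcc)
}

glcm_features <- function(arr, mask, disc = discretization()) {
  d <- dim(arr)
  lev <- level_array(arr, mask, disc)
  idx <- which(mask)
  ijk <- arrayInd(idx, d)
  ng <- max(lev, na.rm = TRUE)
  per_dir <- list()
  for (r in seq_len(nrow(.directions13))) {
    P <- glcm_matrix(lev, d, idx, ijk, .directions13[r, ], ng)
    if (!is.null(P)) per_dir[[length(per_dir) + 1L]] <- glcm_features_from_matrix(P)
  }
  if (length(per_dir) == 0L)
    per_dir <- list(glcm_features_from_matrix(matrix(2, 1, 1)))
  out <- colMeans(do.call(rbind, per_dir))
  names(out) <- .glcm_feature_names
  out
}

## ---- GLRLM -------------------------------------------------------------

glrlm_matrix <- function(lev, d, idx, ijk, off, ng) {
  pred <- neighbor_index(d, ijk, off * -1L)
  li <- lev[idx]
  predlev <- rep(NA_integer_, length(idx))
  predlev[pred$ok] <- lev[pred$lin[pred$ok]]
  is_start <- is.na(predlev) | predlev != li
  starts <- which(is_start)
  maxlen <- max(d)
  counts <- matrix(0, ng, maxlen)
  linidx <- (ijk[, 3] - 1) * d[1] * d[2] + (ijk[, 2] - 1) * d[1] + ijk[, 1]
  for (s in starts) {
    l <- li[s]
    len <- 1L
    ci <- ijk[s, 1]; cj <- ijk[s, 2]; ck <- ijk[s, 3]
    repeat {
      ci <- ci + off[1]; cj <- cj + off[2]; ck <- ck + off[3]
      if (ci < 1 || ci > d[1] || cj < 1 || cj > d[2] || ck < 1 || ck > d[3])
        break
      nl <- lev[(ck - 1) * d[1] * d[2] + (cj - 1) * d[1] + ci]
      if (is.na(nl) || nl != l) break
      len <- len + 1L
    }
    counts[l, len] <- counts[l, len] + 1
  }
  counts
}

.glrlm_feature_names <- c(
  "short_run_emphasis", "long_run_emphasis", "gray_level_nonuniformity",
  "gray_level_nonuniformity_normalized", "run_length_nonuniformity",
  "run_length_nonuniformity_normalized", "run_percentage",
  "gray_level_variance", "run_variance", "run_entropy",
  "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
  "short_run_low_gray_level_emphasis", "short_run_high_gray_level_emphasis",
  "long_run_low_gray_level_emphasis", "long_run_high_gray_level_emphasis")

size_family_features <- function(P, np, names_out) {
  # shared formulas for run-length / size-zone style matrices:
  # P indexed by gray level i (rows) and size/length j (columns)
  nr <- sum(P)
  i <- row(P); j <- col(P)
  p <- P / nr
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  ppos <- p[p > 0]
  out <- c(
    sum(P / j^2) / nr,
    sum(P * j^2) / nr,
    sum(rowSums(P)^2) / nr,
    sum(rowSums(P)^2) / nr^2,
    sum(colSums(P)^2) / nr,
    sum(colSums(P)^2) / nr^2,
    nr / np,
    sum((i - mu_i)^2 * p),
    sum((j - mu_j)^2 * p),
    -sum(ppos * log2(ppos)),
    sum(P / i^2) / nr,
    sum(P * i^2) / nr,
    sum(P / (i^2 * j^2)) / nr,
    sum(P * i^2 / j^2) / nr,
    sum(P * j^2 / i^2) / nr,
    sum(P * i^2 * j^2) / nr)
  names(out) <- names_out
  out
}

glrlm_features <- function(arr, mask, disc = discretization()) {
  d <- dim(arr)
  lev <- level_array(arr, mask, disc)
  idx <- which(mask)
  ijk <- arrayInd(idx, d)
  ng <- max(lev, na.rm = TRUE)
  np <- length(idx)
  per_dir <- lapply(seq_len(nrow(.directions13)), function(r) {
    P <- glrlm_matrix(lev, d, idx, ijk, .directions13[r, ], ng)
    size_family_features(P, np, .glrlm_feature_names)
  })
  out <- colMeans(do.call(rbind, per_dir))
  names(out) <- .glrlm_feature_names
  out
}

## ---- GLSZM -------------------------------------------------------------

# Connected zones of equal gray level, 26-connectivity.
glszm_matrix <- function(lev, d, idx, ng) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  visited <- array(FALSE, d)
  maxsize <- length(idx)
  zones <- list()
  for (v in idx) {
    if (visited[v]) next
    l <- lev[v]
    # BFS flood fill
    queue <- v
    visited[v] <- TRUE
    size <- 0L
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      size <- size + length(cur)
      cijk <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        nb <- neighbor_index(d, cijk, offs[r, ])
        cand <- nb$lin[nb$ok]
        cand <- cand[!visited[cand] & !is.na(lev[cand]) & lev[cand] == l]
        if (length(cand)) {
          cand <- unique(cand)
          visited[cand] <- TRUE
          queue <- c(queue, cand)
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(l, size)
  }
  zm <- do.call(rbind, zones)
  P <- matrix(0, ng, max(zm[, 2]))
  for (r in seq_len(nrow(zm))) P[zm[r, 1], zm[r, 2]] <- P[zm[r, 1], zm[r, 2]] + 1
  P
}

.glszm_feature_names <- c(
  "small_area_emphasis", "large_area_emphasis", "gray_level_nonuniformity",
  "gray_level_nonuniformity_normalized", "size_zone_nonuniformity",
  "size_zone_nonuniformity_normalized", "zone_percentage",
  "gray_level_variance", "zone_variance", "zone_entropy",
  "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
  "small_area_low_gray_level_emphasis", "small_area_high_gray_level_emphasis",
  "large_area_low_gray_level_emphasis", "large_area_high_gray_level_emphasis")

glszm_features <- function(arr, mask, disc = discretization()) {
  d <- dim(arr)
  lev <- level_array(arr, mask, disc)
  idx <- which(mask)
  ng <- max(lev, na.rm = TRUE)
  P <- glszm_matrix(lev, d, idx, ng)
  size_family_features(P, length(idx), .glszm_feature_names)
}

## ---- GLDM --------------------------------------------------------------

.gldm_feature_names <- c(
  "small_dependence_emphasis", "large_dependence_emphasis",
  "gray_level_nonuniformity", "dependence_nonuniformity",
  "dependence_nonuniformity_normalized", "gray_level_variance",
  "dependence_variance", "dependence_entropy", "low_gray_level_emphasis",
  "high_gray_level_emphasis", "small_dependence_low_gray_level_emphasis",
  "small_dependence_high_gray_level_emphasis",
  "large_dependence_low_gray_level_emphasis",
  "large_dependence_high_gray_level_emphasis")

gldm_features <- function(arr, mask, disc = discretization(), alpha = 0) {
  d <- dim(arr)
  lev <- level_array(arr, mask, disc)
  idx <- which(mask)
  ijk <- arrayInd(idx, d)
  ng <- max(lev, na.rm = TRUE)
  li <- lev[idx]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  dep <- integer(length(idx))
  for (r in seq_len(nrow(offs))) {
    nb <- neighbor_index(d, ijk, offs[r, ])
    nl <- rep(NA_integer_, length(idx))
    nl[nb$ok] <- lev[nb$lin[nb$ok]]
    dep <- dep + (!is.na(nl) & abs(nl - li) <= alpha)
  }
  nd <- max(dep) + 1L
  P <- matrix(tabulate((li - 1L) * nd + dep + 1L, nbins = ng * nd),
              ng, nd, byrow = TRUE)
  nz <- sum(P)
  i <- row(P); j <- col(P)   # j = dependence size (count + 1)
  p <- P / nz
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  ppos <- p[p > 0]
  out <- c(
    sum(P / j^2) / nz,
    sum(P * j^2) / nz,
    sum(rowSums(P)^2) / nz,
    sum(colSums(P)^2) / nz,
    sum(colSums(P)^2) / nz^2,
    sum((i - mu_i)^2 * p),
    sum((j - mu_j)^2 * p),
    -sum(ppos * log2(ppos)),
    sum(P / i^2) / nz,
    sum(P * i^2) / nz,
    sum(P / (i^2 * j^2)) / nz,
    sum(P * i^2 / j^2) / nz,
    sum(P * j^2 / i^2) / nz,
    sum(P * i^2 * j^2) / nz)
  names(out) <- .gldm_feature_names
  out
}

## ---- NGTDM -------------------------------------------------------------

.ngtdm_feature_names <- c("coarseness", "contrast", "busyness", "complexity",
                          "strength")

# Convention cap for coarseness when the denominator vanishes (constant or
# single-voxel regions), matching common radiomics practice.
.ngtdm_coarseness_cap <- 1e6

ngtdm_features <- function(arr, mask, disc = discretization()) {
  d <- dim(arr)
  lev <- level_array(arr, mask, disc)
  idx <- which(mask)
  ijk <- arrayInd(idx, d)
  ng <- max(lev, na.rm = TRUE)
  li <- lev[idx]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nsum <- numeric(length(idx))
  ncnt <- integer(length(idx))
  for (r in seq_len(nrow(offs))) {
    nb <- neighbor_index(d, ijk, offs[r, ])
    nl <- rep(NA_real_, length(idx))
    nl[nb$ok] <- lev[nb$lin[nb$ok]]
    has <- !is.na(nl)
    nsum[has] <- nsum[has] + nl[has]
    ncnt <- ncnt + has
  }
  valid <- ncnt > 0
  nvp <- sum(valid)
  absdiff <- abs(li[valid] - nsum[valid] / ncnt[valid])
  s <- vapply(1:ng, function(g) sum(absdiff[li[valid] == g]), 0)
  cnt <- tabulate(li[valid], nbins = ng)
  p <- cnt / nvp
  present <- which(p > 0)
  ngp <- length(present)
  ps <- sum(p * s)
  coarseness <- if (ps > 0) 1 / ps else .ngtdm_coarseness_cap
  if (ngp > 1) {
    pij <- outer(p[present], p[present])
    dij2 <- outer(present, present, function(a, b) (a - b)^2)
    contrast <- sum(pij * dij2) / (ngp * (ngp - 1)) * sum(s) / nvp
    ipi <- present * p[present]
    busy_den <- sum(abs(outer(ipi, ipi, "-")))
    busyness <- if (busy_den > 0) ps / busy_den else 0
    pi_ <- p[present]; si_ <- s[present]
    num <- outer(pi_ * si_, pi_ * si_, "+")
    absd <- abs(outer(present, present, "-"))
    den <- outer(pi_, pi_, "+")
    complexity <- sum(absd * num / den) / nvp
    strength <- if (sum(s) > 0) sum(outer(pi_, pi_, "+") * dij2) / sum(s) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  out <- c(coarseness, contrast, busyness, complexity, strength)
  names(out) <- .ngtdm_feature_names
  out
}

## ---- combined ----------------------------------------------------------

.texture_families <- c(glcm = 24L, glrlm = 16L, glszm = 16L, gldm = 14L,
                       ngtdm = 5L)

#' Texture features of a region
#'
#' The 75 texture features across the five standard families: gray-level
#' co-occurrence (GLCM, 24), run length (GLRLM, 16), size zone (GLSZM, 16),
#' dependence (GLDM, 14) and neighbourhood gray-tone difference (NGTDM, 5),
#' per IBSI-style definitions. GLCM and GLRLM are computed per 3D direction
#' (the 13 unique offsets of the 26-neighbourhood) and averaged; GLCM
#' matrices are symmetric. Degenerate regions (constant intensity, single
#' voxel) return documented convention values rather than NaN.
#'
#' @inheritParams first_order_features
#' @return Named numeric vector of 75 features, names prefixed with the
#'   family (e.g. `glcm_contrast`); attribute `family` gives the family of
#'   each entry.
#' @export
texture_features <- function(vol, mask = NULL, disc = discretization()) {
  if (is_annotated_volume(vol)) {
    arr <- vol$intensities
    if (is.null(mask)) mask <- vol$mask
  } else {
    arr <- vol
    if (is.null(mask)) stopf("mask required when vol is a bare array")
  }
  mask <- array(as.logical(mask), dim = dim(arr))
  if (!any(mask)) stopf("texture_features: empty region")
  vals <- list(glcm = glcm_features(arr, mask, disc),
               glrlm = glrlm_features(arr, mask, disc),
               glszm = glszm_features(arr, mask, disc),
               gldm = gldm_features(arr, mask, disc),
               ngtdm = ngtdm_features(arr, mask, disc))
  out <- unlist(lapply(names(vals), function(f) {
    v <- vals[[f]]
    names(v) <- paste0(f, "_", names(v))
    v
  }))
  attr(out, "family") <- rep(names(vals), times = vapply(vals, length, 0L))
  out
}
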