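# Brute-force oracles: literal-formula implementations over voxel lists and
# explicit pair/zone enumeration, kept deliberately loop-based and separate
# from the package's vectorized code paths.

# Lattice points within physical radius r of the origin.
oracle_ball_count <- function(radius, spacing = c(1, 1, 1)) {
  nmax <- ceiling(radius / spacing)
  cnt <- 0L
  for (x in -nmax[1]:nmax[1]) for (y in -nmax[2]:nmax[2])
    for (z in -nmax[3]:nmax[3]) {
      if ((x * spacing[1])^2 + (y * spacing[2])^2 + (z * spacing[3])^2 <=
          radius^2) cnt <- cnt + 1L
    }
  cnt
}

# O(N*M) dilation by direct distance checks between all voxel pairs.
oracle_dilate <- function(mask, spacing, radius) {
  d <- dim(mask)
  src <- which(mask)
  src_ijk <- arrayInd(src, d)
  out <- array(FALSE, d)
  for (v in seq_len(prod(d))) {
    ijk <- arrayInd(v, d)
    for (s in seq_len(nrow(src_ijk))) {
      dd <- sum(((ijk - src_ijk[s, ]) * spacing)^2)
      if (dd <= radius^2 + 1e-9) { out[v] <- TRUE; break }
    }
  }
  out
}

# All-pairs concordance AUC with ties counted 1/2.
oracle_auc <- function(scores, labels) {
  y <- as.integer(factor(labels)) - 1L
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

oracle_discretize <- function(v, bw) floor((v - min(v)) / bw) + 1

# --- first order, literal formulas over the voxel list ------------------
oracle_firstorder <- function(arr, mask, bw = 25, spacing = c(1, 1, 1)) {
  v <- arr[mask]
  n <- length(v)
  m <- sum(v) / n
  va <- sum((v - m)^2) / n
  lev <- oracle_discretize(v, bw)
  p <- as.vector(table(lev)) / n
  q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  inner <- v[v >= q[1] & v <= q[5]]
  c(energy = sum(v^2),
    total_energy = sum(v^2) * prod(spacing),
    entropy = -sum(p * log2(p)),
    minimum = min(v), p10 = q[1], p90 = q[5], maximum = max(v),
    mean = m, median = q[3], iqr = q[4] - q[2], range = max(v) - min(v),
    mad = sum(abs(v - m)) / n,
    rmad = sum(abs(inner - mean(inner))) / length(inner),
    rms = sqrt(sum(v^2) / n),
    skewness = if (va > 0) (sum((v - m)^3) / n) / sqrt(va)^3 else 0,
    kurtosis = if (va > 0) (sum((v - m)^4) / n) / va^2 else 0,
    variance = va,
    uniformity = sum(p^2))
}

# --- GLCM ---------------------------------------------------------------
oracle_glcm_matrix <- function(lev, mask, off, ng) {
  d <- dim(mask)
  P <- matrix(0, ng, ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    tx <- x + off[1]; ty <- y + off[2]; tz <- z + off[3]
    if (tx < 1 || tx > d[1] || ty < 1 || ty > d[2] || tz < 1 || tz > d[3])
      next
    if (!mask[tx, ty, tz]) next
    i <- lev[x, y, z]; j <- lev[tx, ty, tz]
    P[i, j] <- P[i, j] + 1
    P[j, i] <- P[j, i] + 1
  }
  P
}

oracle_glcm_features <- function(P) {
  p <- P / sum(P)
  ng <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx <- 0; sy <- 0
  for (i in 1:ng) { sx <- sx + (i - mux)^2 * px[i]
                    sy <- sy + (i - muy)^2 * py[i] }
  sx <- sqrt(sx); sy <- sqrt(sy)
  pxmy <- numeric(ng); pxpy <- numeric(2 * ng)
  for (i in 1:ng) for (j in 1:ng) {
    pxmy[abs(i - j) + 1] <- pxmy[abs(i - j) + 1] + p[i, j]
    pxpy[i + j] <- pxpy[i + j] + p[i, j]
  }
  acc <- 0; cp <- 0; cs <- 0; ct <- 0; con <- 0; corr0 <- 0
  je <- 0; jent <- 0; idm <- 0; idmn <- 0; idv <- 0; idn <- 0
  inv <- 0; ss <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    acc <- acc + i * j * pij
    cp <- cp + (i + j - mux - muy)^4 * pij
    cs <- cs + (i + j - mux - muy)^3 * pij
    ct <- ct + (i + j - mux - muy)^2 * pij
    con <- con + (i - j)^2 * pij
    corr0 <- corr0 + i * j * pij
    je <- je + pij^2
    if (pij > 0) jent <- jent - pij * log2(pij)
    idm <- idm + pij / (1 + (i - j)^2)
    idmn <- idmn + pij / (1 + ((i - j) / ng)^2)
    idv <- idv + pij / (1 + abs(i - j))
    idn <- idn + pij / (1 + abs(i - j) / ng)
    if (i != j) inv <- inv + pij / (i - j)^2
    ss <- ss + (i - mux)^2 * pij
  }
  corr <- if (sx > 0 && sy > 0) (corr0 - mux * muy) / (sx * sy) else 1
  da <- 0
  for (k in 0:(ng - 1)) da <- da + k * pxmy[k + 1]
  dent <- 0; dvar <- 0
  for (k in 0:(ng - 1)) {
    if (pxmy[k + 1] > 0) dent <- dent - pxmy[k + 1] * log2(pxmy[k + 1])
    dvar <- dvar + (k - da)^2 * pxmy[k + 1]
  }
  sa <- 0; sent <- 0
  for (k in 2:(2 * ng)) {
    sa <- sa + k * pxpy[k]
    if (pxpy[k] > 0) sent <- sent - pxpy[k] * log2(pxpy[k])
  }
  HX <- 0; HY <- 0
  for (i in 1:ng) {
    if (px[i] > 0) HX <- HX - px[i] * log2(px[i])
    if (py[i] > 0) HY <- HY - py[i] * log2(py[i])
  }
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    e <- px[i] * py[j]
    if (p[i, j] > 0 && e > 0) HXY1 <- HXY1 - p[i, j] * log2(e)
    if (e > 0) HXY2 <- HXY2 - e * log2(e)
  }
  imc1 <- if (max(HX, HY) > 0) (jent - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - jent))))
  lv <- which(px > 0)
  mcc <- 1
  if (length(lv) > 1) {
    Q <- matrix(0, length(lv), length(lv))
    for (a in seq_along(lv)) for (b in seq_along(lv)) {
      s <- 0
      for (k in seq_along(lv))
        s <- s + p[lv[a], lv[k]] * p[lv[b], lv[k]] /
          (px[lv[a]] * py[lv[k]])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(0, ev[2]))
  }
  c(autocorrelation = acc, joint_average = mux, cluster_prominence = cp,
    cluster_shade = cs, cluster_tendency = ct, contrast = con,
    correlation = corr, difference_average = da, difference_entropy = dent,
    difference_variance = dvar, joint_energy = je, joint_entropy = jent,
    imc1 = imc1, imc2 = imc2, idm = idm, idmn = idmn, id = idv, idn = idn,
    inverse_variance = inv, maximum_probability = max(p), sum_average = sa,
    sum_entropy = sent, sum_squares = ss, mcc = mcc)
}

oracle_glcm <- function(arr, mask, bw = 25) {
  lev <- array(NA_integer_, dim(arr))
  lev[mask] <- oracle_discretize(arr[mask], bw)
  ng <- max(lev, na.rm = TRUE)
  dirs <- habitomics:::.directions13
  per <- NULL
  for (r in seq_len(nrow(dirs))) {
    P <- oracle_glcm_matrix(lev, mask, dirs[r, ], ng)
    if (sum(P) == 0) next
    per <- rbind(per, oracle_glcm_features(P))
  }
  colMeans(per)
}

# --- GLRLM --------------------------------------------------------------
oracle_glrlm_matrix <- function(lev, mask, off, ng) {
  d <- dim(mask)
  maxlen <- max(d)
  P <- matrix(0, ng, maxlen)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    # run start: predecessor absent or different level
    px_ <- x - off[1]; py_ <- y - off[2]; pz_ <- z - off[3]
    if (px_ >= 1 && px_ <= d[1] && py_ >= 1 && py_ <= d[2] &&
        pz_ >= 1 && pz_ <= d[3] && mask[px_, py_, pz_] &&
        lev[px_, py_, pz_] == lev[x, y, z]) next
    l <- lev[x, y, z]; len <- 0L
    cx <- x; cy <- y; cz <- z
    while (cx >= 1 && cx <= d[1] && cy >= 1 && cy <= d[2] &&
           cz >= 1 && cz <= d[3] && mask[cx, cy, cz] &&
           lev[cx, cy, cz] == l) {
      len <- len + 1L
      cx <- cx + off[1]; cy <- cy + off[2]; cz <- cz + off[3]
    }
    P[l, len] <- P[l, len] + 1
  }
  P
}

oracle_size_features <- function(P, np, names_out) {
  nr <- sum(P)
  ng <- nrow(P); nl <- ncol(P)
  sre <- 0; lre <- 0; lgl <- 0; hgl <- 0
  srl <- 0; srh <- 0; lrl <- 0; lrh <- 0
  glv <- 0; rv <- 0; re <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:nl) {
    mu_i <- mu_i + i * P[i, j] / nr
    mu_j <- mu_j + j * P[i, j] / nr
  }
  for (i in 1:ng) for (j in 1:nl) {
    c0 <- P[i, j]
    sre <- sre + c0 / j^2
    lre <- lre + c0 * j^2
    lgl <- lgl + c0 / i^2
    hgl <- hgl + c0 * i^2
    srl <- srl + c0 / (i^2 * j^2)
    srh <- srh + c0 * i^2 / j^2
    lrl <- lrl + c0 * j^2 / i^2
    lrh <- lrh + c0 * i^2 * j^2
    glv <- glv + (i - mu_i)^2 * c0 / nr
    rv <- rv + (j - mu_j)^2 * c0 / nr
    if (c0 > 0) re <- re - c0 / nr * log2(c0 / nr)
  }
  gln <- 0
  for (i in 1:ng) gln <- gln + sum(P[i, ])^2
  rln <- 0
  for (j in 1:nl) rln <- rln + sum(P[, j])^2
  out <- c(sre / nr, lre / nr, gln / nr, gln / nr^2, rln / nr, rln / nr^2,
           nr / np, glv, rv, re, lgl / nr, hgl / nr, srl / nr, srh / nr,
           lrl / nr, lrh / nr)
  names(out) <- names_out
  out
}

oracle_glrlm <- function(arr, mask, bw = 25) {
  lev <- array(NA_integer_, dim(arr))
  lev[mask] <- oracle_discretize(arr[mask], bw)
  ng <- max(lev, na.rm = TRUE)
  dirs <- habitomics:::.directions13
  per <- NULL
  for (r in seq_len(nrow(dirs))) {
    P <- oracle_glrlm_matrix(lev, mask, dirs[r, ], ng)
    per <- rbind(per, oracle_size_features(P, sum(mask),
                                           habitomics:::.glrlm_feature_names))
  }
  colMeans(per)
}

# --- GLSZM --------------------------------------------------------------
oracle_glszm <- function(arr, mask, bw = 25) {
  d <- dim(mask)
  lev <- array(NA_integer_, dim(arr))
  lev[mask] <- oracle_discretize(arr[mask], bw)
  ng <- max(lev, na.rm = TRUE)
  seen <- array(FALSE, d)
  zones <- list()
  for (v in which(mask)) {
    if (seen[v]) next
    l <- lev[v]
    stack <- v; seen[v] <- TRUE; size <- 0L
    while (length(stack)) {
      cur <- stack[1]; stack <- stack[-1]
      size <- size + 1L
      cc <- arrayInd(cur, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        tx <- cc[1] + dx; ty <- cc[2] + dy; tz <- cc[3] + dz
        if (tx < 1 || tx > d[1] || ty < 1 || ty > d[2] ||
            tz < 1 || tz > d[3]) next
        if (!mask[tx, ty, tz] || seen[tx, ty, tz]) next
        if (lev[tx, ty, tz] != l) next
        seen[tx, ty, tz] <- TRUE
        stack <- c(stack, (tz - 1) * d[1] * d[2] + (ty - 1) * d[1] + tx)
      }
    }
    zones[[length(zones) + 1L]] <- c(l, size)
  }
  zm <- do.call(rbind, zones)
  P <- matrix(0, ng, max(zm[, 2]))
  for (r in seq_len(nrow(zm))) P[zm[r, 1], zm[r, 2]] <- P[zm[r, 1], zm[r, 2]] + 1
  oracle_size_features(P, sum(mask), habitomics:::.glszm_feature_names)
}

# --- GLDM ---------------------------------------------------------------
oracle_gldm <- function(arr, mask, bw = 25, alpha = 0) {
  d <- dim(mask)
  lev <- array(NA_integer_, dim(arr))
  lev[mask] <- oracle_discretize(arr[mask], bw)
  ng <- max(lev, na.rm = TRUE)
  deps <- NULL
  for (v in which(mask)) {
    cc <- arrayInd(v, d)
    dep <- 0L
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      tx <- cc[1] + dx; ty <- cc[2] + dy; tz <- cc[3] + dz
      if (tx < 1 || tx > d[1] || ty < 1 || ty > d[2] ||
          tz < 1 || tz > d[3]) next
      if (!mask[tx, ty, tz]) next
      if (abs(lev[tx, ty, tz] - lev[v]) <= alpha) dep <- dep + 1L
    }
    deps <- rbind(deps, c(lev[v], dep + 1L))
  }
  P <- matrix(0, ng, max(deps[, 2]))
  for (r in seq_len(nrow(deps))) P[deps[r, 1], deps[r, 2]] <-
      P[deps[r, 1], deps[r, 2]] + 1
  nz <- sum(P)
  ngr <- nrow(P); nd <- ncol(P)
  mu_i <- 0; mu_j <- 0
  for (i in 1:ngr) for (j in 1:nd) {
    mu_i <- mu_i + i * P[i, j] / nz
    mu_j <- mu_j + j * P[i, j] / nz
  }
  sde <- 0; lde <- 0; glv <- 0; dv <- 0; de <- 0
  lgl <- 0; hgl <- 0; sdl <- 0; sdh <- 0; ldl <- 0; ldh <- 0
  for (i in 1:ngr) for (j in 1:nd) {
    c0 <- P[i, j]
    sde <- sde + c0 / j^2
    lde <- lde + c0 * j^2
    glv <- glv + (i - mu_i)^2 * c0 / nz
    dv <- dv + (j - mu_j)^2 * c0 / nz
    if (c0 > 0) de <- de - c0 / nz * log2(c0 / nz)
    lgl <- lgl + c0 / i^2
    hgl <- hgl + c0 * i^2
    sdl <- sdl + c0 / (i^2 * j^2)
    sdh <- sdh + c0 * i^2 / j^2
    ldl <- ldl + c0 * j^2 / i^2
    ldh <- ldh + c0 * i^2 * j^2
  }
  gln <- 0
  for (i in 1:ngr) gln <- gln + sum(P[i, ])^2
  dn <- 0
  for (j in 1:nd) dn <- dn + sum(P[, j])^2
  out <- c(sde / nz, lde / nz, gln / nz, dn / nz, dn / nz^2, glv, dv, de,
           lgl / nz, hgl / nz, sdl / nz, sdh / nz, ldl / nz, ldh / nz)
  names(out) <- habitomics:::.gldm_feature_names
  out
}

# --- NGTDM --------------------------------------------------------------
oracle_ngtdm <- function(arr, mask, bw = 25) {
  d <- dim(mask)
  lev <- array(NA_integer_, dim(arr))
  lev[mask] <- oracle_discretize(arr[mask], bw)
  ng <- max(lev, na.rm = TRUE)
  s <- numeric(ng); cnt <- numeric(ng)
  nvp <- 0L
  for (v in which(mask)) {
    cc <- arrayInd(v, d)
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      tx <- cc[1] + dx; ty <- cc[2] + dy; tz <- cc[3] + dz
      if (tx < 1 || tx > d[1] || ty < 1 || ty > d[2] ||
          tz < 1 || tz > d[3]) next
      if (mask[tx, ty, tz]) nb <- c(nb, lev[tx, ty, tz])
    }
    if (length(nb) == 0) next
    nvp <- nvp + 1L
    i <- lev[v]
    s[i] <- s[i] + abs(i - mean(nb))
    cnt[i] <- cnt[i] + 1
  }
  p <- cnt / nvp
  pres <- which(p > 0)
  ngp <- length(pres)
  ps <- sum(p * s)
  coarse <- if (ps > 0) 1 / ps else habitomics:::.ngtdm_coarseness_cap
  if (ngp > 1) {
    contr <- 0; busy_d <- 0; compl <- 0; stren <- 0
    for (a in pres) for (b in pres) {
      contr <- contr + p[a] * p[b] * (a - b)^2
      busy_d <- busy_d + abs(a * p[a] - b * p[b])
      compl <- compl + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) /
        (p[a] + p[b])
      stren <- stren + (p[a] + p[b]) * (a - b)^2
    }
    contr <- contr / (ngp * (ngp - 1)) * sum(s) / nvp
    busy <- if (busy_d > 0) ps / busy_d else 0
    compl <- compl / nvp
    stren <- if (sum(s) > 0) stren / sum(s) else 0
  } else { contr <- 0; busy <- 0; compl <- 0; stren <- 0 }
  out <- c(coarse, contr, busy, compl, stren)
  names(out) <- habitomics:::.ngtdm_feature_names
  out
}

# Exhaustive mRMR step: evaluate the MID criterion for every candidate.
oracle_mrmr_step <- function(table, labels, selected) {
  feats <- setdiff(names(table), c("sample_id", selected))
  y <- factor(labels)
  bins <- lapply(names(table)[names(table) != "sample_id"],
                 function(f) habitomics:::tertile_bin(table[[f]]))
  names(bins) <- names(table)[names(table) != "sample_id"]
  crit <- vapply(feats, function(f) {
    rel <- habitomics:::discrete_mi(bins[[f]], y)
    red <- if (length(selected) == 0) 0 else
      mean(vapply(selected, function(s)
        habitomics:::discrete_mi(bins[[f]], bins[[s]]), 0))
    rel - red
  }, 0)
  feats[order(-crit, feats)][1]
}

# Paired-bootstrap p for the AUC difference of two models.
oracle_bootstrap_delong <- function(sa, sb, labels, B = 2000, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  y <- factor(labels)
  d0 <- oracle_auc(sa, y) - oracle_auc(sb, y)
  ds <- numeric(B)
  b <- 0L
  while (b < B) {
    i <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[i])) < 2L) next
    b <- b + 1L
    ds[b] <- oracle_auc(sa[i], y[i]) - oracle_auc(sb[i], y[i])
  }
  se <- stats::sd(ds)
  z <- d0 / se
  2 * stats::pnorm(-abs(z))
}
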