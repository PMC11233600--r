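# Feature-name columns of a wide table (everything except sample_id).
feature_columns <- function(table) setdiff(names(table), "sample_id")

as_feature_matrix <- function(table) {
  as.matrix(table[, feature_columns(table), drop = FALSE])
}

#' Intraclass correlation ICC(2,1) between two measurements
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the classical mean squares: with n subjects and k = 2 measurements,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#'
#' @param a,b Numeric vectors of the same length (the two measurements).
#' @return The ICC (scalar; `NA` when both measurements are constant).
#' @export
icc21 <- function(a, b) {
  x <- cbind(a, b)
  n <- nrow(x); k <- 2
  if (stats::var(as.vector(x)) == 0) return(NA_real_)
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  MSR <- k * sum((rm_ - gm)^2) / (n - 1)
  MSC <- n * sum((cm - gm)^2) / (k - 1)
  SSE <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  den <- MSR + (k - 1) * MSE + k / n * (MSC - MSE)
  if (den == 0) return(NA_real_)
  (MSR - MSE) / den
}

#' Robustness filter on segmentation test-retest agreement
#'
#' Retains features whose ICC(2,1) across the two feature tables (e.g.
#' original vs perturbed segmentation) meets the threshold. Features with
#' undefined ICC (zero variance in both tables) are dropped and reported.
#'
#' @param table_a,table_b Wide feature tables sharing `sample_id` and
#'   feature columns.
#' @param threshold Minimum ICC, default 0.85.
#' @return List with `survivors` (character), `icc` (named numeric),
#'   `dropped_undefined` (character).
#' @export
icc_filter <- function(table_a, table_b, threshold = 0.85) {
  feats <- intersect(feature_columns(table_a), feature_columns(table_b))
  if (!identical(table_a$sample_id, table_b$sample_id))
    table_b <- table_b[match(table_a$sample_id, table_b$sample_id), ,
                       drop = FALSE]
  icc <- vapply(feats, function(f) icc21(table_a[[f]], table_b[[f]]), 0)
  undef <- feats[is.na(icc)]
  list(survivors = feats[!is.na(icc) & icc >= threshold],
       icc = icc, dropped_undefined = undef, threshold = threshold)
}

#' Z-score standardization plus Welch t-test filter
#'
#' Standardizes every feature on the supplied (training) samples and keeps
#' features whose two-sample Welch t-test between classes has p < alpha.
#' Zero-variance features get p = 1 by convention (no signal). The
#' standardization parameters are returned for reuse on held-out samples.
#'
#' @param table Wide feature table (training samples).
#' @param labels Factor or vector with two classes, aligned with rows.
#' @param alpha Significance level, default 0.05.
#' @return List with `survivors`, `p` (named), `table_z` (standardized
#'   table), `center`, `scale`.
#' @export
standardize_and_ttest <- function(table, labels, alpha = 0.05) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stopf("labels must have exactly two classes")
  if (min(table(labels)) < 3L) stopf("need at least 3 samples per class")
  feats <- feature_columns(table)
  x <- as_feature_matrix(table)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  z <- sweep(x, 2, ctr, "-")
  nz <- scl > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, scl[nz], "/")
  g1 <- labels == levels(labels)[1]
  p <- vapply(seq_along(feats), function(j) {
    v <- x[, j]
    if (stats::sd(v[g1]) == 0 && stats::sd(v[!g1]) == 0) return(1)
    tryCatch(stats::t.test(v[g1], v[!g1])$p.value, error = function(e) 1)
  }, 0)
  names(p) <- feats
  tz <- table
  tz[, feats] <- z
  list(survivors = feats[p < alpha], p = p, table_z = tz,
       center = ctr, scale = scl, alpha = alpha)
}

#' Apply stored standardization parameters to new samples
#'
#' @param table Wide feature table.
#' @param center,scale Named vectors from [standardize_and_ttest()].
#' @return Standardized table.
#' @export
apply_standardization <- function(table, center, scale) {
  feats <- intersect(feature_columns(table), names(center))
  for (f in feats) {
    s <- if (scale[[f]] > 0) scale[[f]] else 1
    table[[f]] <- (table[[f]] - center[[f]]) / s
  }
  table
}

#' Greedy de-correlation filter on Pearson correlation
#'
#' Repeatedly finds the feature pair with the largest |r| above the
#' threshold and deletes the member with the larger mean |r| to all
#' remaining features; ties are broken by feature-name order. Terminates
#' when no pair exceeds the threshold, so the surviving set has maximum
#' pairwise |r| <= threshold.
#'
#' @param table Wide feature table.
#' @param r_threshold Correlation threshold, default 0.9.
#' @return List with `survivors` and `max_abs_r` (the final maximum
#'   pairwise |r|, `NA` if fewer than two survivors).
#' @export
pearson_greedy_filter <- function(table, r_threshold = 0.9) {
  feats <- feature_columns(table)
  x <- as_feature_matrix(table)
  if (length(feats) < 2L)
    return(list(survivors = feats, max_abs_r = NA_real_))
  r <- abs(suppressWarnings(stats::cor(x)))
  r[is.na(r)] <- 0
  diag(r) <- 0
  keep <- feats
  while (length(keep) > 1L && max(r) > r_threshold) {
    mx <- max(r)
    cand <- which(r == mx, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # tie-break: pair with the alphabetically earliest member names
    ord <- order(keep[cand[, 1]], keep[cand[, 2]])
    pair <- cand[ord[1], ]
    meanr <- rowMeans(r[pair, , drop = FALSE])
    drop_j <- if (meanr[1] > meanr[2]) pair[1]
              else if (meanr[2] > meanr[1]) pair[2]
              else pair[order(keep[pair])[2]]   # drop the later name on ties
    r <- r[-drop_j, -drop_j, drop = FALSE]
    keep <- keep[-drop_j]
  }
  list(survivors = keep,
       max_abs_r = if (length(keep) > 1L) max(r) else NA_real_)
}

# Equal-frequency tertile discretization (fewer categories if ties
# collapse the quantile breaks).
tertile_bin <- function(v) {
  br <- unique(stats::quantile(v, c(0, 1 / 3, 2 / 3, 1), names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(v)))
  as.integer(cut(v, br, include.lowest = TRUE))
}

# Mutual information (nats) between two discrete vectors.
discrete_mi <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / e[pos]))
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection with the difference (MID) criterion: at each
#' step pick the feature maximizing `MI(feature; label)` minus the mean
#' `MI(feature; already-selected)`. Mutual information is estimated on
#' equal-frequency tertile-discretized features. Deterministic: score ties
#' are broken by feature-name order.
#'
#' @param table Wide feature table.
#' @param labels Two-class labels aligned with rows.
#' @param k Number of features to select (<= feature count).
#' @return List with `selected` (ordered character vector) and `scores`
#'   (criterion value at each pick).
#' @export
mrmr_select <- function(table, labels, k) {
  feats <- feature_columns(table)
  if (k > length(feats)) stopf("k = %d exceeds feature count %d",
                               k, length(feats))
  y <- factor(labels)
  xb <- lapply(feats, function(f) tertile_bin(table[[f]]))
  names(xb) <- feats
  rel <- vapply(feats, function(f) discrete_mi(xb[[f]], y), 0)
  selected <- character(0)
  scores <- numeric(0)
  mi_cache <- matrix(NA_real_, length(feats), length(feats),
                     dimnames = list(feats, feats))
  for (step in seq_len(k)) {
    rest <- setdiff(feats, selected)
    crit <- vapply(rest, function(f) {
      red <- if (length(selected) == 0) 0 else {
        vals <- vapply(selected, function(s) {
          if (is.na(mi_cache[f, s])) {
            v <- discrete_mi(xb[[f]], xb[[s]])
            mi_cache[f, s] <<- v; mi_cache[s, f] <<- v
          }
          mi_cache[f, s]
        }, 0)
        mean(vals)
      }
      rel[[f]] - red
    }, 0)
    best <- rest[order(-crit, rest)][1]
    selected <- c(selected, best)
    scores <- c(scores, crit[[best]])
  }
  list(selected = selected, scores = scores, relevance = rel)
}

#' Lasso (L1-penalized logistic) feature selection
#'
#' Fits an L1-penalized logistic regression over a cross-validated lambda
#' path and returns the features with nonzero coefficients, with their
#' coefficient proportions (|coef| / sum |coef|).
#'
#' @param table Standardized wide feature table.
#' @param labels Two-class labels aligned with rows.
#' @param cv_folds Number of CV folds (default 5, stratified).
#' @param lambda `"1se"` (default) or `"min"`.
#' @param seed Seed for the fold assignment.
#' @return List with `survivors`, `coefficients` (named, nonzero),
#'   `proportions`, `lambda`, and the `cv_fit`.
#' @export
lasso_select <- function(table, labels, cv_folds = 5L,
                         lambda = c("1se", "min"), seed = 1L) {
  lambda <- match.arg(lambda)
  y <- factor(labels)
  x <- as_feature_matrix(table)
  if (ncol(x) == 1L) {
    # nothing to shrink against: keep the single feature with its
    # unpenalized logistic coefficient
    fit <- suppressWarnings(stats::glm(y ~ x[, 1], family = stats::binomial()))
    co <- stats::coef(fit)[2]
    names(co) <- colnames(x)
    return(list(survivors = colnames(x), coefficients = co,
                proportions = stats::setNames(1, colnames(x)),
                lambda = NA_real_, cv_fit = NULL))
  }
  foldid <- with_seed(seed, stratified_folds(y, cv_folds))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                          type.measure = "deviance")
  lam <- if (lambda == "1se") cv$lambda.1se else cv$lambda.min
  co <- as.matrix(stats::coef(cv, s = lam))[-1, 1]
  nz <- co[co != 0]
  props <- if (length(nz)) abs(nz) / sum(abs(nz)) else numeric(0)
  list(survivors = names(nz), coefficients = nz, proportions = props,
       lambda = lam, cv_fit = cv)
}

# Stratified fold ids: each class split as evenly as possible.
stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (lv in levels(factor(y))) {
    i <- which(y == lv)
    foldid[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  foldid
}

#' Run the five-stage feature-selection cascade
#'
#' Fixed order: ICC robustness filter, z-score standardization + Welch
#' t-test, greedy Pearson de-correlation, mRMR, Lasso. Survivors are
#' strictly nested across stages. All statistics are computed on the
#' supplied (training) samples only; the returned standardization
#' parameters allow leak-free application to held-out samples.
#'
#' @param table Wide feature table (training samples).
#' @param labels Two-class labels aligned with rows.
#' @param table_retest Optional second feature table (test-retest /
#'   perturbed segmentation) for the ICC stage; if `NULL` the ICC stage is
#'   skipped (all features pass, reported as such).
#' @param icc_threshold,alpha,r_threshold,mrmr_k,cv_folds,lambda,seed Stage
#'   parameters.
#' @return An object of class `selection_report`: per-stage survivors and
#'   counts, per-feature statistics, standardization parameters and final
#'   Lasso coefficients.
#' @export
run_selection_cascade <- function(table, labels, table_retest = NULL,
                                  icc_threshold = 0.85, alpha = 0.05,
                                  r_threshold = 0.9, mrmr_k = 30L,
                                  cv_folds = 5L, lambda = "1se", seed = 1L) {
  stages <- list()
  feats0 <- feature_columns(table)
  if (!is.null(table_retest)) {
    st1 <- icc_filter(table, table_retest, icc_threshold)
    icc <- st1$icc
    surv <- st1$survivors
  } else {
    icc <- NULL
    surv <- feats0
  }
  stages$icc <- surv
  tab <- table[, c("sample_id", surv), drop = FALSE]
  st2 <- standardize_and_ttest(tab, labels, alpha)
  stages$ttest <- st2$survivors
  tabz <- st2$table_z[, c("sample_id", st2$survivors), drop = FALSE]
  if (length(st2$survivors) == 0L)
    stopf("no features survive the t-test filter")
  st3 <- pearson_greedy_filter(tabz, r_threshold)
  stages$pearson <- st3$survivors
  tab3 <- tabz[, c("sample_id", st3$survivors), drop = FALSE]
  k <- min(mrmr_k, length(st3$survivors))
  st4 <- mrmr_select(tab3, labels, k)
  stages$mrmr <- st4$selected
  tab4 <- tab3[, c("sample_id", st4$selected), drop = FALSE]
  st5 <- lasso_select(tab4, labels, cv_folds, lambda, seed = seed)
  stages$lasso <- st5$survivors
  structure(list(
    stages = stages,
    counts = vapply(stages, length, 0L),
    n_input = length(feats0),
    icc = icc, t_p = st2$p,
    center = st2$center, scale = st2$scale,
    mrmr_scores = st4$scores,
    lasso_coefficients = st5$coefficients,
    lasso_proportions = st5$proportions,
    lambda = st5$lambda,
    params = list(icc_threshold = icc_threshold, alpha = alpha,
                  r_threshold = r_threshold, mrmr_k = mrmr_k,
                  cv_folds = cv_folds, lambda = lambda, seed = seed)),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> stages:\n")
  cat(sprintf("  input   : %d features\n", x$n_input))
  for (s in names(x$stages))
    cat(sprintf("  %-8s: %d survivors\n", s, length(x$stages[[s]])))
  invisible(x)
}

#' Serialize a selection report to JSON
#'
#' @param report A `selection_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_selection_report <- function(report, path) {
  out <- list(counts = as.list(report$counts), stages = report$stages,
              lambda = report$lambda,
              lasso_coefficients = as.list(report$lasso_coefficients),
              params = report$params)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
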