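var0 <- function(x) if (length(x) < 2L) 0 else stats::var(x)

# Mid-rank placements used by the DeLong structural components.
delong_components <- function(scores, labels) {
  y <- factor(labels)
  pos <- scores[y == levels(y)[2]]
  neg <- scores[y == levels(y)[1]]
  m <- length(pos); n <- length(neg)
  # V10[i] = P(neg < pos_i) + 0.5 P(neg == pos_i), and symmetrically V01
  v10 <- vapply(pos, function(s) (sum(neg < s) + 0.5 * sum(neg == s)) / n, 0)
  v01 <- vapply(neg, function(s) (sum(pos > s) + 0.5 * sum(pos == s)) / m, 0)
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC AUC with DeLong confidence interval
#'
#' AUC as the Mann-Whitney two-sample U statistic (ties counted 1/2,
#' identical to the trapezoidal ROC area), with a 95% CI from the DeLong
#' structural-component variance, clipped to [0, 1]. The second factor
#' level of `labels` is the positive class.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Two-class labels.
#' @return List with `auc`, `ci` (length 2), `se`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  y <- factor(labels)
  if (nlevels(droplevels(y)) != 2L)
    stopf("roc_auc requires both classes present")
  dc <- delong_components(scores, y)
  v <- var0(dc$v10) / dc$m + var0(dc$v01) / dc$n
  se <- sqrt(v)
  ci <- pmin(1, pmax(0, dc$auc + c(-1.96, 1.96) * se))
  list(auc = dc$auc, ci = ci, se = se, n_pos = dc$m, n_neg = dc$n)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two models scored on the same samples using the
#' DeLong structural-component covariance; returns the z statistic and the
#' two-sided p-value.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Two-class labels (shared).
#' @return List with `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stopf("scores must be paired (equal length)")
  a <- delong_components(scores_a, labels)
  b <- delong_components(scores_b, labels)
  d10 <- a$v10 - b$v10
  d01 <- a$v01 - b$v01
  v <- var0(d10) / a$m + var0(d01) / a$n
  dauc <- a$auc - b$auc
  if (v <= 0) {
    if (abs(dauc) < 1e-12) return(list(auc_a = a$auc, auc_b = b$auc,
                                       z = 0, p = 1))
    stopf("zero variance of the paired AUC difference with unequal AUCs")
  }
  z <- dauc / sqrt(v)
  list(auc_a = a$auc, auc_b = b$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping: samples are binned by predicted probability
#' into `g` equal-frequency groups; the statistic is
#' `sum((O - E)^2 / (E (1 - E / n_g)))` with `df = g' - 2` where `g'` is
#' the number of groups actually used. Groups with a degenerate variance
#' term (mean probability 0 or 1) are merged with their neighbour and the
#' df adjusted.
#'
#' @param probs Predicted probabilities in (0, 1).
#' @param labels Two-class labels (second level = event).
#' @param g Number of groups (default 10).
#' @return List with `statistic`, `df`, `p`, and the per-group table
#'   `groups` (n, observed, expected, mean probability).
#' @export
hosmer_lemeshow <- function(probs, labels, g = 10L) {
  if (any(probs <= 0 | probs >= 1)) stopf("probs must lie strictly in (0,1)")
  y <- as.integer(factor(labels)) - 1L
  n <- length(y)
  if (n < g) stopf("need at least g samples")
  br <- unique(stats::quantile(probs, seq(0, 1, length.out = g + 1)))
  grp <- cut(probs, br, include.lowest = TRUE)
  tab <- data.frame(
    n = as.vector(table(grp)),
    obs = as.vector(tapply(y, grp, sum)),
    exp = as.vector(tapply(probs, grp, sum)),
    pbar = as.vector(tapply(probs, grp, mean)))
  tab <- tab[tab$n > 0, , drop = FALSE]
  # merge groups whose variance term degenerates
  i <- 1L
  while (i <= nrow(tab)) {
    denom <- tab$exp[i] * (1 - tab$exp[i] / tab$n[i])
    if (denom <= .Machine$double.eps * tab$n[i] && nrow(tab) > 1L) {
      j <- if (i == nrow(tab)) i - 1L else i + 1L
      tab$n[j] <- tab$n[j] + tab$n[i]
      tab$obs[j] <- tab$obs[j] + tab$obs[i]
      tab$exp[j] <- tab$exp[j] + tab$exp[i]
      tab$pbar[j] <- tab$exp[j] / tab$n[j]
      tab <- tab[-i, , drop = FALSE]
    } else i <- i + 1L
  }
  stat <- sum((tab$obs - tab$exp)^2 / (tab$exp * (1 - tab$exp / tab$n)))
  df <- nrow(tab) - 2L
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_
  list(statistic = stat, df = df, p = p, groups = tab)
}

#' Decision-curve analysis net benefit
#'
#' Net benefit `NB(pt) = TP/n - FP/n * pt/(1-pt)` for each model at each
#' decision threshold, together with the treat-all policy
#' `NB = pi - (1-pi) * pt/(1-pt)` (pi = prevalence) and treat-none (0).
#'
#' @param probs_by_model Named list of probability vectors.
#' @param labels Two-class labels (second level = event).
#' @param thresholds Decision thresholds in (0, 1); default 0.01..0.99.
#' @return Data frame with columns `threshold`, `model`, `net_benefit`;
#'   models include `treat_all` and `treat_none`.
#' @export
decision_curve <- function(probs_by_model, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stopf("thresholds must lie strictly in (0,1)")
  y <- as.integer(factor(labels)) - 1L
  n <- length(y)
  pi_ <- mean(y)
  rows <- list()
  for (nm in names(probs_by_model)) {
    p <- probs_by_model[[nm]]
    nb <- vapply(thresholds, function(pt) {
      pos <- p >= pt
      sum(pos & y == 1L) / n - sum(pos & y == 0L) / n * pt / (1 - pt)
    }, 0)
    rows[[nm]] <- data.frame(threshold = thresholds, model = nm,
                             net_benefit = nb)
  }
  rows$treat_all <- data.frame(
    threshold = thresholds, model = "treat_all",
    net_benefit = pi_ - (1 - pi_) * thresholds / (1 - thresholds))
  rows$treat_none <- data.frame(threshold = thresholds, model = "treat_none",
                                net_benefit = 0)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cosine-decay learning-rate schedule
#'
#' `eta = eta_min + (eta_max - eta_min)/2 * (1 + cos(pi * T_cur / T_i))`.
#' In `"backbone"` mode the rate is 0 while `T_cur <= T_i / 2` (frozen
#' pretrained backbone) and follows the cosine curve afterwards.
#'
#' @param t_cur Current epoch, `0 <= t_cur <= t_i`.
#' @param t_i Total iteration epochs (> 0).
#' @param eta_min,eta_max Learning-rate bounds, `0 <= eta_min <= eta_max`.
#' @param mode `"task_specific"` (default) or `"backbone"`.
#' @return The learning rate (vectorized over `t_cur`).
#' @export
cosine_lr <- function(t_cur, t_i, eta_min = 0, eta_max = 0.01,
                      mode = c("task_specific", "backbone")) {
  mode <- match.arg(mode)
  if (t_i <= 0) stopf("t_i must be positive")
  if (eta_min < 0 || eta_max < eta_min)
    stopf("require 0 <= eta_min <= eta_max")
  if (any(t_cur < 0 | t_cur > t_i)) stopf("t_cur must lie in [0, t_i]")
  eta <- eta_min + 0.5 * (eta_max - eta_min) * (1 + cos(t_cur / t_i * pi))
  if (mode == "backbone") eta[t_cur <= t_i / 2] <- 0
  eta
}

#' Youden-optimal operating threshold
#'
#' The score threshold maximizing sensitivity + specificity - 1 on the
#' supplied (training) data; ties resolved toward the smallest threshold.
#'
#' @param scores Numeric scores.
#' @param labels Two-class labels.
#' @return Scalar threshold.
#' @export
youden_threshold <- function(scores, labels) {
  y <- as.integer(factor(labels)) - 1L
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    mean(scores[y == 1L] >= t) + mean(scores[y == 0L] < t) - 1
  }, 0)
  cand[which.max(j)]
}

#' Classification metrics at a threshold
#'
#' @param scores Numeric scores.
#' @param labels Two-class labels (second level = positive).
#' @param threshold Operating threshold (score >= threshold is positive).
#' @return Named vector: accuracy, sensitivity, specificity, ppv, npv.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as.integer(factor(labels)) - 1L
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  fp <- sum(pred & !y); fn <- sum(!pred & y)
  c(accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn) tn / (tn + fn) else NA_real_)
}

#' Full evaluation report for a set of models
#'
#' Per-model AUC with DeLong CI and threshold metrics (threshold frozen
#' from training via Youden if not supplied), the pairwise DeLong z/p
#' matrices, Hosmer-Lemeshow calibration (for probability-scaled scores),
#' calibration bins, and the decision-curve table.
#'
#' @param scores_by_model Named list of score vectors on one partition.
#' @param labels Two-class labels for that partition.
#' @param thresholds Named numeric vector of operating thresholds; by
#'   default Youden-optimal on the supplied data (use training-frozen
#'   values for held-out reporting).
#' @param hl_groups Hosmer-Lemeshow group count.
#' @param calibration_bins Number of calibration bins.
#' @return An object of class `evaluation_report`.
#' @export
evaluation_report <- function(scores_by_model, labels, thresholds = NULL,
                              hl_groups = 10L, calibration_bins = 10L) {
  models <- names(scores_by_model)
  y <- factor(labels)
  aucs <- lapply(scores_by_model, roc_auc, labels = y)
  if (is.null(thresholds))
    thresholds <- vapply(scores_by_model, youden_threshold, 0, labels = y)
  metrics <- t(vapply(models, function(m)
    classification_metrics(scores_by_model[[m]], y, thresholds[[m]]),
    numeric(5)))
  nm <- length(models)
  z <- matrix(0, nm, nm, dimnames = list(models, models))
  pmat <- matrix(1, nm, nm, dimnames = list(models, models))
  if (nm > 1) for (i in 1:(nm - 1)) for (j in (i + 1):nm) {
    dt <- delong_test(scores_by_model[[i]], scores_by_model[[j]], y)
    z[i, j] <- dt$z; z[j, i] <- -dt$z
    pmat[i, j] <- pmat[j, i] <- dt$p
  }
  hl <- lapply(models, function(m) {
    s <- scores_by_model[[m]]
    if (!all(s > 0 & s < 1)) return(NULL)
    tryCatch(hosmer_lemeshow(s, y, hl_groups), error = function(e) NULL)
  })
  names(hl) <- models
  calib <- lapply(models, function(m) {
    s <- scores_by_model[[m]]
    br <- unique(stats::quantile(s, seq(0, 1, length.out = calibration_bins + 1)))
    if (length(br) < 2) return(NULL)
    grp <- cut(s, br, include.lowest = TRUE)
    data.frame(bin = levels(grp),
               mean_predicted = as.vector(tapply(s, grp, mean)),
               observed = as.vector(tapply(as.integer(y) - 1L, grp, mean)),
               n = as.vector(table(grp)))
  })
  names(calib) <- models
  dca <- decision_curve(scores_by_model, y)
  structure(list(
    auc = data.frame(model = models,
                     auc = vapply(aucs, `[[`, 0, "auc"),
                     ci_low = vapply(aucs, function(a) a$ci[1], 0),
                     ci_high = vapply(aucs, function(a) a$ci[2], 0),
                     row.names = NULL),
    thresholds = thresholds, metrics = metrics,
    delong_z = z, delong_p = pmat,
    hosmer_lemeshow = hl, calibration = calib,
    decision_curve = dca, prevalence = mean(y == levels(y)[2])),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  df <- x$auc
  df$auc <- sprintf("%.3f (%.3f-%.3f)", df$auc, df$ci_low, df$ci_high)
  print(df[, c("model", "auc")], row.names = FALSE)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_evaluation_report <- function(report, path) {
  out <- list(
    auc = report$auc,
    thresholds = as.list(report$thresholds),
    metrics = as.data.frame(report$metrics),
    delong_p = report$delong_p,
    hosmer_lemeshow = lapply(report$hosmer_lemeshow, function(h)
      if (is.null(h)) NULL else h[c("statistic", "df", "p")]),
    prevalence = report$prevalence)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
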