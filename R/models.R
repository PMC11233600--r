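#' Stratified train/validation split
#'
#' @param labels Two-class labels.
#' @param prop Training proportion (default 0.7).
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `validation`.
#' @export
split_cohort <- function(labels, prop = 0.7, seed = 1L) {
  y <- factor(labels)
  with_seed(seed, {
    tr <- integer(0)
    for (lv in levels(y)) {
      i <- which(y == lv)
      tr <- c(tr, sample(i, max(1L, round(prop * length(i)))))
    }
    tr <- sort(tr)
    list(train = tr, validation = setdiff(seq_along(y), tr))
  })
}

.default_grids <- function(p) list(
  lr = data.frame(dummy = 1),
  mlp = expand.grid(size = c(3L, 5L), decay = c(0.01, 0.1)),
  rf = expand.grid(mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3)))),
                   ntree = 300L),
  svm = expand.grid(cost = c(0.5, 1, 4), gamma = c(1 / p, 2 / p)),
  xgboost = expand.grid(nrounds = 50L, max_depth = c(2L, 3L),
                        eta = c(0.1, 0.3)),
  extratrees = expand.grid(mtry = unique(pmax(1L, c(floor(sqrt(p)),
                                                    floor(p / 3)))),
                           num.trees = 300L)
)

fit_algo <- function(algorithm, params, x, y, seed) {
  with_seed(seed, switch(algorithm,
    lr = suppressWarnings(stats::glm(y ~ ., data = data.frame(x, y = y),
                                     family = stats::binomial())),
    mlp = nnet::nnet(x, stats::model.matrix(~ y - 1)[, 2, drop = FALSE],
                     size = params$size, decay = params$decay,
                     maxit = 200, trace = FALSE, entropy = TRUE),
    rf = randomForest::randomForest(x, y, mtry = params$mtry,
                                    ntree = params$ntree),
    svm = e1071::svm(x, y, cost = params$cost, gamma = params$gamma,
                     probability = TRUE, kernel = "radial"),
    xgboost = xgboost::xgboost(
      x, y, objective = "binary:logistic",
      nrounds = params$nrounds, max_depth = params$max_depth,
      learning_rate = params$eta, nthreads = 1L, verbosity = 0,
      seed = as.integer(seed %% 2147483647)),
    extratrees = ranger::ranger(x = x, y = y, probability = TRUE,
                                splitrule = "extratrees",
                                num.random.splits = 1L,
                                mtry = params$mtry,
                                num.trees = params$num.trees,
                                seed = seed,
                                num.threads = 1L),
    stopf("unknown algorithm '%s'", algorithm)))
}

predict_algo <- function(algorithm, fit, x, positive) {
  switch(algorithm,
    lr = as.numeric(stats::predict(fit, newdata = data.frame(x),
                                   type = "response")),
    mlp = as.numeric(stats::predict(fit, x)),
    rf = as.numeric(stats::predict(fit, x, type = "prob")[, positive]),
    svm = {
      pr <- stats::predict(fit, x, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, positive])
    },
    xgboost = as.numeric(stats::predict(fit, x)),
    extratrees = as.numeric(stats::predict(fit, data = x)$predictions[, positive]))
}

#' Train a per-region signature model
#'
#' Grid search with stratified k-fold cross-validation: every grid point is
#' scored by mean out-of-fold AUC, the best point (first in grid order on
#' ties) is refit on the full training set, and the fitted model emits a
#' per-sample signature score in [0, 1] (probability of the positive
#' class). Deterministic given `seed`.
#'
#' @param table Wide feature table of the selected features (training
#'   samples).
#' @param labels Two-class labels; the second factor level is the positive
#'   class.
#' @param algorithm One of `"lr"`, `"mlp"`, `"rf"`, `"svm"`, `"xgboost"`,
#'   `"extratrees"`.
#' @param grid Data frame of hyperparameter combinations; `NULL` for the
#'   built-in default grid.
#' @param seed RNG seed (folds and stochastic fits).
#' @param cv_folds Number of CV folds (default 5).
#' @param region_tag Provenance tag stored on the model.
#' @return An object of class `signature_model` with elements `fit`,
#'   `algorithm`, `best_params`, `cv_auc` (per grid point), `scores`
#'   (training scores), `features`, `region_tag`.
#' @export
train_signature <- function(table, labels, algorithm = "lr", grid = NULL,
                            seed = 1L, cv_folds = 5L, region_tag = NA) {
  y <- factor(labels)
  if (nlevels(y) != 2L) stopf("labels must have two classes")
  positive <- levels(y)[2]
  x <- as_feature_matrix(table)
  if (is.null(grid)) grid <- .default_grids(ncol(x))[[algorithm]]
  foldid <- with_seed(seed, stratified_folds(y, cv_folds))
  if (any(tapply(y, foldid, function(v) length(unique(v))) < 2L))
    stopf("degenerate fold: a CV fold contains a single class")
  cv_auc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    aucs <- vapply(seq_len(cv_folds), function(fold) {
      tr <- foldid != fold
      fit <- fit_algo(algorithm, grid[gi, , drop = FALSE],
                      x[tr, , drop = FALSE], y[tr],
                      seed = child_seed(seed, gi * 100 + fold))
      sc <- predict_algo(algorithm, fit, x[!tr, , drop = FALSE], positive)
      roc_auc(sc, y[!tr])$auc
    }, 0)
    cv_auc[gi] <- mean(aucs)
  }
  best <- which.max(cv_auc)
  fit <- fit_algo(algorithm, grid[best, , drop = FALSE], x, y,
                  seed = child_seed(seed, 999983))
  scores <- predict_algo(algorithm, fit, x, positive)
  structure(list(fit = fit, algorithm = algorithm,
                 best_params = grid[best, , drop = FALSE],
                 grid = grid, cv_auc = cv_auc,
                 scores = scores, features = colnames(x),
                 positive = positive, levels = levels(y),
                 region_tag = region_tag, seed = seed),
            class = "signature_model")
}

#' @export
predict.signature_model <- function(object, table, ...) {
  x <- as.matrix(table[, object$features, drop = FALSE])
  predict_algo(object$algorithm, object$fit, x, object$positive)
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model> ", x$algorithm,
      if (!is.na(x$region_tag)) paste0(" [", x$region_tag, "]"),
      ", ", length(x$features), " features, best CV AUC ",
      sprintf("%.3f", max(x$cv_auc)), "\n", sep = "")
  invisible(x)
}

# Integer encoding of the clinical covariates; one column per covariate so
# the report prints a single OR per characteristic.
encode_clinical <- function(records) {
  lv <- function(x, levels) as.integer(factor(x, levels = levels)) - 1L
  data.frame(
    age = as.numeric(records$age),
    gender = lv(records$gender, c("male", "female")),
    stage = lv(records$stage, c("AIS", "IA", "IB")),
    smoking = lv(records$smoking, c("no", "yes")),
    ct_pattern = lv(records$ct_pattern, c("ground-glass", "mixed", "solid")),
    histology = lv(records$histology, c("adenocarcinoma", "other", "unknown")),
    location = lv(records$location,
                  c("left upper lobe", "left lower lobe", "right upper lobe",
                    "right middle lobe", "right lower lobe")))
}

glm_or_row <- function(fit, term) {
  co <- summary(fit)$coefficients
  if (!term %in% rownames(co)) return(c(NA, NA, NA, NA))
  b <- co[term, 1]; se <- co[term, 2]; p <- co[term, 4]
  c(exp(b), exp(b - 1.96 * se), exp(b + 1.96 * se), p)
}

#' Univariable and stepwise multivariable clinical analysis
#'
#' Per-covariate univariable logistic regression (odds ratio, Wald 95% CI,
#' p), followed by p-value-driven stepwise selection (enter at p < 0.05,
#' remove at p > 0.10) and a multivariable logistic model on the retained
#' covariates. Multi-category covariates are integer-coded (one OR per
#' characteristic). Quasi-separation is flagged (`separation = TRUE`)
#' rather than crashed on.
#'
#' @param records Clinical records data frame (see [generate_cohort()]).
#' @param labels Two-class labels; second level is the event.
#' @return An object of class `clinical_analysis`: data frames
#'   `univariable` and `multivariable` (covariate, OR, CI, p), plus the
#'   fitted multivariable `fit` and `selected` covariates.
#' @export
clinical_analysis <- function(records, labels) {
  y <- factor(labels)
  if (nlevels(y) != 2L)
    stopf("clinical_analysis requires both classes present")
  if (length(y) < 20L) stopf("need n >= 20 samples")
  X <- encode_clinical(records)
  yb <- as.integer(y) - 1L
  separation <- FALSE
  uni <- t(vapply(names(X), function(v) {
    fit <- withCallingHandlers(
      stats::glm(yb ~ ., data = data.frame(X[v], yb = yb),
                 family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities", conditionMessage(w)))
          separation <<- TRUE
        invokeRestart("muffleWarning")
      })
    glm_or_row(fit, v)
  }, numeric(4)))
  univariable <- data.frame(covariate = names(X), or = uni[, 1],
                            ci_low = uni[, 2], ci_high = uni[, 3],
                            p = uni[, 4], row.names = NULL)
  # stepwise by p-value: forward at p<0.05 with backward pruning at p>0.10
  selected <- character(0)
  repeat {
    changed <- FALSE
    rest <- setdiff(names(X), selected)
    if (length(rest)) {
      pv <- vapply(rest, function(v) {
        fit <- suppressWarnings(stats::glm(
          yb ~ ., data = data.frame(X[c(selected, v)], yb = yb),
          family = stats::binomial()))
        glm_or_row(fit, v)[4]
      }, 0)
      if (any(!is.na(pv) & pv < 0.05)) {
        selected <- c(selected, rest[which.min(pv)])
        changed <- TRUE
      }
    }
    if (length(selected) > 1L) {
      fit <- suppressWarnings(stats::glm(
        yb ~ ., data = data.frame(X[selected], yb = yb),
        family = stats::binomial()))
      pv <- vapply(selected, function(v) glm_or_row(fit, v)[4], 0)
      worst <- which.max(pv)
      if (!is.na(pv[worst]) && pv[worst] > 0.10) {
        selected <- selected[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  multivariable <- NULL
  fit <- NULL
  if (length(selected)) {
    fit <- suppressWarnings(stats::glm(
      yb ~ ., data = data.frame(X[selected], yb = yb),
      family = stats::binomial()))
    mv <- t(vapply(selected, function(v) glm_or_row(fit, v), numeric(4)))
    multivariable <- data.frame(covariate = selected, or = mv[, 1],
                                ci_low = mv[, 2], ci_high = mv[, 3],
                                p = mv[, 4], row.names = NULL)
  }
  structure(list(univariable = univariable, multivariable = multivariable,
                 selected = selected, fit = fit, separation = separation,
                 encoded = X),
            class = "clinical_analysis")
}

#' @export
print.clinical_analysis <- function(x, ...) {
  cat("<clinical_analysis>\nUnivariable:\n")
  print(transform(x$univariable, or = signif(or, 4), p = signif(p, 3)))
  if (!is.null(x$multivariable)) {
    cat("Multivariable (stepwise-selected):\n")
    print(transform(x$multivariable, or = signif(or, 4), p = signif(p, 3)))
  } else cat("Multivariable: no covariate entered\n")
  invisible(x)
}

#' Build a fusion nomogram
#'
#' Logistic fusion of per-sample signature scores with clinical smoking
#' status, re-encoded on a points scale: each predictor's points are an
#' affine map of its value, scaled so the predictor with the largest
#' coefficient-times-range spans 100 points; total points map back to the
#' predicted probability exactly (round-trip identity of the linear
#' predictor). Constant predictors contribute zero points. Collinear
#' predictors are flagged and their aliased coefficients set to zero with a
#' warning.
#'
#' @param signature_scores Data frame (or named list) of per-sample scores,
#'   e.g. peritumoral, habitat and deep-learning-signature columns.
#' @param smoking Optional 0/1 (or "no"/"yes") vector; appended as a
#'   predictor named `smoking`.
#' @param labels Two-class labels (training partition).
#' @return An object of class `nomogram_model`.
#' @export
build_nomogram <- function(signature_scores, smoking = NULL, labels) {
  X <- as.data.frame(signature_scores)
  if (!is.null(smoking)) {
    if (is.character(smoking) || is.factor(smoking))
      smoking <- as.integer(factor(smoking, levels = c("no", "yes"))) - 1L
    X$smoking <- as.numeric(smoking)
  }
  y <- factor(labels)
  yb <- as.integer(y) - 1L
  fit <- suppressWarnings(stats::glm(yb ~ ., data = data.frame(X, yb = yb),
                                     family = stats::binomial()))
  beta <- stats::coef(fit)
  collinear <- anyNA(beta[-1]) &&
    any(is.na(beta[-1]) & vapply(X, function(v) stats::sd(v) > 0, TRUE))
  if (collinear)
    warnf("collinear predictors in nomogram fusion; aliased coefficients set to 0")
  beta[is.na(beta)] <- 0
  intercept <- beta[1]
  b <- beta[-1]
  rng <- vapply(X, function(v) diff(range(v)), 0)
  lo <- vapply(X, min, 0); hi <- vapply(X, max, 0)
  # reference value per predictor: the end of its observed range where
  # beta * x is smallest, so points are non-negative
  ref <- ifelse(b >= 0, lo, hi)
  span <- abs(b) * rng
  unit <- max(span) / 100   # linear-predictor increment per point
  structure(list(coefficients = b, intercept = intercept, ref = ref,
                 unit = unit, ranges = rng, fit = fit,
                 predictors = names(X), levels = levels(y),
                 collinear = collinear),
            class = "nomogram_model")
}

#' Points assigned by a nomogram
#'
#' @param model A `nomogram_model`.
#' @param newdata Data frame with the predictor columns.
#' @return Matrix of per-predictor points plus a `total` column.
#' @export
nomogram_points <- function(model, newdata) {
  X <- as.data.frame(newdata)[, model$predictors, drop = FALSE]
  pts <- sapply(model$predictors, function(v) {
    if (model$unit == 0) return(rep(0, nrow(X)))
    model$coefficients[[v]] * (X[[v]] - model$ref[[v]]) / model$unit
  })
  pts <- matrix(pts, nrow = nrow(X),
                dimnames = list(NULL, model$predictors))
  cbind(pts, total = rowSums(pts))
}

#' @export
predict.nomogram_model <- function(object, newdata, type = c("prob", "link"),
                                   ...) {
  type <- match.arg(type)
  X <- as.data.frame(newdata)[, object$predictors, drop = FALSE]
  lp0 <- object$intercept +
    sum(object$coefficients * object$ref)
  total <- nomogram_points(object, X)[, "total"]
  lp <- lp0 + object$unit * total
  if (object$unit == 0)
    lp <- object$intercept +
      as.matrix(X) %*% object$coefficients
  lp <- as.numeric(lp)
  if (type == "link") lp else stats::plogis(lp)
}

#' @export
print.nomogram_model <- function(x, ...) {
  cat("<nomogram_model> predictors:",
      paste(x$predictors, collapse = ", "), "\n")
  cat("coefficients:",
      paste(sprintf("%s=%.3f", x$predictors, x$coefficients),
            collapse = ", "), "\n")
  invisible(x)
}
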