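sig_table <- function(x) data.frame(sample_id = sprintf("S%03d", seq_len(nrow(x))),
                                    x, check.names = FALSE)

test_that("signature training is deterministic and separates separable data", {
  set.seed(1)
  n <- 80
  lab <- factor(rep(c("wild-type", "mutant"), each = n / 2),
                levels = c("wild-type", "mutant"))
  x <- matrix(rnorm(n * 3), n); colnames(x) <- c("a", "b", "c")
  x[, 1] <- ifelse(lab == "mutant", 2, -2) + rnorm(n, sd = 0.1)
  tab <- sig_table(x)
  m1 <- train_signature(tab, lab, "lr", seed = 5)
  expect_equal(roc_auc(m1$scores, lab)$auc, 1)
  expect_true(all(m1$scores >= 0 & m1$scores <= 1))
  m2 <- train_signature(tab, lab, "lr", seed = 5)
  expect_identical(m1$scores, m2$scores)
  expect_identical(m1$best_params, m2$best_params)
})

test_that("permuted labels give chance-level cross-validated AUC", {
  set.seed(2)
  n <- 120
  x <- matrix(rnorm(n * 4), n); colnames(x) <- letters[1:4]
  aucs <- vapply(1:5, function(s) {
    set.seed(s)
    lab <- factor(sample(rep(c("wild-type", "mutant"), each = n / 2)),
                  levels = c("wild-type", "mutant"))
    max(train_signature(sig_table(x), lab, "lr", seed = s)$cv_auc)
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("all six algorithm families fit, score in [0,1] and predict on new data", {
  sim <- simulate_feature_table(90, d = 2, n_noise = 3, seed = 3)
  tab <- sig_table(as.matrix(sim$features))
  newx <- tab[1:10, ]
  for (alg in c("lr", "mlp", "rf", "svm", "xgboost", "extratrees")) {
    m <- train_signature(tab, sim$labels, alg, seed = 4, cv_folds = 3)
    expect_true(all(m$scores >= 0 & m$scores <= 1), info = alg)
    expect_gt(max(m$cv_auc), 0.7)
    p <- predict(m, newx)
    expect_identical(length(p), 10L)
    expect_true(all(p >= 0 & p <= 1), info = alg)
  }
})

test_that("train AUC is at least CV AUC on average (overfit direction)", {
  diffs <- vapply(1:10, function(s) {
    sim <- simulate_feature_table(80, d = 1, n_noise = 5, seed = s)
    m <- train_signature(sig_table(as.matrix(sim$features)), sim$labels,
                         "lr", seed = s)
    roc_auc(m$scores, sim$labels)$auc - max(m$cv_auc)
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("univariable logistic OR equals the 2x2 cross-product", {
  # smoking x label counts: (yes,mutant)=39 (no,mutant)=132
  #                         (yes,wild)=46  (no,wild)=51
  rec <- data.frame(
    age = 60, gender = "female", stage = "IA",
    smoking = rep(c("yes", "no", "yes", "no"), c(39, 132, 46, 51)),
    ct_pattern = "mixed", histology = "adenocarcinoma",
    location = "left upper lobe")
  lab <- factor(rep(c("mutant", "wild-type"), c(171, 97)),
                levels = c("wild-type", "mutant"))
  # age/gender constant -> some univariable fits are degenerate; smoking is
  # the covariate under test
  ca <- suppressWarnings(clinical_analysis(rec, lab))
  or_smoking <- ca$univariable$or[ca$univariable$covariate == "smoking"]
  expect_equal(or_smoking, (39 * 51) / (132 * 46), tolerance = 1e-6)
})

test_that("null covariates' OR confidence intervals cover 1 most of the time", {
  cover <- vapply(1:60, function(s) {
    set.seed(s)
    n <- 150
    lab <- factor(rep(c("mutant", "wild-type"), c(90, 60)),
                  levels = c("wild-type", "mutant"))
    rec <- data.frame(
      age = round(rnorm(n, 60, 9)),
      gender = sample(c("male", "female"), n, TRUE),
      stage = sample(c("AIS", "IA", "IB"), n, TRUE),
      smoking = sample(c("yes", "no"), n, TRUE),
      ct_pattern = sample(c("ground-glass", "mixed", "solid"), n, TRUE),
      histology = "adenocarcinoma",
      location = "left upper lobe")
    ca <- suppressWarnings(clinical_analysis(rec, lab))
    row <- ca$univariable[ca$univariable$covariate == "smoking", ]
    row$ci_low <= 1 && row$ci_high >= 1
  }, TRUE)
  expect_gte(mean(cover), 0.9)
})

test_that("degenerate clinical inputs error out", {
  rec <- data.frame(age = rep(60, 30), gender = "male", stage = "IA",
                    smoking = "no", ct_pattern = "solid",
                    histology = "other", location = "left lower lobe")
  expect_error(clinical_analysis(rec, rep("mutant", 30)), "both classes")
  expect_error(clinical_analysis(rec[1:10, ],
                                 rep(c("mutant", "wild-type"), 5)), "n >= 20")
})

test_that("stepwise multivariable analysis retains a strong covariate", {
  set.seed(9)
  n <- 400
  smoking <- rbinom(n, 1, 0.35)
  p <- plogis(1 - 1.5 * smoking)
  lab <- factor(ifelse(rbinom(n, 1, p) == 1, "mutant", "wild-type"),
                levels = c("wild-type", "mutant"))
  rec <- data.frame(
    age = round(rnorm(n, 60, 9)),
    gender = sample(c("male", "female"), n, TRUE),
    stage = sample(c("AIS", "IA", "IB"), n, TRUE),
    smoking = ifelse(smoking == 1, "yes", "no"),
    ct_pattern = sample(c("ground-glass", "mixed", "solid"), n, TRUE),
    histology = sample(c("adenocarcinoma", "other"), n, TRUE),
    location = sample(c("left upper lobe", "right lower lobe"), n, TRUE))
  ca <- clinical_analysis(rec, lab)
  expect_true("smoking" %in% ca$selected)
  expect_true(all(ca$multivariable$ci_low <= ca$multivariable$or &
                    ca$multivariable$or <= ca$multivariable$ci_high))
})

test_that("nomogram probabilities round-trip the logistic model exactly", {
  set.seed(10)
  n <- 200
  scores <- data.frame(p3 = runif(n), habitat = runif(n))
  smoking <- rbinom(n, 1, 0.3)
  lp <- -1 + 2.5 * scores$habitat + 1.2 * scores$p3 + 0.8 * smoking
  lab <- factor(ifelse(rbinom(n, 1, plogis(lp)) == 1, "mutant", "wild-type"),
                levels = c("wild-type", "mutant"))
  nm <- build_nomogram(scores, smoking = smoking, labels = lab)
  X <- cbind(scores, smoking = smoking)
  direct <- as.numeric(predict(nm$fit, newdata = X, type = "response"))
  via_points <- predict(nm, X)
  expect_lt(max(abs(direct - via_points)), 1e-9)
  pts <- nomogram_points(nm, X)
  expect_true(all(pts[, nm$predictors] >= -1e-9))
  expect_lte(max(apply(pts[, nm$predictors, drop = FALSE], 2, max)), 100 + 1e-6)
})

test_that("planted fusion weights are recovered within their CIs", {
  set.seed(11)
  n <- 400
  s1 <- runif(n); s2 <- runif(n)
  beta <- c(-1, 2, 3)
  lab <- factor(ifelse(rbinom(n, 1, plogis(beta[1] + beta[2] * s1 +
                                             beta[3] * s2)) == 1,
                       "mutant", "wild-type"),
                levels = c("wild-type", "mutant"))
  nm <- build_nomogram(data.frame(s1 = s1, s2 = s2), labels = lab)
  est <- coef(nm$fit)[-1]
  se <- sqrt(diag(vcov(nm$fit)))[-1]
  expect_true(all(abs(est - beta[2:3]) < 2.5 * se))
})

test_that("constant predictors leave nomogram probabilities unchanged", {
  set.seed(12)
  n <- 120
  s1 <- runif(n)
  lab <- factor(ifelse(rbinom(n, 1, plogis(2 * s1 - 1)) == 1,
                       "mutant", "wild-type"),
                levels = c("wild-type", "mutant"))
  nm1 <- build_nomogram(data.frame(s1 = s1), labels = lab)
  nm2 <- build_nomogram(data.frame(s1 = s1, flat = rep(0.7, n)), labels = lab)
  p1 <- predict(nm1, data.frame(s1 = s1))
  p2 <- predict(nm2, data.frame(s1 = s1, flat = rep(0.7, n)))
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("stratified splits keep class balance and are reproducible", {
  lab <- factor(rep(c("wild-type", "mutant"), c(40, 60)))
  sp <- split_cohort(lab, prop = 0.7, seed = 3)
  expect_identical(sp, split_cohort(lab, prop = 0.7, seed = 3))
  expect_identical(length(sp$train), 70L)
  expect_identical(sum(lab[sp$train] == "mutant"), 42L)
})
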