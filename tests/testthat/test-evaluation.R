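test_that("AUC matches hand counts, symmetry and the all-pairs oracle", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  for (s in 1:20) {
    set.seed(s)
    n <- sample(10:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- round(rnorm(n), 1)   # ties likely
    a <- roc_auc(sc, y)$auc
    expect_equal(a, oracle_auc(sc, y), tolerance = 1e-12)
    expect_equal(roc_auc(sc, 1 - y)$auc, 1 - a, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC and DeLong CI agree with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(30)
  y <- rbinom(80, 1, 0.5); y[1:2] <- 0:1
  sc <- rnorm(80) + y
  ours <- roc_auc(sc, y)
  ref <- pROC::roc(y, sc, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$ci, ci[c(1, 3)], tolerance = 1e-4)
})

test_that("paired DeLong test matches pROC and a bootstrap oracle", {
  set.seed(31)
  n <- 120
  y <- rbinom(n, 1, 0.5); y[1:2] <- 0:1
  sa <- rnorm(n) + 0.9 * y
  sb <- rnorm(n) + 0.4 * y
  dt <- delong_test(sa, sb, y)
  expect_equal(delong_test(sa, sa, y)$p, 1)
  expect_equal(delong_test(sa, sa, y)$z, 0)
  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE, direction = "<"),
                        pROC::roc(y, sb, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(dt$p, ref$p.value, tolerance = 1e-9)
  pb <- oracle_bootstrap_delong(sa, sb, y, B = 2000, seed = 2)
  expect_lt(abs(dt$p - pb), 0.02)
})

test_that("a zero-variance paired difference with unequal AUCs is rejected", {
  # one positive and one negative sample: no variance, opposite AUCs
  expect_error(delong_test(c(0, 1), c(1, 0), c(0, 1)), "zero variance")
})

test_that("DeLong detects an informative model against noise", {
  hits <- vapply(1:60, function(s) {
    set.seed(s)
    n <- 200
    y <- rbinom(n, 1, 0.5); y[1:2] <- 0:1
    good <- rnorm(n) + 1.2 * y
    noise <- rnorm(n)
    delong_test(good, noise, y)$p < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.8)
})

test_that("DeLong CI covers the true AUC at the nominal rate", {
  d <- 1
  true_auc <- pnorm(d / sqrt(2))
  cover <- vapply(1:200, function(s) {
    set.seed(s)
    n <- 150
    y <- rbinom(n, 1, 0.5); y[1:2] <- 0:1
    sc <- rnorm(n) + d * y
    ci <- roc_auc(sc, y)$ci
    ci[1] <= true_auc && true_auc <= ci[2]
  }, TRUE)
  expect_lt(abs(mean(cover) - 0.95), 0.04)
})

test_that("Hosmer-Lemeshow is exact on perfectly calibrated bins", {
  probs <- rep(seq(0.05, 0.5, by = 0.05), each = 20)
  labels <- as.vector(vapply(seq(0.05, 0.5, by = 0.05), function(p)
    rep(c(1, 0), c(p * 20, 20 - p * 20)), numeric(20)))
  hl <- hosmer_lemeshow(probs, labels, g = 10)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_identical(hl$df, 8L)
  expect_error(hosmer_lemeshow(c(0, 0.5), c(0, 1)), "strictly")
})

test_that("Hosmer-Lemeshow has near-nominal size and real power", {
  # calibration null: probabilities from a correctly specified fitted
  # logistic model (the g - 2 degrees of freedom assume fitted parameters)
  rej_null <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rnorm(1000)
    y <- rbinom(1000, 1, plogis(-0.3 + 0.8 * x))
    p <- fitted(glm(y ~ x, family = binomial()))
    hosmer_lemeshow(p, y)$p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej_null) - 0.05), 0.06)
  rej_alt <- vapply(1:30, function(s) {
    set.seed(s)
    p <- runif(2000, 0.05, 0.95)
    y <- rbinom(2000, 1, p)
    hosmer_lemeshow(p^2, y)$p < 0.05
  }, TRUE)
  expect_gt(mean(rej_alt), 0.8)
})

test_that("decision-curve net benefit matches its closed forms", {
  y <- rep(c(1, 0), each = 50)   # prevalence 0.5
  dc <- decision_curve(list(perfect = y), y, thresholds = c(0.25, 0.5, 0.75))
  ta <- dc[dc$model == "treat_all" & dc$threshold == 0.25, "net_benefit"]
  expect_equal(ta, 0.5 - 0.5 * (0.25 / 0.75))  # = 1/3
  expect_true(all(dc[dc$model == "perfect", "net_benefit"] == 0.5))
  expect_true(all(dc[dc$model == "treat_none", "net_benefit"] == 0))
  # any model's net benefit never exceeds prevalence
  for (s in 1:20) {
    set.seed(s)
    n <- 80
    y2 <- rbinom(n, 1, runif(1, 0.2, 0.8)); y2[1:2] <- 0:1
    p2 <- runif(n)
    dc2 <- decision_curve(list(m = p2), y2)
    expect_true(all(dc2$net_benefit <= mean(y2) + 1e-12))
  }
})

test_that("cosine learning-rate schedule matches the printed formula", {
  expect_equal(cosine_lr(0, 100), 0.01)
  expect_equal(cosine_lr(100, 100), 0)
  expect_equal(cosine_lr(50, 100), 0.005)
  expect_equal(cosine_lr(25, 100, mode = "backbone"), 0)
  expect_equal(cosine_lr(75, 100, mode = "backbone"),
               0.005 * (1 + cos(0.75 * pi)))
  # monotone non-increasing over [0, T_i]
  lr <- cosine_lr(0:100, 100)
  expect_true(all(diff(lr) <= 1e-15))
  lrb <- cosine_lr(0:100, 100, mode = "backbone")
  expect_true(all(diff(lrb) <= 1e-15) || all(lrb[0:50 + 1] == 0))
  expect_error(cosine_lr(1, 0), "positive")
  expect_error(cosine_lr(5, 4), "t_cur")
})

test_that("classification metrics and Youden threshold are consistent", {
  sc <- c(0.1, 0.2, 0.6, 0.7, 0.8, 0.9)
  y <- c(0, 0, 0, 1, 1, 1)
  thr <- youden_threshold(sc, y)
  m <- classification_metrics(sc, y, thr)
  expect_equal(unname(m["sensitivity"]), 1)
  expect_equal(unname(m["specificity"]), 1)
  expect_equal(unname(m["accuracy"]), 1)
})

test_that("evaluation_report assembles consistent components", {
  set.seed(40)
  n <- 150
  y <- factor(ifelse(rbinom(n, 1, 0.6) == 1, "mutant", "wild-type"),
              levels = c("wild-type", "mutant"))
  sig <- plogis(rnorm(n) + 1.5 * (y == "mutant"))
  noise <- plogis(rnorm(n))
  rep_ <- evaluation_report(list(sig = sig, noise = noise), y)
  expect_identical(nrow(rep_$auc), 2L)
  expect_true(all(rep_$auc$ci_low <= rep_$auc$auc &
                    rep_$auc$auc <= rep_$auc$ci_high))
  expect_equal(rep_$delong_z["sig", "noise"], -rep_$delong_z["noise", "sig"])
  expect_equal(diag(rep_$delong_z), c(sig = 0, noise = 0))
  expect_equal(rep_$delong_p["sig", "noise"], rep_$delong_p["noise", "sig"])
  expect_true(all(rep_$decision_curve$net_benefit <=
                    rep_$prevalence + 1e-12))
  p <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(rep_, p)
  expect_true(jsonlite::validate(paste(readLines(p), collapse = "")))
})
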