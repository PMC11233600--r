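make_table <- function(x) data.frame(sample_id = sprintf("S%03d", seq_len(nrow(x))),
                                     x, check.names = FALSE)

test_that("ICC(2,1) behaves at its anchors", {
  set.seed(1)
  a <- rnorm(500)
  expect_equal(icc21(a, a), 1)
  # variance components 9:1 -> ICC about 0.9
  s <- rnorm(500, sd = 3)
  b1 <- s + rnorm(500, sd = 1)
  b2 <- s + rnorm(500, sd = 1)
  expect_lt(abs(icc21(b1, b2) - 0.9), 0.04)
  # permuted pairing destroys agreement
  expect_lt(abs(icc21(b1, sample(b2))), 0.15)
  expect_true(is.na(icc21(rep(1, 10), rep(1, 10))))
})

test_that("icc_filter retains robust features and drops undefined ones", {
  set.seed(2)
  n <- 300
  s <- rnorm(n, sd = 3)
  x <- data.frame(good = s + rnorm(n, 0.3), noisy = rnorm(n),
                  flat = rep(1, n))
  y <- data.frame(good = s + rnorm(n, 0.3), noisy = rnorm(n),
                  flat = rep(1, n))
  res <- icc_filter(make_table(x), make_table(y))
  expect_true("good" %in% res$survivors)
  expect_false("noisy" %in% res$survivors)
  expect_identical(res$dropped_undefined, "flat")
})

test_that("t-test filter has nominal type-I error and near-certain power", {
  set.seed(3)
  n <- 200
  lab <- rep(c("a", "b"), each = n / 2)
  nullx <- matrix(rnorm(n * 1000), n)
  colnames(nullx) <- sprintf("f%04d", 1:1000)
  res <- standardize_and_ttest(make_table(nullx), lab)
  expect_lt(abs(length(res$survivors) / 1000 - 0.05), 0.03)
  # strong shift is always retained
  x <- data.frame(sig = rnorm(n) + 2 * (lab == "b"))
  res2 <- standardize_and_ttest(make_table(x), lab)
  expect_identical(res2$survivors, "sig")
  # z-scored columns
  z <- as.matrix(res2$table_z[, "sig", drop = FALSE])
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # zero-variance convention
  x2 <- data.frame(flat = rep(1, n))
  expect_equal(unname(standardize_and_ttest(make_table(x2), lab)$p["flat"]), 1)
})

test_that("greedy Pearson filter de-correlates with name-order ties", {
  set.seed(4)
  n <- 500
  a <- rnorm(n)
  x <- data.frame(a1 = a, a2 = a, ind1 = rnorm(n), ind2 = rnorm(n))
  res <- pearson_greedy_filter(make_table(x), 0.9)
  expect_identical(sum(c("a1", "a2") %in% res$survivors), 1L)
  expect_true(all(c("ind1", "ind2") %in% res$survivors))
  # independent features all survive
  ind <- matrix(rnorm(n * 8), n); colnames(ind) <- letters[1:8]
  expect_identical(pearson_greedy_filter(make_table(ind))$survivors,
                   letters[1:8])
  # post-condition on random correlated tables
  for (s in 1:10) {
    set.seed(s)
    base <- matrix(rnorm(100 * 3), 100)
    xx <- base[, sample(3, 12, replace = TRUE)] + 0.3 * matrix(rnorm(1200), 100)
    colnames(xx) <- sprintf("v%02d", 1:12)
    out <- pearson_greedy_filter(make_table(xx), 0.8)
    if (length(out$survivors) > 1)
      expect_lte(out$max_abs_r, 0.8)
  }
})

test_that("mRMR selects by relevance first and penalizes redundancy", {
  set.seed(5)
  n <- 200
  lab <- rep(c(0, 1), each = n / 2)
  strong <- lab + rnorm(n, sd = 0.1)
  weak <- lab + rnorm(n, sd = 0.9)
  x <- data.frame(strong = strong, strong_dup = strong, weak = weak,
                  n1 = rnorm(n), n2 = rnorm(n))
  res <- mrmr_select(make_table(x), lab, k = 3)
  expect_identical(res$selected[1], "strong")
  # the duplicate is deferred behind the independent informative feature
  expect_lt(match("weak", res$selected),
            match("strong_dup", c(res$selected, "strong_dup")))
  expect_error(mrmr_select(make_table(x), lab, k = 10), "exceeds")
})

test_that("each greedy mRMR step equals the exhaustive criterion argmax", {
  for (s in 1:5) {
    set.seed(s)
    n <- 150
    lab <- rbinom(n, 1, 0.5)
    x <- matrix(rnorm(n * 7), n)
    x[, 1] <- x[, 1] + lab
    x[, 2] <- x[, 1] + rnorm(n, sd = 0.3)
    colnames(x) <- sprintf("f%d", 1:7)
    tab <- make_table(x)
    res <- mrmr_select(tab, lab, k = 4)
    sel <- character(0)
    for (step in 1:4) {
      expect_identical(res$selected[step], oracle_mrmr_step(tab, lab, sel))
      sel <- c(sel, res$selected[step])
    }
  }
})

test_that("Lasso keeps the informative feature and zeroes most noise", {
  hits <- 0; zeroed <- numeric(0)
  for (s in 1:3) {
    sim <- simulate_feature_table(300, d = 1.5, n_noise = 30, seed = s)
    res <- lasso_select(make_table(scale(as.matrix(sim$features))),
                        sim$labels, seed = s)
    hits <- hits + ("signal" %in% res$survivors)
    zeroed <- c(zeroed, 1 - sum(grepl("^noise", res$survivors)) / 30)
    if (length(res$survivors))
      expect_equal(sum(res$proportions), 1)
  }
  expect_equal(hits, 3)
  expect_true(mean(zeroed) >= 0.9)
})

test_that("Lasso on pure noise returns an empty set without crashing", {
  set.seed(6)
  x <- matrix(rnorm(120 * 10), 120)
  colnames(x) <- sprintf("n%02d", 1:10)
  lab <- rbinom(120, 1, 0.5)
  res <- lasso_select(make_table(x), lab, seed = 1)
  expect_true(length(res$survivors) <= 2)  # typically empty at lambda.1se
})

test_that("the cascade yields nested survivor sets and a faithful report", {
  set.seed(7)
  sim <- simulate_feature_table(200, d = 1.5, n_noise = 25, seed = 7)
  tab <- make_table(as.matrix(sim$features))
  retest <- tab
  for (f in feature_cols <- setdiff(names(tab), "sample_id"))
    retest[[f]] <- retest[[f]] + rnorm(200, sd = 0.05)
  rep_ <- run_selection_cascade(tab, sim$labels, table_retest = retest,
                                mrmr_k = 10, seed = 1)
  st <- rep_$stages
  expect_true(all(st$ttest %in% st$icc))
  expect_true(all(st$pearson %in% st$ttest))
  expect_true(all(st$mrmr %in% st$pearson))
  expect_true(all(st$lasso %in% st$mrmr))
  expect_true(all(diff(rep_$counts) <= 0))
  expect_true("signal" %in% st$lasso)
  p <- withr::local_tempfile(fileext = ".json")
  write_selection_report(rep_, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_identical(back$counts$lasso, length(st$lasso))
})

test_that("selection statistics depend on training samples only", {
  sim <- simulate_feature_table(150, d = 1, n_noise = 10, seed = 8)
  tab <- make_table(as.matrix(sim$features))
  train <- 1:100
  r1 <- run_selection_cascade(tab[train, ], sim$labels[train], seed = 2)
  # perturb the held-out rows arbitrarily; the report must be identical
  tab2 <- tab
  tab2[101:150, -1] <- tab2[101:150, -1] * 10 + 5
  r2 <- run_selection_cascade(tab2[train, ], sim$labels[train], seed = 2)
  expect_identical(r1$stages, r2$stages)
  expect_identical(r1$lasso_coefficients, r2$lasso_coefficients)
})
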