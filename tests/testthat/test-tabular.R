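test_that("Mann-Whitney U matches brute-force pair counting and enumeration", {
  brute_u <- function(x1, x0) {
    u <- 0
    for (a in x1) for (b in x0) u <- u + (a > b) + 0.5 * (a == b)
    u
  }
  set.seed(20)
  for (i in 1:25) {
    n1 <- sample(2:8, 1); n0 <- sample(2:8, 1)
    x1 <- sample(1:6, n1, replace = TRUE)  # ties guaranteed possible
    x0 <- sample(1:6, n0, replace = TRUE)
    out <- compare_groups(data.frame(f = c(x0, x1) + 0.5),  # non-binary
                          c(rep(0, n0), rep(1, n1)))
    expect_equal(out$statistic, brute_u(x1 + 0.5, x0 + 0.5))
  }
  ## tie-corrected normal p matches the closed-form z on a worked case
  x0 <- c(1, 2, 3, 4); x1 <- c(3, 5, 6, 7)
  out <- compare_groups(data.frame(f = c(x0, x1) + 0.1), rep(0:1, each = 4))
  u <- brute_u(x1 + 0.1, x0 + 0.1)
  r <- rank(c(x0, x1))
  ties <- table(c(x0, x1))
  sig <- sqrt(4 * 4 / 12 * (9 - sum(ties^3 - ties) / (8 * 7)))
  z <- (u - 8) / sig
  expect_equal(out$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-10)
})

test_that("identical groups yield p near 1; constants are flagged", {
  d <- data.frame(a = rnorm(20), b = runif(20), const = rep(1.5, 20))
  dd <- rbind(d, d)
  y <- rep(0:1, each = 20)
  out <- compare_groups(dd, y)
  expect_true(all(out$p_value[out$feature %in% c("a", "b")] > 0.99))
  expect_true(out$degenerate[out$feature == "const"])
})

test_that("chi-square on the degenerate 2x2 toy table is 20 without correction", {
  x <- c(rep(1, 10), rep(0, 10))
  y <- c(rep(1, 10), rep(0, 10))
  out <- compare_groups(data.frame(risk = x), y)
  expect_identical(out$test, "chi_square")
  expect_equal(out$statistic, 20)
  expect_equal(out$summary0, 0)
  expect_equal(out$summary1, 10)
})

test_that("a planted marker is flagged significant with high power", {
  sp <- cohort_spec(n_patients = 10, clinical_effects = c(fibrinogen_like = 0.8))
  hits <- 0
  for (s in 1:12) {
    set.seed(s)
    y <- rep(0:1, each = 100)
    tab <- t(vapply(y, function(cl) synth_clinical(cl, sp),
                    numeric(sp$n_clinical)))
    out <- compare_groups(as.data.frame(tab), y)
    hits <- hits + (out$p_value[out$feature == "fibrinogen_like"] < 0.01)
  }
  expect_gte(hits / 12, 0.9)
})

test_that("random-forest screening selects k features, planted ones first", {
  set.seed(77)
  n <- 120
  x <- as.data.frame(matrix(rnorm(n * 30), n,
                            dimnames = list(NULL, sprintf("f%02d", 1:30))))
  y <- rep(0:1, each = n / 2)
  x$f07 <- x$f07 + 1.2 * y
  firsts <- vapply(1:15, function(s) {
    sel <- select_top_features(x, y, k = 15, ntree = 300, seed = s)
    expect_length(sel$selected, 15)
    expect_equal(sum(sel$ranking$importance), 1, tolerance = 1e-9)
    expect_true(all(sel$ranking$importance >= 0))
    sel$ranking$feature[1]
  }, character(1))
  expect_gte(mean(firsts == "f07"), 0.95)
  expect_error(select_top_features(x, y, k = 31), "exceeds")
})

test_that("a duplicated informative column splits its importance", {
  set.seed(5)
  n <- 150
  x <- as.data.frame(matrix(rnorm(n * 10), n,
                            dimnames = list(NULL, sprintf("f%02d", 1:10))))
  y <- rep(0:1, each = n / 2)
  x$f03 <- x$f03 + 1.5 * y
  base <- select_top_features(x, y, k = 3, seed = 1)
  imp_single <- base$ranking$importance[base$ranking$feature == "f03"]
  x2 <- x
  x2$f03_copy <- x$f03
  dup <- select_top_features(x2, y, k = 3, seed = 1)
  imp_pair <- sum(dup$ranking$importance[dup$ranking$feature %in%
                                           c("f03", "f03_copy")])
  expect_lt(abs(imp_pair - imp_single) / imp_single, 0.5)
})

test_that("screening is label-permutation sensitive", {
  sp <- cohort_spec(n_patients = 10)
  set.seed(55)
  y <- rep(0:1, each = 60)
  tab <- as.data.frame(t(vapply(y, function(cl) synth_clinical(cl, sp),
                                numeric(sp$n_clinical))))
  planted <- names(sp$clinical_effects)
  freq <- vapply(1:20, function(s) {
    set.seed(s * 13)
    ys <- sample(y)
    sel <- select_top_features(tab, ys, k = 15, ntree = 200, seed = s)
    mean(planted %in% sel$selected)
  }, numeric(1))
  ## under shuffled labels planted markers are not preferred: ~ k/50
  expect_lt(abs(mean(freq) - 15 / 50), 0.15)
})

test_that("baselines produce the five-model report and a null result on noise", {
  set.seed(91)
  n <- 300
  feats <- as.data.frame(matrix(rnorm(n * 12), n,
                                dimnames = list(NULL, sprintf("v%02d", 1:12))))
  y <- sample(rep(0:1, n / 2))   # labels independent of features
  splits <- sample(rep(c("train", "internal", "external"), c(200, 50, 50)))
  out <- run_baselines(feats, y, splits, seed = 3)
  expect_setequal(unique(out$model),
                  c("logistic_regression", "random_forest", "svm", "knn",
                    "xgboost"))
  expect_equal(nrow(out), 10)  # 5 models x 2 evaluation splits
  expect_true(all(out$auc > 0.3 & out$auc < 0.7))
  ## determinism for the seeded learners
  out2 <- run_baselines(feats, y, splits, seed = 3)
  det <- c("logistic_regression", "random_forest", "xgboost")
  expect_identical(out$auc[out$model %in% det], out2$auc[out2$model %in% det])
})

test_that("the baseline feature table concatenates the three blocks", {
  g <- test_cohort("small")
  bt <- baseline_feature_table(g$manifest, image_size = c(16, 16),
                               clinical_k = 10, seed = 1)
  expect_equal(nrow(bt$features), 24)
  expect_length(bt$selected_clinical, 10)
  ## 15 pulse + 2x(2 and 4 masks) x 18 colour summaries + 10 clinical
  expect_equal(ncol(bt$features), 15 + (2 + 4) * 18 + 10)
  expect_false(anyNA(bt$features))
})
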