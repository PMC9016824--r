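test_that("stratified folds balance both groups and are seeded", {
  y <- rep(c(1, 0), each = 50)
  f <- stratified_folds(y, 10, seed = 3)
  tab <- table(f, y)
  expect_true(all(tab == 5))                 # every fold: 5 AD + 5 HC
  expect_identical(f, stratified_folds(y, 10, seed = 3))
  expect_error(stratified_folds(y, 60), "smallest group")
  y2 <- c(rep(1, 7), rep(0, 10))
  f2 <- stratified_folds(y2, 3, seed = 1)
  # per fold, each group's count is within 1 of perfect stratification
  expect_true(all(abs(table(f2, y2) - rep(c(10, 7) / 3, each = 3)) <= 1))
})

test_that("ridge logistic matches glm on well-conditioned data", {
  set.seed(200)
  x <- rnorm(300)
  y <- rbinom(300, 1, plogis(0.5 + 1.2 * x))
  ours <- fit_logistic(x, y)
  ref <- glm(y ~ x, family = binomial)
  expect_equal(unname(ours$coefficients), unname(coef(ref)), tolerance = 1e-4)
  expect_true(ours$converged)
})

test_that("ridge keeps separated fits finite with perfect training accuracy", {
  x <- c(1:10, 21:30)
  y <- rep(c(0, 1), each = 10)
  f <- fit_logistic(x, y)
  expect_true(all(is.finite(f$coefficients)))
  expect_equal(mean((predict(f, x) >= 0.5) == (y == 1)), 1)
})

test_that("null predictors give a null fit", {
  # balanced labels, constant predictor: intercept ~ 0, probability ~ 0.5
  f <- fit_logistic(rep(2, 40), rep(c(0, 1), 20))
  expect_equal(unname(f$coefficients[1]), 0, tolerance = 1e-6)
  expect_equal(unname(predict(f, 2)), 0.5, tolerance = 1e-6)
  # permuted labels: slope statistically indistinguishable from zero
  set.seed(210)
  x <- rnorm(400)
  y <- sample(rep(c(0, 1), 200))
  f2 <- fit_logistic(x, y)
  se <- sqrt(diag(summary(glm(y ~ x, family = binomial))$cov.scaled))[2]
  expect_lt(abs(f2$coefficients[2]), 3 * se)
})

test_that("AUC equals the exhaustive pairwise oracle, ties included", {
  set.seed(220)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 2, 0.25), n, replace = TRUE)   # forces ties
    expect_equal(roc_analysis(s, y)$auc, auc_pairs(s, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on a random instance", {
  set.seed(230)
  y <- rbinom(80, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(80) + y
  expect_equal(roc_analysis(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("ROC worked example, symmetry and perfect separation", {
  expect_equal(roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  r <- roc_analysis(c(1, 2, 3, 11, 12, 13), rep(c(0, 1), each = 3))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$accuracy, 1)
  set.seed(240)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  expect_equal(roc_analysis(-s, y)$auc, 1 - roc_analysis(s, y)$auc,
               tolerance = 1e-12)
})

test_that("reported metrics are internally consistent and beat the majority rule", {
  set.seed(250)
  for (i in 1:20) {
    n <- 40
    y <- rep(c(0, 1), each = n / 2)      # balanced, as in the study design
    s <- rnorm(n) + 0.8 * y
    r <- roc_analysis(s, y)
    expect_equal(r$accuracy,
                 (r$sensitivity * sum(y) + r$specificity * sum(1 - y)) / n,
                 tolerance = 1e-12)
    expect_gte(r$accuracy, 0.5)
    expect_true(all(c(r$auc, r$sensitivity, r$specificity, r$accuracy) >= 0))
    expect_true(all(c(r$auc, r$sensitivity, r$specificity, r$accuracy) <= 1))
  }
})

test_that("cross-validation is separable on a perfect feature and null otherwise", {
  y <- rep(c(0, 1), each = 25)
  cv <- crossvalidate(as.numeric(y), y, k = 5, seed = 4)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$auc, 1)
  set.seed(260)
  cv0 <- crossvalidate(rnorm(100), rep(c(0, 1), 50), k = 10, seed = 4)
  expect_gt(cv0$auc, 0.35)
  expect_lt(cv0$auc, 0.65)
})

test_that("held-out metrics reuse a fixed training threshold", {
  m <- threshold_metrics(c(0.2, 0.4, 0.6, 0.9), c(0, 1, 1, 1), 0.5)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 3 / 4)
})

test_that("Cohen's d matches hand arithmetic and is antisymmetric", {
  expect_equal(cohens_d(c(4, 5, 6), c(1, 2, 3)), 3.0)
  expect_equal(cohens_d(c(1, 2, 3), c(4, 5, 6)), -3.0)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("Kruskal-Wallis wraps the rank test with a degenerate guard", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, 3.857, tolerance = 1e-3)
  expect_equal(kw$p.value,
               stats::kruskal.test(list(c(1, 2, 3), c(4, 5, 6)))$p.value)
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  ident <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p.value, 1)
})

test_that("Pearson correlation matches the oracle with t-distribution p", {
  expect_equal(pearson_corr(1:10, 1:10)$r, 1)
  expect_equal(pearson_corr(1:10, -(1:10))$r, -1)
  # hand arithmetic: cov 11, sds sqrt(5) and sqrt(26) on n-1 scale
  ex <- pearson_corr(c(1, 2, 3, 4), c(2, 4, 5, 9))
  expect_equal(ex$r, 11 / sqrt(5 * 26), tolerance = 1e-12)
  expect_equal(ex$r, 0.9648, tolerance = 1e-4)
  expect_equal(ex$p.value, cor.test(c(1, 2, 3, 4), c(2, 4, 5, 9))$p.value)
  expect_equal(pearson_corr(c(1, 2, NA, 4), c(2, 4, 5, 9))$n, 3)
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("evaluate_measure bundles CV metrics, effect size and correlations", {
  set.seed(270)
  y <- rep(c(1, 0), each = 20)
  v <- rnorm(40) + 2.5 * y
  mmse <- 29 - 6 * y + rnorm(40)
  ev <- evaluate_measure(v, y, k = 5, seed = 2, mmse = mmse)
  expect_s3_class(ev, "aqi_eval")
  expect_equal(ev$effect_size, cohens_d(v[y == 1], v[y == 0]))
  expect_equal(ev$measure_threshold, roc_analysis(v, y)$threshold)
  expect_lt(ev$cor_mmse$r, 0)
  expect_lt(ev$kruskal$p.value, 0.01)
})
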