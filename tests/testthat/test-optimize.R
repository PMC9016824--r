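# Toy cohorts for the grid-search contract: noiseless templates whose curves
# differ only at the frame with mid-time 1050 s, so only parameter sets that
# sample S(1050) can separate the groups.
toy_cohort <- function(bump = 5, n_per_group = 5) {
  sch <- pib_schedule()
  mid <- mid_times(sch)
  base <- ifelse(mid <= 150, 10 + (100 - 10) * mid / 150,
                 100 - (100 - 60) * (mid - 150) / (3450 - 150))
  ad <- base
  ad[mid == 1050] <- ad[mid == 1050] + bump
  mk <- function(v) matrix(v, 1, 26, dimnames = list("ctx", NULL))
  make_cohort(c(replicate(n_per_group, mk(ad), simplify = FALSE),
                replicate(n_per_group, mk(base), simplify = FALSE)),
              c(rep("AD", n_per_group), rep("HC", n_per_group)))
}

test_that("grid search finds the unique separating parameter set", {
  coh <- toy_cohort(bump = 5)
  grid <- grid_spec(t1 = c(450, 1050, 1350), t2 = 1650, a = 0.4)
  tn <- tune_aqi_params(coh, "ctx", grid, folds = 5, seed = 3)
  expect_equal(tn$best_params$t1, 1050)
  expect_equal(tn$best_params$t2, 1650)
  expect_equal(tn$best_params$a, 0.4)
  expect_equal(tn$best_accuracy, 1.0)
  # all other grid points see identical features in both groups
  other <- tn$surface[tn$surface$t1 != 1050, ]
  expect_true(all(other$accuracy <= 0.5 + 1e-9))
})

test_that("a no-signal cohort yields a flat surface and the min-scan-time corner", {
  coh <- toy_cohort(bump = 0)
  grid <- grid_spec(t1 = c(450, 1050), t2 = c(1050, 1650), a = c(0.2, 0.5))
  tn <- tune_aqi_params(coh, "ctx", grid, folds = 5, seed = 3)
  expect_true(all(abs(tn$surface$accuracy - 0.5) < 1e-9))
  # tie-break: minimal max(t1, t2), then minimal t1, then minimal a
  expect_equal(tn$best_params$t1, 450)
  expect_equal(tn$best_params$t2, 1050)
  expect_equal(tn$best_params$a, 0.2)
})

test_that("grid points violating t2 > t_max are excluded, not fatal", {
  coh <- toy_cohort()
  grid <- grid_spec(t1 = 450, t2 = c(100, 1650), a = 0.5)
  expect_message(tn <- tune_aqi_params(coh, "ctx", grid, folds = 5, seed = 3),
                 "invalid")
  expect_true(all(is.na(tn$surface$accuracy[tn$surface$t2 == 100])))
  expect_false(any(tn$surface$valid[tn$surface$t2 == 100]))
})

test_that("the tuner is deterministic under a fixed fold seed", {
  coh <- simulate_cohort(cohort_config(n_ad = 6, n_hc = 6, seed = 14))
  grid <- grid_spec(t1 = c(450, 1650), t2 = c(1350, 1650), a = c(0.3, 0.7))
  a <- tune_aqi_params(coh, "caudal_anterior_cingulate", grid, folds = 3, seed = 5)
  b <- tune_aqi_params(coh, "caudal_anterior_cingulate", grid, folds = 3, seed = 5)
  expect_identical(a$surface, b$surface)
  expect_identical(a$best_params, b$best_params)
})

test_that("lasso selection handles degenerate inputs", {
  x <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, paste0("r", 1:4)))
  sel <- lasso_select(x, rep(1, 10))
  expect_length(sel$regions, 0)
  expect_true(all(sel$beta_full == 0))
  x2 <- cbind(x, const = 1)
  y <- rep(c(0, 1), 5)
  expect_warning(sel2 <- lasso_select(x2, y, folds = 3, seed = 1),
                 "constant feature")
  expect_equal(sel2$dropped, "const")
})

test_that("1-SE lasso recovers exactly the informative regions", {
  set.seed(106)
  n <- 200
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("region_", 1:10)))
  y <- rep(c(1, 0), each = n / 2)
  x[, 1] <- x[, 1] + 3 * y     # strong signal
  x[, 2] <- x[, 2] + 2 * y     # weaker signal
  sel <- lasso_select(x, y, folds = 10, seed = 9)
  expect_setequal(sel$regions, c("region_1", "region_2"))
  expect_equal(sel$regions[1], "region_1")   # ordered by |beta|
  # sparsity is monotone along the returned path
  nz <- sel$cv$nzero
  lam <- sel$cv$lambda
  expect_true(all(diff(nz[order(-lam)]) >= 0))
})

test_that("the lasso path approaches OLS as the penalty vanishes", {
  set.seed(116)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("r", 1:3)))
  y <- drop(x %*% c(1, -0.5, 0.25)) + rnorm(20, 0, 0.1)
  lam <- c(exp(seq(log(2), log(1e-5), length.out = 60)), 0)
  sel <- lasso_select(x, y, lambda = lam, folds = 5, seed = 2, thresh = 1e-12)
  b0 <- drop(as.matrix(coef(sel$cv$glmnet.fit, s = 0)))[-1]
  xs <- scale(x)
  ols <- drop(solve(crossprod(cbind(1, xs)), crossprod(cbind(1, xs), y)))[-1]
  expect_equal(unname(b0), unname(ols), tolerance = 1e-4)
})

test_that("overall fit is centered OLS on z-scored features", {
  # balanced labels give an intercept of exactly the label mean
  set.seed(126)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0, 1), each = 10)
  f <- fit_overall(x, y)
  expect_equal(unname(coef(f)[1]), 0.5, tolerance = 1e-12)
  # hand normal equations on the 4-subject worked design
  x4 <- matrix(c(-1, -1, 1, 1), 4, 1, dimnames = list(NULL, "a"))
  y4 <- c(0, 0, 1, 1)
  f4 <- fit_overall(x4, y4)
  z <- scale(x4)
  beta_hand <- solve(crossprod(cbind(1, z)), crossprod(cbind(1, z), y4))
  expect_equal(unname(coef(f4)), unname(drop(beta_hand)), tolerance = 1e-12)
  expect_equal(unname(fitted(f4) >= 0.5), y4 == 1)   # perfect predictor
  expect_equal(unname(residuals(f4)), unname(y4 - fitted(f4)))
})

test_that("zero-variance features cannot be z-scored", {
  x <- cbind(a = rep(2, 8), b = rnorm(8))
  expect_error(fit_overall(x, rep(c(0, 1), 4)), "zero-variance")
})

test_that("prediction applies stored training statistics", {
  set.seed(136)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0, 1), 15)
  f <- fit_overall(x, y)
  # training features reproduce the in-sample fitted values exactly
  expect_equal(predict(f, x), unname(fitted(f)), ignore_attr = TRUE)
  # features at the training means collapse to the intercept
  at_mean <- matrix(f$center, 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(predict(f, at_mean)), unname(coef(f)[1]))
  expect_error(predict(f, matrix(0, 1, 1, dimnames = list(NULL, "a"))),
               "missing region value\\(s\\): b")
})

test_that("the published-style coefficient arithmetic is reproduced", {
  model <- structure(list(coefficients = c(`(Intercept)` = 0.5378,
                                           X1 = 3.6092, X2 = 0.2750),
                          center = c(X1 = 0, X2 = 0),
                          scale = c(X1 = 1, X2 = 1),
                          selection = NULL, regions = c("X1", "X2"),
                          params = aqi_params()),
                     class = "aqi_fit")
  z <- matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("X1", "X2")))
  expect_equal(unname(predict(model, z)), 4.1470, tolerance = 1e-12)
})

test_that("lasso-backed aqi_fit recovers the simulated signal regions", {
  coh <- simulate_cohort(cohort_config(n_ad = 25, n_hc = 25, seed = 20))
  f <- aqi_fit(coh, folds = 5, seed = 6)
  expect_setequal(f$regions, c("caudal_anterior_cingulate", "caudate"))
  expect_equal(f$selection$regions[1], "caudal_anterior_cingulate")
})
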