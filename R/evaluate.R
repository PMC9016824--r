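#' Stratified fold assignment
#'
#' Partitions subjects into `k` folds so that each group's counts differ by
#' at most one across folds (with 50 AD + 50 HC and k = 10, every fold holds
#' exactly 5 + 5).
#'
#' @param labels 0/1 (or two-level) group vector.
#' @param k number of folds, `2 <= k <=` smallest group size.
#' @param seed integer seed for the random partition (NULL: use current RNG).
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(labels, k = 10, seed = NULL) {
  labels <- as.vector(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("both groups must be present")
  if (k < 2 || k > min(tab))
    stop(sprintf("k must be between 2 and the smallest group size (%d)", min(tab)))
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (g in names(tab)) {
    idx <- sample(which(labels == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Ridge-stabilized logistic regression
#'
#' Maximizes the Bernoulli log-likelihood with a small L2 penalty on the
#' slope(s) by iteratively reweighted least squares. The ridge keeps the
#' solution finite on perfectly separated data, which otherwise sends the
#' slope to infinity.
#'
#' @param x numeric vector or matrix of predictors.
#' @param y 0/1 response; both classes must be present.
#' @param ridge L2 penalty on the slopes (not the intercept).
#' @param tol relative convergence tolerance on the coefficients.
#' @param maxit maximum IRLS iterations.
#' @return An object of class `"aqi_logit"` with `coefficients` (intercept
#'   first), `iterations` and `converged`.
#' @export
fit_logistic <- function(x, y, ridge = 1e-6, tol = 1e-8, maxit = 100L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- cbind(1, x)
  p <- ncol(X)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- drop(solve(crossprod(X, w * X) + pen, crossprod(X, w * z)))
    delta <- max(abs(new - beta) / (abs(beta) + 1))
    beta <- new
    if (delta < tol)
      return(structure(list(coefficients = beta, iterations = it,
                            converged = TRUE, ridge = ridge),
                       class = "aqi_logit"))
  }
  stop(sprintf("IRLS did not converge in %d iterations (last step %.3g)",
               maxit, delta))
}

#' @export
predict.aqi_logit <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- drop(cbind(1, as.matrix(newdata)) %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
print.aqi_logit <- function(x, ...) {
  cat("ridge-logistic fit: coefficients",
      paste(signif(x$coefficients, 5), collapse = ", "),
      sprintf("(%d IRLS iterations)\n", x$iterations))
  invisible(x)
}

#' ROC analysis with Youden-optimal threshold
#'
#' AUC is the Mann-Whitney probability that a random positive scores above a
#' random negative, with ties counted one half. The curve is swept over all
#' distinct scores (rule: positive when `score >= threshold`); the reported
#' threshold maximizes Youden's J = sensitivity + specificity - 1, ties
#' broken toward higher specificity.
#'
#' @param scores numeric scores, higher meaning more AD-like.
#' @param labels 0/1 labels (1 = AD).
#' @return An object of class `"aqi_roc"`: `auc`, `threshold`,
#'   `sensitivity`, `specificity`, `accuracy`, and the full `curve`
#'   data.frame (threshold, sensitivity, specificity).
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[labels == 0] < t), 0)
  j <- sens + spec - 1
  best <- order(-j, -spec, -thr)[1L]
  acc <- (sens[best] * n1 + spec[best] * n0) / (n1 + n0)
  structure(list(auc = auc, threshold = thr[best],
                 sensitivity = sens[best], specificity = spec[best],
                 accuracy = acc,
                 curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec)),
            class = "aqi_roc")
}

#' @export
print.aqi_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f | threshold %.4g -> sens %.3f spec %.3f acc %.3f\n",
              x$auc, x$threshold, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' @export
plot.aqi_roc <- function(x, ...) {
  graphics::plot(1 - x$curve$specificity, x$curve$sensitivity, type = "s",
                 xlab = "false positive rate", ylab = "true positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Classification metrics at a fixed threshold
#'
#' Applies a previously derived threshold (rule: `score >= threshold` is
#' called AD) to new scores, as when a held-out test set is evaluated with
#' the training-set threshold.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param threshold decision threshold on the score scale.
#' @return List with `sensitivity`, `specificity`, `accuracy`.
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  labels <- as.numeric(labels)
  pos <- labels == 1
  if (!any(pos) || all(pos)) stop("both classes must be present")
  sens <- mean(scores[pos] >= threshold)
  spec <- mean(scores[!pos] < threshold)
  list(sensitivity = sens, specificity = spec,
       accuracy = (sens * sum(pos) + spec * sum(!pos)) / length(labels))
}

#' Stratified k-fold cross-validated classification of one measure
#'
#' Trains a ridge-stabilized logistic classifier on k-1 folds, scores the
#' held-out fold, pools all out-of-fold probabilities and runs
#' [roc_analysis()] on them against the true labels. For a single-feature
#' measure the Youden threshold is additionally mapped to the measure scale
#' by running the ROC sweep on the raw measure values.
#'
#' @param x numeric vector (one measure per subject) or matrix of features.
#' @param y 0/1 labels.
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param ridge logistic stabilizer, see [fit_logistic()].
#' @return An object of class `"aqi_cv"`: the pooled `scores`, `folds`,
#'   `roc` (an `"aqi_roc"` on the pooled probabilities), plus `auc`,
#'   `accuracy`, `sensitivity`, `specificity`, `threshold` (probability
#'   scale) and `measure_threshold` (measure scale, single feature only).
#' @export
crossvalidate <- function(x, y, k = 10, seed = NULL, ridge = 1e-6) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  fold <- stratified_folds(y, k, seed)
  scores <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- fit_logistic(x[tr, , drop = FALSE], y[tr], ridge = ridge)
    scores[!tr] <- predict(fit, x[!tr, , drop = FALSE])
  }
  roc <- roc_analysis(scores, y)
  measure_threshold <- if (ncol(x) == 1L)
    roc_analysis(drop(x), y)$threshold else NA_real_
  structure(list(scores = scores, folds = fold, roc = roc,
                 auc = roc$auc, accuracy = roc$accuracy,
                 sensitivity = roc$sensitivity,
                 specificity = roc$specificity,
                 threshold = roc$threshold,
                 measure_threshold = measure_threshold),
            class = "aqi_cv")
}

#' @export
print.aqi_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV: AUC %.4f, accuracy %.3f (sens %.3f, spec %.3f)\n",
              max(x$folds), x$auc, x$accuracy, x$sensitivity, x$specificity))
  if (!is.na(x$measure_threshold))
    cat(sprintf("optimal threshold on the measure scale: %.4g\n",
                x$measure_threshold))
  invisible(x)
}

#' Cohen's d effect size (AD minus HC, pooled SD)
#'
#' @param x_ad,x_hc measure values per group (>= 2 each).
#' @return Effect size d.
#' @export
cohens_d <- function(x_ad, x_hc) {
  n1 <- length(x_ad); n2 <- length(x_hc)
  if (n1 < 2 || n2 < 2) stop("need >= 2 values per group")
  sp <- sqrt(((n1 - 1) * stats::var(x_ad) + (n2 - 1) * stats::var(x_hc)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  (mean(x_ad) - mean(x_hc)) / sp
}

#' Kruskal-Wallis test with degenerate-tie guard
#'
#' Wraps [stats::kruskal.test()] (rank H statistic with tie correction,
#' chi-square p with groups - 1 df). When every value is identical the tie
#' correction denominator vanishes; that case returns H = 0, p = 1.
#'
#' @param x list of group value vectors, or a vector with `g` giving groups.
#' @param g optional grouping vector when `x` is not a list.
#' @return List with `statistic` (H), `p.value` and `df`.
#' @export
kruskal_wallis <- function(x, g = NULL) {
  if (!is.list(x)) {
    if (is.null(g)) stop("supply a list of groups or a grouping vector g")
    x <- split(as.numeric(x), g)
  }
  if (length(x) < 2 || any(lengths(x) == 0))
    stop("need >= 2 non-empty groups")
  vals <- unlist(x, use.names = FALSE)
  if (length(unique(vals)) == 1L)
    return(list(statistic = 0, p.value = 1, df = length(x) - 1L))
  kt <- stats::kruskal.test(x)
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       df = unname(kt$parameter))
}

#' Pearson correlation with a clinical score
#'
#' Product-moment correlation with the t-distribution p-value (n - 2 df);
#' pairs with a missing value in either vector are dropped.
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs).
#' @return List with `r`, `p.value` and `n` (complete pairs used).
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the vectors")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Full evaluation report for one measure
#'
#' Bundles the statistics used to compare AQI, SUVR and DVR: stratified
#' k-fold CV logistic classification with ROC metrics and the Youden
#' threshold, Cohen's d, the Kruskal-Wallis test, and (when clinical scores
#' are supplied) Pearson correlations with MMSE and CDR-SOB.
#'
#' @param values measure value per subject.
#' @param labels 0/1 labels (1 = AD).
#' @param k CV folds.
#' @param seed fold seed.
#' @param mmse,cdr_sob optional clinical scores per subject.
#' @param ridge logistic stabilizer.
#' @return An object of class `"aqi_eval"`.
#' @export
evaluate_measure <- function(values, labels, k = 10, seed = NULL,
                             mmse = NULL, cdr_sob = NULL, ridge = 1e-6) {
  labels <- as.numeric(labels)
  cv <- crossvalidate(values, labels, k = k, seed = seed, ridge = ridge)
  out <- list(cv = cv, auc = cv$auc, accuracy = cv$accuracy,
              sensitivity = cv$sensitivity, specificity = cv$specificity,
              threshold = cv$threshold,
              measure_threshold = cv$measure_threshold,
              effect_size = cohens_d(values[labels == 1], values[labels == 0]),
              kruskal = kruskal_wallis(split(values, labels)),
              cor_mmse = if (!is.null(mmse)) pearson_corr(values, mmse),
              cor_cdr_sob = if (!is.null(cdr_sob)) pearson_corr(values, cdr_sob))
  structure(out, class = "aqi_eval")
}

#' @export
print.aqi_eval <- function(x, ...) {
  cat(sprintf("AUC %.4f | accuracy %.3f | sensitivity %.3f | specificity %.3f\n",
              x$auc, x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("measure-scale threshold %.4g | Cohen's d %.2f | Kruskal-Wallis H %.2f (p %.2g)\n",
              x$measure_threshold, x$effect_size,
              x$kruskal$statistic, x$kruskal$p.value))
  if (!is.null(x$cor_mmse))
    cat(sprintf("corr MMSE r %.3f (p %.2g)", x$cor_mmse$r, x$cor_mmse$p.value))
  if (!is.null(x$cor_cdr_sob))
    cat(sprintf(" | corr CDR-SOB r %.3f (p %.2g)",
                x$cor_cdr_sob$r, x$cor_cdr_sob$p.value))
  if (!is.null(x$cor_mmse) || !is.null(x$cor_cdr_sob)) cat("\n")
  invisible(x)
}
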