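#' Fit the overall amyloid quantification index
#'
#' The central model of the package: region AQI values are computed for a
#' cohort, featured regions are selected by cross-validated lasso
#' ([lasso_select()]), each selected feature is z-scored with training-set
#' statistics, and the 0/1 group label is regressed on the z-scores by
#' ordinary least squares. The fitted linear combination
#' `AQI_overall = b0 + b1 X1 + b2 X2 + ...` (X z-scored region AQI) is the
#' subject-level index; on a balanced cohort the intercept is exactly the
#' label mean, 0.5.
#'
#' @param cohort a `"pet_cohort"` with both groups, or a numeric feature
#'   matrix of region AQI values (subjects x regions, colnames required)
#'   accompanied by `labels`.
#' @param params an [aqi_params()] used when features are computed from a
#'   cohort.
#' @param regions candidate regions (default: all non-reference regions).
#' @param reference_region excluded from the default candidates.
#' @param select logical; `FALSE` skips lasso selection and uses all
#'   candidate regions.
#' @param folds,seed CV folds and seed for the lasso lambda choice.
#' @param labels 0/1 labels, required when `cohort` is a matrix.
#' @return An object of class `"aqi_fit"` with elements `coefficients`
#'   (intercept first, then one per selected region), `center`/`scale`
#'   (training z-score statistics), `selection` (the
#'   `"lasso_selection"`, or NULL), `regions`, `params`, `fitted.values`
#'   and `y`. Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_ad = 6, n_hc = 6, seed = 3))
#' fit <- aqi_fit(coh, select = FALSE, regions = "caudal_anterior_cingulate")
#' coef(fit)
#' @export
aqi_fit <- function(cohort, params = aqi_params(), regions = NULL,
                    reference_region = "cerebellar_cortex", select = TRUE,
                    folds = 10, seed = 1L, labels = NULL) {
  if (inherits(cohort, "pet_cohort")) {
    x <- aqi_features(cohort, params, regions, reference_region)
    y <- attr(x, "labels")
  } else {
    x <- as.matrix(cohort)
    if (is.null(colnames(x))) stop("feature matrix needs region colnames")
    if (is.null(labels)) stop("labels are required with a feature matrix")
    y <- as.numeric(labels)
    if (!is.null(regions)) x <- x[, regions, drop = FALSE]
  }
  if (anyNA(y)) stop("all subjects must have a known group")
  if (length(unique(y)) < 2) stop("both groups must be present")
  selection <- NULL
  if (isTRUE(select)) {
    selection <- lasso_select(x, y, folds = folds, seed = seed)
    if (length(selection$regions) == 0)
      stop("lasso selected no region; refit with select = FALSE or supply regions")
    x <- x[, selection$regions, drop = FALSE]
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "))
  z <- scale(x, center = ctr, scale = scl)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, z), y)
  structure(list(coefficients = fit$coefficients,
                 center = ctr, scale = scl,
                 selection = selection, regions = colnames(x),
                 params = params,
                 fitted.values = drop(cbind(1, z) %*% fit$coefficients),
                 y = y),
            class = "aqi_fit")
}

#' Predict the overall index for new subjects
#'
#' Z-scores the selected regions' AQI with the stored training statistics
#' and applies the fitted linear combination.
#'
#' @param object an `"aqi_fit"`.
#' @param newdata a `"pet_cohort"` or a matrix/data.frame of region AQI
#'   values whose columns cover the model's regions.
#' @param ... unused.
#' @return Numeric vector of AQI_overall scores.
#' @export
predict.aqi_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  if (inherits(newdata, "pet_cohort"))
    newdata <- aqi_features(newdata, object$params)
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$regions, colnames(newdata))
  if (length(miss))
    stop("missing region value(s): ", paste(miss, collapse = ", "))
  z <- scale(newdata[, object$regions, drop = FALSE],
             center = object$center, scale = object$scale)
  drop(cbind(1, z) %*% object$coefficients)
}

#' @export
coef.aqi_fit <- function(object, ...) object$coefficients

#' @export
fitted.aqi_fit <- function(object, ...) object$fitted.values

#' @export
residuals.aqi_fit <- function(object, ...) object$y - object$fitted.values

#' @export
print.aqi_fit <- function(x, ...) {
  co <- x$coefficients
  terms <- paste(sprintf("%.4f x %s", co[-1L], names(co)[-1L]),
                 collapse = " + ")
  cat("overall AQI model:\n  AQI_overall =", terms,
      sprintf("+ %.4f\n", co[1L]))
  cat("  (regions z-scored with training statistics; HC = 0, AD = 1)\n")
  invisible(x)
}

#' @export
summary.aqi_fit <- function(object, ...) {
  acc <- mean((object$fitted.values >= 0.5) == (object$y == 1))
  structure(list(fit = object, in_sample_accuracy = acc),
            class = "summary.aqi_fit")
}

#' @export
print.summary.aqi_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$selection)) {
    cat("lasso region selection:\n")
    for (i in seq_along(x$fit$selection$regions))
      cat(sprintf("  %s (beta = %.4f)\n", x$fit$selection$regions[i],
                  x$fit$selection$beta[i]))
    cat(sprintf("  lambda (1-SE rule) = %.4g\n", x$fit$selection$lambda))
  }
  cat(sprintf("in-sample accuracy at score 0.5: %.3f (n = %d)\n",
              x$in_sample_accuracy, length(x$fit$y)))
  invisible(x)
}

#' Z-score and linearly combine features without region selection
#'
#' Lower-level building block of [aqi_fit()]: fits the overall index on an
#' explicit feature matrix (no lasso step).
#'
#' @param x numeric matrix of region AQI values (colnames required).
#' @param y 0/1 labels.
#' @return An `"aqi_fit"`.
#' @export
fit_overall <- function(x, y) {
  aqi_fit(x, labels = y, select = FALSE)
}
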