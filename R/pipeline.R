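#' End-to-end synthetic study pipeline
#'
#' Simulates (or accepts) a training and a held-out testing cohort, computes
#' AQI, SUVR and reference-Logan DVR, fits the overall AQI model (lasso
#' region selection + z-scored linear combination), evaluates each measure
#' on the training set by stratified k-fold cross-validation, and then
#' evaluates the testing set with the measure-scale threshold derived from
#' the training set.
#'
#' @param config a [cohort_config()] describing the training cohort; its
#'   `seed` drives all simulation randomness.
#' @param n_test_ad,n_test_hc held-out testing cohort sizes (simulated with
#'   `config$seed + 1`); set both to 0 to skip the testing stage.
#' @param train,test optional pre-built `"pet_cohort"` objects; when given,
#'   simulation is skipped.
#' @param params an [aqi_params()].
#' @param window a [quant_window()].
#' @param suvr_regions regions averaged into the composite SUVR/DVR value;
#'   default the featured regions of [region_presets()].
#' @param folds,seed CV folds and fold/selection seed.
#' @return An object of class `"aqi_pipeline"`: the fitted `model`, the
#'   per-measure `train` evaluations (`"aqi_eval"`), the `test` metrics at
#'   the training thresholds, and the cohorts used.
#' @export
run_aqi_pipeline <- function(config = cohort_config(),
                             n_test_ad = 10, n_test_hc = 10,
                             train = NULL, test = NULL,
                             params = aqi_params(), window = quant_window(),
                             suvr_regions = c("caudal_anterior_cingulate",
                                              "caudate"),
                             folds = 10, seed = 1L) {
  if (is.null(train)) train <- simulate_cohort(config)
  if (is.null(test) && (n_test_ad > 0 || n_test_hc > 0)) {
    tc <- config
    tc$n_ad <- n_test_ad
    tc$n_hc <- n_test_hc
    tc$seed <- if (is.null(config$seed)) NULL else config$seed + 1L
    test <- simulate_cohort(tc)
  }
  y_tr <- cohort_labels(train)
  model <- aqi_fit(train, params = params, folds = folds, seed = seed)
  meas_tr <- cohort_measures(train, c("suvr", "dvr"), params, window)
  vals_tr <- list(
    AQI = predict(model),
    SUVR = composite_measure(meas_tr, "SUVR", suvr_regions)$value,
    DVR = composite_measure(meas_tr, "DVR", suvr_regions)$value)
  mmse <- vapply(train$subjects, function(s) as.numeric(s$mmse), 0)
  cdr <- vapply(train$subjects, function(s) as.numeric(s$cdr_sob), 0)
  train_eval <- lapply(vals_tr, evaluate_measure, labels = y_tr, k = folds,
                       seed = seed, mmse = mmse, cdr_sob = cdr)
  test_eval <- NULL
  if (!is.null(test)) {
    y_te <- cohort_labels(test)
    meas_te <- cohort_measures(test, c("suvr", "dvr"), params, window)
    vals_te <- list(
      AQI = predict(model, test),
      SUVR = composite_measure(meas_te, "SUVR", suvr_regions)$value,
      DVR = composite_measure(meas_te, "DVR", suvr_regions)$value)
    test_eval <- lapply(names(vals_te), function(m) {
      thr <- train_eval[[m]]$measure_threshold
      c(threshold_metrics(vals_te[[m]], y_te, thr),
        list(auc = roc_analysis(vals_te[[m]], y_te)$auc,
             threshold = thr))
    })
    names(test_eval) <- names(vals_te)
  }
  structure(list(model = model, train_eval = train_eval,
                 test_eval = test_eval, train = train, test = test,
                 train_values = vals_tr, folds = folds, seed = seed),
            class = "aqi_pipeline")
}

#' @export
print.aqi_pipeline <- function(x, ...) {
  cat(sprintf("aqi pipeline: %d training / %d testing subjects, %d-fold CV\n",
              length(x$train$subjects),
              if (is.null(x$test)) 0L else length(x$test$subjects), x$folds))
  cat("\ntraining set (cross-validated):\n")
  cat(sprintf("%-6s %8s %8s %8s %8s %10s %8s\n",
              "", "AUC", "sens", "spec", "acc", "threshold", "d"))
  for (m in names(x$train_eval)) {
    e <- x$train_eval[[m]]
    cat(sprintf("%-6s %8.4f %8.3f %8.3f %8.3f %10.4g %8.2f\n",
                m, e$auc, e$sensitivity, e$specificity, e$accuracy,
                e$measure_threshold, e$effect_size))
  }
  if (!is.null(x$test_eval)) {
    cat("\ntesting set (training-derived threshold):\n")
    cat(sprintf("%-6s %8s %8s %8s %8s\n", "", "AUC", "sens", "spec", "acc"))
    for (m in names(x$test_eval)) {
      e <- x$test_eval[[m]]
      cat(sprintf("%-6s %8.4f %8.3f %8.3f %8.3f\n",
                  m, e$auc, e$sensitivity, e$specificity, e$accuracy))
    }
  }
  invisible(x)
}
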