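#' Lasso selection of featured regions
#'
#' Fits the lasso path of the 0/1 group label on internally standardized
#' region features (squared-error loss, as in MSE-based lasso regression),
#' chooses the regularization strength by the cross-validated one-standard-
#' error rule (largest lambda whose CV MSE is within one SE of the minimum),
#' and returns the regions whose coefficients survive, ordered by
#' decreasing |beta|. Coefficients are reported on the standardized-feature
#' scale.
#'
#' @param x numeric matrix, one column per region (colnames required).
#' @param y 0/1 group labels.
#' @param lambda optional lambda sequence passed to glmnet.
#' @param folds CV folds for the lambda choice (stratified on `y`).
#' @param seed fold seed.
#' @param floor minimum |beta| counted as selected.
#' @param ... further arguments passed to [glmnet::cv.glmnet()] (e.g.
#'   `thresh`).
#' @return An object of class `"lasso_selection"`: `regions` (character,
#'   by decreasing |beta|), `beta` (named, selected only), `beta_full`
#'   (all regions at the chosen lambda), `lambda`, and the `cv` glmnet fit.
#'   With a constant response the selection is empty.
#' @export
lasso_select <- function(x, y, lambda = NULL, folds = 10, seed = 1L,
                         floor = 1e-6, ...) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("x must have region column names")
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("dimension mismatch")
  empty <- structure(list(regions = character(0),
                          beta = stats::setNames(numeric(0), character(0)),
                          beta_full = stats::setNames(rep(0, ncol(x)), colnames(x)),
                          lambda = NA_real_, cv = NULL, dropped = character(0)),
                     class = "lasso_selection")
  if (stats::var(y) == 0) return(empty)
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped))
    warning("dropping constant feature column(s): ",
            paste(dropped, collapse = ", "))
  keep <- sds > 0
  if (!any(keep)) return(empty)
  xs <- scale(x[, keep, drop = FALSE])
  # stratify folds for a binary response, plain random folds otherwise
  foldid <- if (length(unique(y)) == 2) {
    stratified_folds(y, folds, seed)
  } else {
    if (!is.null(seed)) set.seed(seed)
    sample(rep_len(seq_len(folds), length(y)))
  }
  cv <- glmnet::cv.glmnet(xs, y, family = "gaussian", standardize = FALSE,
                          foldid = foldid, lambda = lambda, ...)
  beta <- drop(as.matrix(stats::coef(cv, s = "lambda.1se")))[-1L]
  names(beta) <- colnames(xs)
  beta_full <- stats::setNames(rep(0, ncol(x)), colnames(x))
  beta_full[names(beta)] <- beta
  sel <- beta[abs(beta) > floor]
  sel <- sel[order(-abs(sel))]
  structure(list(regions = names(sel), beta = sel, beta_full = beta_full,
                 lambda = cv$lambda.1se, cv = cv, dropped = dropped),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  if (length(x$regions) == 0) {
    cat("lasso selection: no region selected\n")
  } else {
    cat(sprintf("lasso selection (lambda = %.4g, 1-SE rule): %d region(s)\n",
                x$lambda, length(x$regions)))
    for (i in seq_along(x$regions))
      cat(sprintf("  %s (beta = %.4f)\n", x$regions[i], x$beta[i]))
  }
  invisible(x)
}
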