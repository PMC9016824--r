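#' Grid specification for AQI parameter tuning
#'
#' Defaults follow the original search: t1 from 50 to 3300 s and t2 from 300
#' to 3300 s in 50-s steps, a from 0 to 1 in 0.1 steps. (t1 starts at 50 s
#' rather than 0 because the index divides by t1.)
#'
#' @param t1,t2 numeric vectors of candidate time points (s).
#' @param a numeric vector of candidate weights in [0, 1].
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(t1 = seq(50, 3300, by = 50),
                      t2 = seq(300, 3300, by = 50),
                      a = seq(0, 1, by = 0.1)) {
  if (any(t1 <= 0) || any(t2 <= 0)) stop("t1 and t2 must be > 0")
  if (any(a < 0 | a > 1)) stop("a must be in [0, 1]")
  structure(list(t1 = sort(unique(t1)), t2 = sort(unique(t2)),
                 a = sort(unique(a))),
            class = "grid_spec")
}

#' Grid-search optimization of the AQI parameters
#'
#' Evaluates every (t1, t2, a) grid point by computing the region AQI for
#' all subjects and scoring it with stratified k-fold cross-validated
#' logistic classification ([crossvalidate()]); the accuracy at the
#' CV-pooled Youden threshold is recorded. Grid points for which t2 does not
#' exceed every subject's peak time (or that reach beyond the scan) are
#' excluded as invalid rather than failing the search. The maximizer is
#' returned with ties broken by minimal required scan time `max(t1, t2)`,
#' then minimal t1, then minimal a, making the result deterministic.
#'
#' @param cohort a `"pet_cohort"` containing both groups.
#' @param region region whose AQI is tuned.
#' @param grid a [grid_spec()].
#' @param folds CV folds.
#' @param seed fold-assignment seed (one assignment is shared by all grid
#'   points).
#' @return An object of class `"aqi_tune"`: `best_params` ([aqi_params()]),
#'   `best_accuracy`, and the full accuracy `surface` data.frame
#'   (t1, t2, a, accuracy, valid).
#' @export
tune_aqi_params <- function(cohort, region, grid = grid_spec(), folds = 10,
                            seed = 1L) {
  stopifnot(inherits(cohort, "pet_cohort"), inherits(grid, "grid_spec"))
  y <- cohort_labels(cohort)
  if (length(unique(y)) < 2) stop("cohort must contain both groups")
  tacs <- lapply(cohort$subjects, subject_tac, region = region)
  last_mid <- min(vapply(tacs, function(tc)
    tc$schedule$mid[length(tc$schedule$mid)], 0))
  tmax <- vapply(tacs, find_tmax, 0)
  s_tmax <- vapply(tacs, function(tc) max(tc$activity), 0)
  s0 <- vapply(tacs, function(tc) tc$activity[1L], 0)
  dose <- vapply(tacs, function(tc) tc$injected_dose, 0)
  times <- sort(unique(c(grid$t1, grid$t2)))
  times <- times[times <= last_mid + 1e-9]
  s_at <- vapply(tacs, function(tc) interpolate_tac(tc, times),
                 numeric(length(times)))   # times x subjects
  fold <- stratified_folds(y, folds, seed)
  surf <- expand.grid(t1 = grid$t1, t2 = grid$t2, a = grid$a,
                      KEEP.OUT.ATTRS = FALSE)
  surf$accuracy <- NA_real_
  surf$valid <- surf$t1 <= last_mid + 1e-9 & surf$t2 <= last_mid + 1e-9 &
    surf$t2 > max(tmax)
  n_invalid <- sum(!surf$valid)
  if (n_invalid > 0)
    message(sprintf("tune_aqi_params: %d of %d grid points invalid (t2 <= t_max for some subject or beyond scan); excluded",
                    n_invalid, nrow(surf)))
  if (!any(surf$valid)) stop("no valid grid point")
  cv_acc <- function(x) {
    scores <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- fit_logistic(x[tr], y[tr])
      scores[!tr] <- predict(fit, x[!tr])
    }
    roc_analysis(scores, y)$accuracy
  }
  tix <- match(surf$t1, times)
  t2ix <- match(surf$t2, times)
  for (i in which(surf$valid)) {
    s1 <- s_at[tix[i], ]
    s2 <- s_at[t2ix[i], ]
    x <- (surf$a[i] * (s1 - s0) / surf$t1[i] -
            (1 - surf$a[i]) * (s_tmax - s2) / (surf$t2[i] - tmax)) / dose
    surf$accuracy[i] <- cv_acc(x)
  }
  ok <- which(surf$valid)
  best <- ok[order(-surf$accuracy[ok], pmax(surf$t1[ok], surf$t2[ok]),
                   surf$t1[ok], surf$a[ok])][1L]
  structure(list(best_params = aqi_params(surf$a[best], surf$t1[best],
                                          surf$t2[best]),
                 best_accuracy = surf$accuracy[best],
                 surface = surf, region = region, folds = folds, seed = seed),
            class = "aqi_tune")
}

#' @export
print.aqi_tune <- function(x, ...) {
  cat(sprintf("AQI grid search on '%s': best accuracy %.3f at a = %g, t1 = %g s, t2 = %g s\n",
              x$region, x$best_accuracy, x$best_params$a, x$best_params$t1,
              x$best_params$t2))
  cat(sprintf("(%d valid of %d grid points, %d-fold CV)\n",
              sum(x$surface$valid), nrow(x$surface), x$folds))
  invisible(x)
}

#' @export
plot.aqi_tune <- function(x, t1 = x$best_params$t1, ...) {
  d <- x$surface[x$surface$t1 == t1 & x$surface$valid, ]
  if (nrow(d) == 0) stop("no valid surface points at t1 = ", t1)
  t2v <- sort(unique(d$t2)); av <- sort(unique(d$a))
  z <- matrix(NA_real_, length(t2v), length(av))
  z[cbind(match(d$t2, t2v), match(d$a, av))] <- d$accuracy
  graphics::image(t2v, av, z, xlab = "t2 (s)", ylab = "a",
                  main = sprintf("CV accuracy, t1 = %g s", t1), ...)
  graphics::points(x$best_params$t2, x$best_params$a, pch = 4, cex = 2)
  invisible(x)
}
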