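#' AQI parameters
#'
#' The weight and time points of the two-slope amyloid quantification index:
#' `a` weighs the retention slope from scan start up to `t1` against the
#' clearance slope from the uptake peak down to `t2`. The defaults
#' (`a = 0.5`, `t1 = t2 = 1650` s) are the grid-search optimum on the
#' original training data and imply that no frame ending after 30 min is
#' needed.
#'
#' @param a slope weight in [0, 1].
#' @param t1 retention-slope time point (s), > 0.
#' @param t2 clearance-slope time point (s); must exceed the TAC's peak time
#'   when applied.
#' @return An object of class `"aqi_params"`.
#' @export
aqi_params <- function(a = 0.5, t1 = 1650, t2 = 1650) {
  if (!is.numeric(a) || a < 0 || a > 1) stop("a must be in [0, 1]")
  if (t1 <= 0) stop("t1 must be > 0")
  if (t2 <= 0) stop("t2 must be > 0")
  structure(list(a = a, t1 = t1, t2 = t2), class = "aqi_params")
}

#' @export
print.aqi_params <- function(x, ...) {
  cat(sprintf("aqi_params: a = %g, t1 = %g s, t2 = %g s\n", x$a, x$t1, x$t2))
  invisible(x)
}

#' Late-window settings for SUVR and Logan DVR
#'
#' @param start,end window bounds (s); frames belong to the window when their
#'   mid-time lies in the closed interval. Default 1800--3600 s (30--60 min
#'   post-injection).
#' @param reference_region reference region label (default cerebellar cortex).
#' @return An object of class `"quant_window"`.
#' @export
quant_window <- function(start = 1800, end = 3600,
                         reference_region = "cerebellar_cortex") {
  if (start < 0 || end <= start) stop("need 0 <= start < end")
  structure(list(start = start, end = end,
                 reference_region = reference_region),
            class = "quant_window")
}

#' Region-level amyloid quantification index
#'
#' The reference-free two-slope index
#' \deqn{AQI = a (S(t_1) - S(0))/t_1 - (1 - a)(S(t_{max}) - S(t_2))/(t_2 - t_{max})}
#' normalized by the injected dose. `S(.)` is the linearly interpolated TAC,
#' `S(0)` the first-frame average, `S(t_max)` the value of the peak frame.
#' The first term rewards mid-phase retention, the second penalizes fast
#' clearance from the peak; amyloid-positive tissue (greater retention,
#' slower clearance) raises both contributions.
#'
#' @param tac a [tac()].
#' @param params an [aqi_params()]; `t1` and `t2` must not exceed the last
#'   frame mid-time and `t2` must exceed the peak time.
#' @return AQI value, in (Bq/ml/s)/MBq. May be of either sign.
#' @examples
#' sch <- pib_schedule()
#' act <- approx(c(5, 150, 3450), c(10, 100, 40), xout = mid_times(sch))$y
#' compute_aqi(tac("ctx", sch, act, 1))
#' @export
compute_aqi <- function(tac, params = aqi_params()) {
  stopifnot(inherits(tac, "tac"), inherits(params, "aqi_params"))
  last_mid <- tac$schedule$mid[length(tac$schedule$mid)]
  if (params$t1 > last_mid + 1e-9 || params$t2 > last_mid + 1e-9)
    stop(sprintf("t1/t2 must be <= last frame mid-time (%g s)", last_mid))
  tmax <- find_tmax(tac)
  if (params$t2 <= tmax)
    stop(sprintf("t2 (%g s) must exceed the peak time t_max (%g s)",
                 params$t2, tmax))
  s0 <- tac$activity[1L]
  s_tmax <- max(tac$activity)
  s1 <- interpolate_tac(tac, params$t1)
  s2 <- interpolate_tac(tac, params$t2)
  raw <- params$a * (s1 - s0) / params$t1 -
    (1 - params$a) * (s_tmax - s2) / (params$t2 - tmax)
  raw / tac$injected_dose
}

# frames whose mid-time lies in the closed window
window_frames <- function(schedule, window) {
  which(schedule$mid >= window$start - 1e-9 & schedule$mid <= window$end + 1e-9)
}

#' Standardized uptake value ratio
#'
#' Ratio of the duration-weighted mean activity of the target region to that
#' of the reference region over the frames whose mid-times fall in the late
#' window.
#'
#' @param target,reference [tac()] objects sharing one schedule.
#' @param window a [quant_window()].
#' @return SUVR (unitless, > 0 for physical inputs).
#' @export
compute_suvr <- function(target, reference, window = quant_window()) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (!same_schedule(target$schedule, reference$schedule))
    stop("target and reference must share a frame schedule")
  w <- window_frames(target$schedule, window)
  if (length(w) < 2L)
    stop(sprintf("fewer than 2 frames have mid-times in [%g, %g] s",
                 window$start, window$end))
  dur <- target$schedule$duration[w]
  ref_mean <- sum(reference$activity[w] * dur) / sum(dur)
  if (ref_mean <= 0) stop("reference mean activity in the window is <= 0")
  (sum(target$activity[w] * dur) / sum(dur)) / ref_mean
}

#' Reference-region Logan graphical distribution volume ratio
#'
#' For each window frame i with mid-time t_i, plots
#' `y_i = int_0^{t_i} C_T / C_T(t_i)` against
#' `x_i = int_0^{t_i} C_ref / C_T(t_i)` (trapezoidal integrals of the
#' piecewise-linear TACs) and returns the ordinary least-squares slope, which
#' approaches DVR = 1 + BPND once the plot is linear. No population k2'
#' correction term is applied (set `k2_ref_pop` to add one).
#'
#' @inheritParams compute_suvr
#' @param k2_ref_pop optional population reference efflux rate (1/min); when
#'   given, `C_ref(t_i)/k2' ` is added to the numerator of `x_i` as in the
#'   full reference-Logan formulation.
#' @return DVR (unitless).
#' @export
logan_dvr <- function(target, reference, window = quant_window(),
                      k2_ref_pop = NULL) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (!same_schedule(target$schedule, reference$schedule))
    stop("target and reference must share a frame schedule")
  w <- window_frames(target$schedule, window)
  if (length(w) < 2L)
    stop(sprintf("fewer than 2 frames have mid-times in [%g, %g] s",
                 window$start, window$end))
  ct <- target$activity[w]
  if (any(ct <= 0))
    stop("target activity must be > 0 at all window frames")
  mids <- target$schedule$mid[w]
  int_t <- trapezoid_integral(target, mids)
  int_r <- trapezoid_integral(reference, mids)
  if (!is.null(k2_ref_pop))
    int_r <- int_r + reference$activity[w] / (k2_ref_pop / 60)
  x <- int_r / ct
  y <- int_t / ct
  unname(stats::lm.fit(cbind(1, x), y)$coefficients[2L])
}

#' Region-level measures for every subject of a cohort
#'
#' @param cohort a `"pet_cohort"`.
#' @param measures subset of `c("aqi", "suvr", "dvr")`.
#' @param params an [aqi_params()] for the AQI.
#' @param window a [quant_window()] for SUVR/DVR; its `reference_region` must
#'   be present in every subject.
#' @param regions regions to quantify; default all target (non-reference)
#'   regions.
#' @return A long data.frame with columns `subject_id`, `group`, `region`,
#'   `measure`, `value`.
#' @export
cohort_measures <- function(cohort, measures = c("aqi", "suvr", "dvr"),
                            params = aqi_params(), window = quant_window(),
                            regions = NULL) {
  stopifnot(inherits(cohort, "pet_cohort"))
  measures <- match.arg(measures, several.ok = TRUE)
  all_regions <- rownames(cohort$subjects[[1]]$activity)
  if (is.null(regions))
    regions <- setdiff(all_regions, window$reference_region)
  if (any(c("suvr", "dvr") %in% measures) &&
      !window$reference_region %in% all_regions)
    stop(sprintf("reference region '%s' is missing from the cohort",
                 window$reference_region))
  rows <- list()
  for (s in cohort$subjects) {
    ref <- if (window$reference_region %in% rownames(s$activity))
      subject_tac(s, window$reference_region) else NULL
    for (rg in regions) {
      tc <- subject_tac(s, rg)
      for (m in measures) {
        val <- switch(m,
                      aqi = compute_aqi(tc, params),
                      suvr = compute_suvr(tc, ref, window),
                      dvr = logan_dvr(tc, ref, window))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s$subject_id, group = s$group, region = rg,
          measure = toupper(m), value = val, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-subject composite of a region-level measure
#'
#' Averages one measure over a set of regions for each subject, e.g. the
#' multi-region SUVR/DVR value used for classification.
#'
#' @param measures_df output of [cohort_measures()].
#' @param measure one of `"AQI"`, `"SUVR"`, `"DVR"`.
#' @param regions regions to average over; default all present.
#' @return A data.frame with `subject_id`, `group`, `value`, ordered as the
#'   input.
#' @export
composite_measure <- function(measures_df, measure, regions = NULL) {
  d <- measures_df[measures_df$measure == toupper(measure), , drop = FALSE]
  if (!is.null(regions)) {
    miss <- setdiff(regions, unique(d$region))
    if (length(miss))
      stop("missing region value(s): ", paste(miss, collapse = ", "))
    d <- d[d$region %in% regions, , drop = FALSE]
  }
  if (nrow(d) == 0) stop("no rows for measure ", measure)
  ids <- unique(d$subject_id)
  val <- vapply(ids, function(id) mean(d$value[d$subject_id == id]), 0)
  grp <- vapply(ids, function(id) d$group[d$subject_id == id][1L], "")
  data.frame(subject_id = ids, group = grp, value = unname(val),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' AQI feature matrix of a cohort
#'
#' One row per subject, one column per target region, entries the
#' dose-normalized region AQI.
#'
#' @inheritParams cohort_measures
#' @param reference_region region excluded from the default region set.
#' @return Numeric matrix with subject ids as rownames and regions as
#'   colnames; attribute `"labels"` holds the 0/1 group coding (HC = 0,
#'   AD = 1).
#' @export
aqi_features <- function(cohort, params = aqi_params(), regions = NULL,
                         reference_region = "cerebellar_cortex") {
  stopifnot(inherits(cohort, "pet_cohort"))
  all_regions <- rownames(cohort$subjects[[1]]$activity)
  if (is.null(regions)) regions <- setdiff(all_regions, reference_region)
  x <- matrix(NA_real_, length(cohort$subjects), length(regions),
              dimnames = list(vapply(cohort$subjects, function(s) s$subject_id, ""),
                              regions))
  for (i in seq_along(cohort$subjects))
    for (rg in regions)
      x[i, rg] <- compute_aqi(subject_tac(cohort$subjects[[i]], rg), params)
  attr(x, "labels") <- cohort_labels(cohort)
  x
}
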