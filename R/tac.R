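#' Region time-activity curve
#'
#' A framed time-activity curve (TAC): one region's activity concentration
#' per frame plus the injected dose used for normalization. The curve value
#' at time zero, S(0), is by convention the first-frame average, i.e.
#' `activity[1]`.
#'
#' @param region region label (character scalar).
#' @param schedule a [frame_schedule()].
#' @param activity numeric vector of activity concentrations (Bq/ml), one per
#'   frame; all finite.
#' @param injected_dose injected dose in MBq (> 0).
#' @return An object of class `"tac"`.
#' @examples
#' tc <- tac("cerebellar_cortex", pib_schedule(), seq(100, 2600, 100), 370)
#' find_tmax(tc)
#' @export
tac <- function(region, schedule, activity, injected_dose) {
  stopifnot(inherits(schedule, "frame_schedule"))
  activity <- as.numeric(activity)
  if (length(activity) != length(schedule$start))
    stop(sprintf("activity has %d values but the schedule has %d frames",
                 length(activity), length(schedule$start)))
  if (!all(is.finite(activity)))
    stop("activity values must be finite")
  if (!is.numeric(injected_dose) || length(injected_dose) != 1L || injected_dose <= 0)
    stop("injected_dose must be a positive scalar (MBq)")
  structure(list(region = as.character(region), schedule = schedule,
                 activity = activity, injected_dose = injected_dose),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("tac: region '%s', %d frames, dose %.1f MBq, peak %.1f Bq/ml at %g s\n",
              x$region, length(x$activity), x$injected_dose,
              max(x$activity), find_tmax(x)))
  invisible(x)
}

#' Linear interpolation of a TAC at arbitrary times
#'
#' The TAC is treated as piecewise linear in the (mid-time, activity) points.
#' Below the first mid-time the curve is held constant at `activity[1]`
#' (consistent with S(0) being the first-frame average). Queries beyond the
#' last mid-time are an error: no extrapolation is performed.
#'
#' @param tac a [tac()].
#' @param query_times numeric vector of times (s) in `[0, last mid-time]`.
#' @return Numeric vector of interpolated activities (Bq/ml).
#' @export
interpolate_tac <- function(tac, query_times) {
  stopifnot(inherits(tac, "tac"))
  mid <- tac$schedule$mid
  if (any(query_times < 0))
    stop("query times must be >= 0")
  if (any(query_times > mid[length(mid)] + 1e-9))
    stop(sprintf("query time %g s is beyond the last frame mid-time (%g s); no extrapolation",
                 max(query_times), mid[length(mid)]))
  if (length(mid) == 1L) return(rep(tac$activity, length(query_times)))
  stats::approx(mid, tac$activity, xout = pmin(query_times, mid[length(mid)]),
                method = "linear", yleft = tac$activity[1L])$y
}

#' Time of peak uptake
#'
#' Returns the mid-time of the frame with maximal activity; on ties, the
#' earliest such frame.
#'
#' @param tac a [tac()].
#' @return t_max in seconds.
#' @export
find_tmax <- function(tac) {
  stopifnot(inherits(tac, "tac"))
  if (all(is.na(tac$activity))) stop("all activity values are NaN/NA")
  tac$schedule$mid[which.max(tac$activity)]
}

#' Trapezoidal integral of a TAC from scan start
#'
#' Integrates the piecewise-linear TAC from 0 to `upto`, prepending the point
#' (0, `activity[1]`) so the integral covers the full scan from injection.
#'
#' @param tac a [tac()].
#' @param upto upper limit(s) of integration (s), each in `[0, last mid-time]`.
#' @return Integral value(s) in Bq s/ml.
#' @export
trapezoid_integral <- function(tac, upto) {
  stopifnot(inherits(tac, "tac"))
  if (any(upto < 0)) stop("integration limit must be >= 0")
  mid <- tac$schedule$mid
  if (any(upto > mid[length(mid)] + 1e-9))
    stop("integration limit beyond the last frame mid-time")
  tt <- c(0, mid)
  yy <- c(tac$activity[1L], tac$activity)
  # cumulative trapezoid areas at the knots, then an exact partial segment
  area <- c(0, cumsum(diff(tt) * (yy[-length(yy)] + yy[-1L]) / 2))
  seg <- findInterval(upto, tt, rightmost.closed = TRUE)
  yq <- stats::approx(tt, yy, xout = upto)$y
  area[seg] + (upto - tt[seg]) * (yy[seg] + yq) / 2
}

#' Truncate a TAC to an early-scan window
#'
#' Keeps only frames whose end time is at or before `t_cut`. With the PiB
#' schedule and `t_cut = 1800`, 20 frames remain (the last retained mid-time
#' is 1650 s), which is all the data the default AQI needs.
#'
#' @param tac a [tac()].
#' @param t_cut cutoff time (s), > 0.
#' @return A new [tac()] containing the surviving frames.
#' @export
truncate_tac <- function(tac, t_cut) {
  stopifnot(inherits(tac, "tac"))
  if (!is.numeric(t_cut) || length(t_cut) != 1L || t_cut <= 0)
    stop("t_cut must be a positive scalar (s)")
  keep <- tac$schedule$end <= t_cut + 1e-9
  if (!any(keep))
    stop(sprintf("no frame ends at or before t_cut = %g s", t_cut))
  sch <- frame_schedule(tac$schedule$start[keep], tac$schedule$duration[keep])
  tac(tac$region, sch, tac$activity[keep], tac$injected_dose)
}
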