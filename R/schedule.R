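#' Frame schedule of a dynamic PET acquisition
#'
#' Describes the framing of a dynamic scan as contiguous frames starting at
#' time zero. All times are in seconds.
#'
#' @param frame_start numeric vector of frame start times (s); must begin at 0
#'   and be contiguous with `frame_duration`.
#' @param frame_duration numeric vector of frame durations (s), all positive.
#' @return An object of class `"frame_schedule"` with elements `start`,
#'   `duration`, `end` and `mid` (frame middle times).
#' @examples
#' sch <- frame_schedule(c(0, 10, 20), c(10, 10, 60))
#' mid_times(sch)
#' @seealso [pib_schedule()] for the 60-min PiB framing used throughout.
#' @export
frame_schedule <- function(frame_start, frame_duration) {
  frame_start <- as.numeric(frame_start)
  frame_duration <- as.numeric(frame_duration)
  if (length(frame_start) != length(frame_duration) || length(frame_start) == 0L)
    stop("frame_start and frame_duration must be non-empty vectors of equal length")
  if (anyNA(frame_start) || anyNA(frame_duration))
    stop("frame times must be finite")
  if (any(frame_duration <= 0))
    stop("all frame durations must be > 0")
  if (abs(frame_start[1L]) > 1e-9)
    stop("first frame must start at 0 s")
  if (length(frame_start) > 1L) {
    gap <- frame_start[-1L] - (frame_start[-length(frame_start)] +
                               frame_duration[-length(frame_duration)])
    if (any(abs(gap) > 1e-6)) {
      bad <- which(abs(gap) > 1e-6)[1L]
      stop(sprintf("frames must be contiguous: gap of %.3f s before frame %d",
                   gap[bad], bad + 1L))
    }
  }
  structure(list(start = frame_start,
                 duration = frame_duration,
                 end = frame_start + frame_duration,
                 mid = frame_start + frame_duration / 2),
            class = "frame_schedule")
}

#' The 60-min dynamic PiB frame schedule
#'
#' The standard amyloid acquisition framing: 12 x 10 s, 3 x 60 s, 11 x 5 min,
#' 26 frames covering 0--3600 s.
#'
#' @return A [frame_schedule()].
#' @export
pib_schedule <- function() {
  dur <- c(rep(10, 12), rep(60, 3), rep(300, 11))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' Frame middle times
#'
#' @param schedule a [frame_schedule()].
#' @return Numeric vector of frame mid-times (s), strictly increasing.
#' @export
mid_times <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$mid
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("frame_schedule: %d frames, 0-%g s\n", length(x$start), max(x$end)))
  cat("durations (s):", paste(rle(x$duration)$lengths, "x", rle(x$duration)$values,
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.frame_schedule <- function(x) length(x$start)

same_schedule <- function(a, b) {
  length(a$start) == length(b$start) &&
    all(abs(a$start - b$start) < 1e-6) &&
    all(abs(a$duration - b$duration) < 1e-6)
}
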