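#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule is the ordered set of contiguous, non-overlapping time
#' frames (in minutes from injection) over which list-mode data are binned.
#'
#' @param starts,ends Numeric vectors of frame start/end times in minutes.
#'   Frames must be contiguous (each start equals the previous end), the first
#'   frame must start at 0, and end times must be strictly increasing.
#' @return An object of class `frame_schedule` with columns `start`, `end`,
#'   `mid` (arithmetic midpoint) and `dur` (duration), all in minutes.
#' @examples
#' fdg_schedule()
#' acac_schedule()
#' @export
frame_schedule <- function(starts, ends) {
  starts <- as.numeric(starts); ends <- as.numeric(ends)
  if (length(starts) != length(ends) || length(starts) < 1L)
    stop("starts and ends must be non-empty vectors of equal length")
  if (starts[1L] != 0) stop("first frame must start at 0")
  if (any(ends <= starts)) stop("every frame must have end > start")
  if (any(diff(ends) <= 0)) stop("frame end times must be strictly increasing")
  if (length(starts) > 1L && any(abs(starts[-1L] - ends[-length(ends)]) > 1e-9))
    stop("frames must be contiguous (each start equals the previous end)")
  out <- data.frame(start = starts, end = ends,
                    mid = (starts + ends) / 2, dur = ends - starts)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

# Build a contiguous schedule from (count, duration) blocks.
schedule_from_blocks <- function(counts, durations_min) {
  dur <- rep(durations_min, counts)
  ends <- cumsum(dur)
  frame_schedule(c(0, ends[-length(ends)]), ends)
}

#' Standard 60-min FDG frame schedule
#'
#' 12 x 10 s, 8 x 30 s, 6 x 4 min and 6 x 5 min frames (26 frames, 60 min).
#' @return A [frame_schedule()].
#' @export
fdg_schedule <- function() {
  schedule_from_blocks(c(12L, 8L, 6L, 6L), c(10 / 60, 30 / 60, 4, 5))
}

#' Standard 10-min acetoacetate frame schedule
#'
#' 12 x 10 s, 8 x 30 s and 1 x 4 min frames (21 frames, 10 min), matching the
#' short physical half-life and fast kinetics of 11C-acetoacetate.
#' @return A [frame_schedule()].
#' @export
acac_schedule <- function() {
  schedule_from_blocks(c(12L, 8L, 1L), c(10 / 60, 30 / 60, 4))
}

#' Total duration of a frame schedule in minutes
#' @param schedule A [frame_schedule()].
#' @return Scalar, minutes.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$end[nrow(schedule)]
}

#' Time-activity curve for one tracer
#'
#' Frame-averaged tissue radioactivity concentration over a dynamic scan.
#'
#' @param schedule A [frame_schedule()].
#' @param values Numeric vector, one finite activity value (kBq/mL) per frame.
#' @param tracer_label `"glucose_tracer"` or `"acac_tracer"`.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, values, tracer_label = c("glucose_tracer", "acac_tracer")) {
  stopifnot(inherits(schedule, "frame_schedule"))
  tracer_label <- match.arg(tracer_label)
  values <- as.numeric(values)
  if (length(values) != nrow(schedule))
    stop("need exactly one value per frame (", nrow(schedule), " frames, ",
         length(values), " values)")
  if (any(!is.finite(values))) stop("TAC values must be finite")
  structure(list(schedule = schedule, values = values, tracer_label = tracer_label),
            class = "tac")
}
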