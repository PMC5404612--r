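#' Construct a PET frame schedule
#'
#' Builds the temporal sampling grid shared by all time-activity curves of a
#' dynamic acquisition from a compact binning specification. The conventional
#' 120-min raclopride protocol, for example, bins list-mode data into
#' 6 x 0.5, 3 x 1, 2 x 2 and 22 x 5 min frames (33 frames in total).
#'
#' @param spec A list of \code{c(count, duration)} pairs (or a 2-column
#'   matrix/data.frame with columns count, duration), durations in minutes.
#' @return An object of class \code{frame_schedule}: a list with numeric
#'   vectors \code{start}, \code{end}, \code{mid}, \code{dur} (minutes) and
#'   the frame count \code{n}. Frames are contiguous, start at 0 and are
#'   interpreted as half-open intervals \code{[start, end)}.
#' @examples
#' sched <- make_frame_schedule(list(c(6, 0.5), c(3, 1), c(2, 2), c(22, 5)))
#' sched$n            # 33
#' max(sched$end)     # 120
#' @export
make_frame_schedule <- function(spec) {
  if (is.matrix(spec) || is.data.frame(spec)) {
    spec <- lapply(seq_len(nrow(spec)), function(i) as.numeric(spec[i, 1:2]))
  }
  if (!is.list(spec) || length(spec) == 0L) {
    stop("'spec' must be a non-empty list of (count, duration) pairs")
  }
  counts <- vapply(spec, function(p) as.numeric(p[[1]]), numeric(1))
  durs <- vapply(spec, function(p) as.numeric(p[[2]]), numeric(1))
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts))) {
    stop("frame counts must be positive integers")
  }
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("frame durations must be positive")
  }
  dur <- rep(durs, times = counts)
  end <- cumsum(dur)
  start <- c(0, end[-length(end)])
  new_frame_schedule(start, end)
}

new_frame_schedule <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) stop("empty schedule")
  if (abs(start[1]) > 1e-12) stop("schedule must start at time 0")
  if (any(end <= start)) stop("frame_end must exceed frame_start")
  if (length(start) > 1L) {
    if (any(diff(start) <= 0)) stop("frame starts must be strictly increasing")
    if (any(abs(start[-1] - end[-length(end)]) > 1e-9)) {
      stop("frames must be contiguous")
    }
  }
  structure(
    list(start = start, end = end, mid = (start + end) / 2,
         dur = end - start, n = length(start)),
    class = "frame_schedule"
  )
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule: %d frames, 0-%g min>\n", x$n, max(x$end)))
  invisible(x)
}

#' Reassemble a frame schedule from start/end vectors
#'
#' Used when reading TAC tables whose first two columns carry the frame
#' timing; validates the same invariants as \code{\link{make_frame_schedule}}.
#'
#' @param start,end Numeric vectors of frame start/end times in minutes.
#' @return A \code{frame_schedule}.
#' @export
frame_schedule_from_times <- function(start, end) {
  new_frame_schedule(as.numeric(start), as.numeric(end))
}

#' Default 33-frame, 120-min binning
#'
#' @return The frame specification list \code{list(c(6,0.5), c(3,1), c(2,2),
#'   c(22,5))} used as the simulator default.
#' @export
default_frame_spec <- function() {
  list(c(6, 0.5), c(3, 1), c(2, 2), c(22, 5))
}

#' Average a fine-grid curve over acquisition frames
#'
#' Computes, for each frame, the time average of a curve sampled on a regular
#' fine grid, via the trapezoidal cumulative integral (so frame boundaries
#' need not coincide with grid nodes).
#'
#' @param fine A \code{fine_tac} (see \code{\link{simulate_reference_tac}}) or
#'   a list with fields \code{t} and \code{y}.
#' @param schedule A \code{frame_schedule}; must be contained in the support
#'   of \code{fine}.
#' @return Numeric vector of per-frame averages.
#' @export
frame_average <- function(fine, schedule) {
  t <- fine$t; y <- fine$y
  if (max(schedule$end) > max(t) + 1e-9) {
    stop("schedule extends past the support of the fine-grid curve")
  }
  n <- length(t)
  # cumulative trapezoid of y over t
  cum <- c(0, cumsum(0.5 * (y[-1] + y[-n]) * diff(t)))
  F <- stats::approxfun(t, cum, rule = 2)
  (F(schedule$end) - F(schedule$start)) / schedule$dur
}
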