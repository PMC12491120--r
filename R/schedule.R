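#' Build a dynamic PET frame schedule
#'
#' A frame schedule lists, for each reconstructed timeframe, its start time
#' and duration in seconds post-injection. Frames must be contiguous: each
#' frame starts where the previous one ends, with the first frame at t = 0.
#'
#' @param durations_s Numeric vector of frame durations in seconds (all > 0).
#' @return A tibble with columns `frame`, `start_s`, `dur_s`.
#' @examples
#' frame_schedule(c(rep(20, 3), rep(60, 2)))
#' @export
frame_schedule <- function(durations_s) {
  durations_s <- as.numeric(durations_s)
  if (length(durations_s) < 1 || any(!is.finite(durations_s)) || any(durations_s <= 0)) {
    abort("All frame durations must be finite and > 0.")
  }
  tibble(
    frame = seq_along(durations_s),
    start_s = cumsum(c(0, durations_s[-length(durations_s)])),
    dur_s = durations_s
  )
}

#' The 55-frame dynamic acquisition schedule
#'
#' The list-mode reconstruction used throughout this package's default
#' simulations: 15 frames of 20 s, 15 frames of 40 s and 25 frames of 60 s,
#' covering 0--40 minutes post-injection (2400 s total).
#'
#' @return A 55-row frame schedule tibble.
#' @export
schedule_paper55 <- function() {
  frame_schedule(c(rep(20, 15), rep(40, 15), rep(60, 25)))
}

#' Validate a frame schedule
#'
#' Checks positivity of durations, strictly increasing start times, and
#' contiguity (no gaps or overlaps between frames). Gaps are rejected rather
#' than interpolated.
#'
#' @param schedule A frame schedule tibble (`start_s`, `dur_s`).
#' @return The schedule, invisibly, if valid; otherwise an error.
#' @export
validate_schedule <- function(schedule) {
  if (!is.data.frame(schedule) || !all(c("start_s", "dur_s") %in% names(schedule))) {
    abort("`schedule` must be a data frame with columns `start_s` and `dur_s`.")
  }
  if (any(schedule$dur_s <= 0)) abort("Frame durations must all be > 0.")
  n <- nrow(schedule)
  if (n > 1 && any(diff(schedule$start_s) <= 0)) {
    abort("Frame start times must be strictly increasing.")
  }
  ends <- schedule$start_s + schedule$dur_s
  if (n > 1 && any(abs(schedule$start_s[-1] - ends[-n]) > 1e-9)) {
    abort("Frame schedule is not contiguous: each frame must start where the previous ends.")
  }
  invisible(schedule)
}

## frame mid-times in minutes
frame_mid_min <- function(schedule) (schedule$start_s + schedule$dur_s / 2) / 60

## frame durations in minutes
frame_dur_min <- function(schedule) schedule$dur_s / 60
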