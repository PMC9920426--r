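## Sliding-window extraction and Fall/ADL labeling against the manually
## delimited actual-fall interval.

#' Window extraction specification
#'
#' Windows are half-open intervals `[start, start + window_s)` taken every
#' `jump_s` seconds from time 0 until the last window that still fits in the
#' file; the actual-fall interval is treated as closed.
#'
#' @param window_s window size in seconds (the study grid uses 5..9 s).
#' @param jump_s stride between consecutive window starts (default 1 s).
#' @return a `window_spec` list.
#' @export
window_spec <- function(window_s = 9, jump_s = 1) {
  if (window_s <= 0 || jump_s <= 0) stop("window_spec: sizes must be positive", call. = FALSE)
  structure(list(window_s = window_s, jump_s = jump_s), class = "window_spec")
}

#' Label one window against an actual-fall interval
#'
#' A window from an ADL file (no fall interval) is always an ADL.  A window
#' from a fall file is a Fall if and only if it overlaps at least 50% of the
#' actual fall, i.e. `overlap >= 0.5 * (b - a)`; ties (exactly 50%) count as
#' Fall.  The threshold is measured against the fall duration, not the
#' window.
#'
#' @param start,end window bounds (half-open `[start, end)`).
#' @param fall `NULL` or closed interval `c(a, b)`.
#' @return `"Fall"` or `"ADL"`.
#' @export
label_window <- function(start, end, fall = NULL) {
  if (is.null(fall)) {
    return(LABEL_ADL)
  }
  ov <- min(end, fall[2]) - max(start, fall[1])
  if (ov >= 0.5 * (fall[2] - fall[1])) LABEL_FALL else LABEL_ADL
}

#' Number of windows that fit in a file
#'
#' Closed form `floor((duration - window_s) / jump_s) + 1`, or 0 when the
#' file is shorter than one window.  A small tolerance absorbs floating-point
#' representation of durations such as 16.5 s.
#'
#' @param duration file duration in seconds.
#' @param spec a [window_spec()].
#' @return integer window count.
#' @export
count_windows <- function(duration, spec = window_spec()) {
  if (duration < spec$window_s) {
    return(0L)
  }
  as.integer(floor((duration - spec$window_s) / spec$jump_s + 1e-9) + 1)
}

#' Extract labeled sliding windows from a recording
#'
#' Window starts are `0, jump_s, 2 jump_s, ...` while
#' `start + window_s <= duration`; each window is labeled with
#' [label_window()].  Samples after the last full window are discarded.
#'
#' @param rec a `fall_recording`.
#' @param spec a [window_spec()].
#' @return data.frame with columns `start`, `end`, `label` and
#'   `samples_per_sensor` (sample count per sensor at the recording rate,
#'   e.g. 450 for a 9 s window at 50 Hz); zero rows (with a warning) if the
#'   file is shorter than one window.
#' @export
extract_windows <- function(rec, spec = window_spec()) {
  stopifnot(inherits(rec, "fall_recording"))
  dur <- rec$duration_s
  n <- count_windows(dur, spec)
  if (n == 0) {
    warning(sprintf(
      "recording %s/%s trial %d (%.2f s) shorter than %.2f s window; no windows",
      rec$activity, rec$user_id, rec$trial, dur, spec$window_s
    ), call. = FALSE)
    return(data.frame(
      start = numeric(0), end = numeric(0),
      label = character(0), samples_per_sensor = integer(0)
    ))
  }
  starts <- (seq_len(n) - 1) * spec$jump_s
  labels <- vapply(starts, function(s) {
    label_window(s, s + spec$window_s, rec$actual_fall)
  }, character(1))
  rate <- trace_rate(rec$traces[[1]])
  data.frame(
    start = starts, end = starts + spec$window_s, label = labels,
    samples_per_sensor = as.integer(round(spec$window_s * rate))
  )
}

## Sample indices of window [t, t+w): i such that t*f <= i < (t+w)*f
## (0-based sample i sits at time i/f), giving exactly 450 samples at
## (9 s, 50 Hz).
window_sample_index <- function(start, end, rate) {
  i0 <- ceiling(start * rate - 1e-9)
  i1 <- ceiling(end * rate - 1e-9) - 1
  seq.int(i0, i1) + 1L # 1-based rows
}
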