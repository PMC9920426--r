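## Frequency reduction, rolling-median filtering, vertical-acceleration
## projection, and the quaternion helpers shared with the synthetic generator.

#' Quaternion rotation of 3-vectors
#'
#' Rotates body-frame vectors into the world frame using unit quaternions in
#' scalar-first order `(qw, qx, qy, qz)`.  This is the single place in the
#' package where the quaternion convention is fixed.
#'
#' @param q numeric length-4 quaternion, or an n x 4 matrix of quaternions.
#' @param v numeric length-3 vector, or an n x 3 matrix of vectors.
#' @return rotated vector(s), same shape as `v`.
#' @export
quat_rotate <- function(q, v) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (is.null(dim(v))) {
    single <- TRUE
    v <- matrix(v, nrow = 1)
  } else {
    single <- FALSE
  }
  if (nrow(q) == 1 && nrow(v) > 1) q <- q[rep(1, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1 && nrow(q) > 1) v <- v[rep(1, nrow(q)), , drop = FALSE]
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  # v' = v + 2 q_vec x (q_vec x v + w v)
  tx <- y * vz - z * vy + w * vx
  ty <- z * vx - x * vz + w * vy
  tz <- x * vy - y * vx + w * vz
  out <- cbind(
    vx + 2 * (y * tz - z * ty),
    vy + 2 * (z * tx - x * tz),
    vz + 2 * (x * ty - y * tx)
  )
  if (single && nrow(out) == 1) as.numeric(out) else out
}

quat_conjugate <- function(q) {
  if (is.null(dim(q))) c(q[1], -q[2], -q[3], -q[4]) else cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}

#' Axis-angle quaternion(s)
#' @param axis unit 3-vector.
#' @param angle rotation angle(s) in radians.
#' @return n x 4 matrix of scalar-first quaternions.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  cbind(cos(angle / 2), sin(angle / 2) %o% axis)
}

#' Reduce a trace to a lower sampling rate
#'
#' Produces a uniform grid at `target_hz` spanning the trace duration, with
#' values obtained by linear interpolation (`method = "linear"`, the default)
#' or by per-segment medians (`method = "median"`, an anti-aliasing
#' alternative for sensitivity checks).  Linear interpolation introduces no
#' new extrema beyond the source min/max per axis and handles non-integer
#' rate ratios such as 50 to 40 Hz.  Upsampling is refused: no new data can
#' be acquired by resampling.
#'
#' @param trace a `sensor_trace`.
#' @param target_hz target rate in Hz (must not exceed the source rate).
#' @param method `"linear"` or `"median"`.
#' @return a `sensor_trace` at `target_hz`.
#' @export
resample <- function(trace, target_hz, method = c("linear", "median")) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "sensor_trace"))
  if (nrow(trace) == 0) stop("resample: empty trace", call. = FALSE)
  src <- trace_rate(trace)
  if (target_hz <= 0) stop("resample: target rate must be positive", call. = FALSE)
  if (target_hz > src + 1e-9) {
    stop("resample: target rate ", target_hz, " Hz exceeds source rate ", src, " Hz", call. = FALSE)
  }
  dur <- trace_duration(trace)
  n_out <- max(1L, round(dur * target_hz))
  t_out <- (seq_len(n_out) - 1) / target_hz
  cols <- setdiff(names(trace), "t")
  out <- data.frame(t = t_out)
  for (col in cols) {
    v <- trace[[col]]
    if (nrow(trace) == 1) {
      out[[col]] <- rep(v, n_out)
    } else if (method == "linear") {
      out[[col]] <- stats::approx(trace$t, v, xout = t_out, rule = 2)$y
    } else {
      edges <- c(t_out, dur)
      seg <- findInterval(trace$t, edges, rightmost.closed = FALSE)
      seg[seg < 1] <- 1
      seg[seg > n_out] <- n_out
      med <- tapply(v, factor(seg, levels = seq_len(n_out)), stats::median)
      filled <- as.numeric(med)
      # empty segments fall back to interpolation of the source
      empty <- is.na(filled)
      if (any(empty)) {
        filled[empty] <- stats::approx(trace$t, v, xout = t_out[empty], rule = 2)$y
      }
      out[[col]] <- filled
    }
  }
  sensor_trace(trace_sensor(trace), out, target_hz)
}

#' Rolling median filter
#'
#' Per-axis centre-aligned sliding median: for every `window` consecutive
#' values the centre value becomes the median of the window.  Edge samples
#' with insufficient neighbours keep their original values, so the trace
#' length is unchanged.
#'
#' @param trace a `sensor_trace`.
#' @param window odd integer window length (default 5).
#' @return filtered `sensor_trace` of identical length.
#' @export
median_filter <- function(trace, window = 5) {
  stopifnot(inherits(trace, "sensor_trace"))
  if (window %% 2 == 0 || window < 3) {
    stop("median_filter: window must be an odd integer >= 3", call. = FALSE)
  }
  out <- trace
  cols <- setdiff(names(trace), "t")
  if (nrow(trace) >= window) {
    for (col in cols) {
      out[[col]] <- as.numeric(stats::runmed(trace[[col]], k = window, endrule = "keep"))
    }
  }
  sensor_trace(trace_sensor(trace), as.data.frame(out), trace_rate(trace))
}

#' Vertical acceleration
#'
#' Rotates body-frame accelerometer readings into the world frame using the
#' orientation stream and returns the world z-component: the acceleration
#' projected on the vertically upward vector, which at rest is aligned with
#' (and opposite to) gravity.  Orientation quaternions are linearly
#' interpolated to the accelerometer timestamps and renormalised.
#'
#' @param accel accelerometer `sensor_trace`.
#' @param orientation orientation `sensor_trace` (unit quaternions; a norm
#'   deviating from 1 by more than `tol` is rejected).
#' @param tol unit-norm tolerance (default 1e-6 on the squared norm).
#' @return a single-axis `sensor_trace` (columns `t, x, y, z` with the
#'   vertical projection in `z` and zeros in `x, y`), at the accelerometer
#'   rate.
#' @export
vertical_acceleration <- function(accel, orientation, tol = 1e-6) {
  stopifnot(trace_sensor(accel) == "accelerometer", trace_sensor(orientation) == "orientation")
  qm <- as.matrix(orientation[c("qw", "qx", "qy", "qz")])
  norms <- rowSums(qm^2)
  if (any(abs(norms - 1) > tol)) {
    stop("vertical_acceleration: non-unit quaternion in orientation trace", call. = FALSE)
  }
  if (nrow(orientation) == 1) {
    qi <- qm[rep(1, nrow(accel)), , drop = FALSE]
  } else {
    qi <- vapply(
      1:4,
      function(j) stats::approx(orientation$t, qm[, j], xout = accel$t, rule = 2)$y,
      numeric(nrow(accel))
    )
    qi <- qi / sqrt(rowSums(qi^2))
  }
  aw <- quat_rotate(qi, as.matrix(accel[c("x", "y", "z")]))
  out <- data.frame(t = accel$t, x = 0, y = 0, z = aw[, 3])
  sensor_trace("accelerometer", out, trace_rate(accel))
}

#' Apply preprocessing to a whole recording
#'
#' Convenience wrapper applying, in order: optional rolling-median filtering,
#' optional vertical-acceleration projection (replaces the accelerometer
#' trace by its vertical projection), and optional frequency reduction.
#'
#' @param rec a `fall_recording`.
#' @param target_hz target rate, or `NULL` to keep the source rate.
#' @param median_window odd window for [median_filter()], or `NULL` to skip.
#' @param vertical if `TRUE`, replace the accelerometer trace by its
#'   vertical projection (requires an orientation trace).
#' @return the preprocessed `fall_recording`.
#' @export
preprocess_recording <- function(rec, target_hz = NULL, median_window = NULL,
                                 vertical = FALSE) {
  traces <- rec$traces
  if (!is.null(median_window)) {
    traces <- lapply(traces, median_filter, window = median_window)
  }
  if (vertical) {
    if (is.null(traces$accelerometer) || is.null(traces$orientation)) {
      stop("preprocess_recording: vertical projection needs accelerometer and orientation traces",
        call. = FALSE
      )
    }
    traces$accelerometer <- vertical_acceleration(traces$accelerometer, traces$orientation)
  }
  if (!is.null(target_hz)) {
    traces <- lapply(traces, function(tr) {
      if (target_hz < trace_rate(tr)) resample(tr, target_hz) else tr
    })
  }
  recording(rec$user_id, rec$cohort, rec$activity, rec$trial, traces, rec$actual_fall)
}
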