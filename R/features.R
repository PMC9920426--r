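## FS-1 feature set: maximum, minimum, mean and (sample) variance per axis
## per sensor -- batch over a window, and streaming one reading at a time via
## recursive updates suitable for a device that cannot store the window.

STATS <- c("max", "min", "mean", "var")

sensor_abbrev <- c(accelerometer = "accel", gyroscope = "gyro", orientation = "orient")

#' Feature pool for a sensor selection
#'
#' A pool element is a (sensor, statistic) pair, applied jointly to the x, y
#' and z axes; the full three-sensor FS-1 pool has 4 statistics x 3 sensors =
#' 12 elements, the accelerometer-only pool has 4.
#'
#' @param sensors character vector of sensors.
#' @return character vector like `"accel_max"`, `"gyro_var"`, ...
#' @export
feature_pool <- function(sensors = SENSORS) {
  sensors <- match.arg(sensors, SENSORS, several.ok = TRUE)
  as.vector(t(outer(sensor_abbrev[sensors], STATS, paste, sep = "_")))
}

#' Feature column names for a (sensor, statistic) subset
#' @param pool_elements elements of [feature_pool()].
#' @return column names `<sensor>_<stat>_<axis>` over axes x, y, z.
#' @export
feature_columns <- function(pool_elements) {
  as.vector(t(outer(pool_elements, c("x", "y", "z"), paste, sep = "_")))
}

axis_stats_vector <- function(v) {
  n <- length(v)
  c(
    max = max(v), min = min(v), mean = sum(v) / n,
    var = if (n < 2) 0 else stats::var(v)
  )
}

#' Batch FS-1 features over a window of samples
#'
#' Exact maximum, minimum, arithmetic mean and sample variance (N-1
#' denominator) per axis.
#'
#' @param samples numeric matrix with one column per axis (x, y, z); for the
#'   orientation sensor the quaternion vector part is used as the three axes.
#' @param sensor sensor name, used to prefix the feature names.
#' @return named numeric vector `<sensor>_<stat>_<axis>`.
#' @export
batch_features <- function(samples, sensor = "accelerometer") {
  samples <- as.matrix(samples)
  if (nrow(samples) == 0) stop("batch_features: empty window", call. = FALSE)
  ab <- sensor_abbrev[[match.arg(sensor, SENSORS)]]
  axes <- c("x", "y", "z")
  out <- numeric(0)
  for (j in seq_len(ncol(samples))) {
    s <- axis_stats_vector(samples[, j])
    names(s) <- paste(ab, STATS, axes[j], sep = "_")
    out <- c(out, s)
  }
  out[order(match(sub("_[xyz]$", "", names(out)), paste(ab, STATS, sep = "_")))]
}

#' Create an empty streaming-statistics state
#'
#' Holds, per axis, the reading counter N and the running maximum, minimum,
#' mean and sample variance, updated recursively as each new sensor reading
#' arrives (no window buffer is kept).  With N = 0 the state is empty; with
#' N = 1 the variance is 0.
#'
#' @param n_axes number of axes (default 3).
#' @return a `stream_state`.
#' @export
stream_state <- function(n_axes = 3) {
  structure(
    list(
      n = 0L,
      max = rep(NA_real_, n_axes), min = rep(NA_real_, n_axes),
      mean = rep(NA_real_, n_axes), var = rep(NA_real_, n_axes)
    ),
    class = "stream_state"
  )
}

#' Update streaming statistics with one reading
#'
#' Recursive updates, per axis: the maximum and minimum replace-or-keep; the
#' mean moves by `(new_reading - previous_mean) / N` with N the count
#' including the new reading; the running sample variance absorbs
#' `(new_reading - previous_mean) * (new_reading - new_mean)` scaled by
#' `N - 1`, staying exactly equal to the batch N-1-denominator variance at
#' every step (0 while N <= 1).
#'
#' @param state a `stream_state`.
#' @param reading numeric vector, one value per axis.
#' @return the updated `stream_state`.
#' @export
stream_update <- function(state, reading) {
  stopifnot(inherits(state, "stream_state"))
  reading <- as.numeric(reading)
  if (length(reading) != length(state$max)) {
    stop("stream_update: reading has ", length(reading), " axes, state has ",
      length(state$max),
      call. = FALSE
    )
  }
  if (any(!is.finite(reading))) stop("stream_update: non-finite reading rejected", call. = FALSE)
  if (state$n == 0L) {
    state$max <- reading
    state$min <- reading
    state$mean <- reading
    state$var <- rep(0, length(reading))
    state$n <- 1L
    return(state)
  }
  n_new <- state$n + 1L
  prev_mean <- state$mean
  state$max <- pmax(state$max, reading)
  state$min <- pmin(state$min, reading)
  state$mean <- prev_mean + (reading - prev_mean) / n_new
  state$var <- state$var +
    ((reading - prev_mean) * (reading - state$mean) - state$var) / (n_new - 1L)
  state$n <- n_new
  state
}

#' Finalize a streaming window into a feature vector
#'
#' Returns the FS-1 feature vector accumulated so far together with a reset
#' (empty) state for the next window.  Finalizing an empty state is an error.
#'
#' @param state a `stream_state` with at least one reading.
#' @param sensor sensor name used to prefix feature names.
#' @return list with `features` (named numeric vector, same layout as
#'   [batch_features()]) and `state` (fresh empty `stream_state`).
#' @export
stream_finalize <- function(state, sensor = "accelerometer") {
  stopifnot(inherits(state, "stream_state"))
  if (state$n == 0L) stop("stream_finalize: no data in window", call. = FALSE)
  ab <- sensor_abbrev[[match.arg(sensor, SENSORS)]]
  axes <- c("x", "y", "z")[seq_along(state$max)]
  vals <- rbind(max = state$max, min = state$min, mean = state$mean, var = state$var)
  features <- as.vector(vals)
  names(features) <- as.vector(outer(STATS, axes, function(s, a) paste(ab, s, a, sep = "_")))
  # reorder to match batch_features layout (stat-major within sensor)
  features <- features[as.vector(t(outer(paste(ab, STATS, sep = "_"), axes, paste, sep = "_")))]
  list(features = features, state = stream_state(length(state$max)))
}

## ---------------------------------------------------------------------------
## Feature tables: the offline pipeline's tabular interface

#' Compute the labeled feature table of a set of recordings
#'
#' Runs the offline pipeline: optional frequency reduction, sliding-window
#' extraction with overlap labeling, and batch FS-1 features per window and
#' sensor.  Columns are `<sensor>_<stat>_<axis>` (orientation uses the
#' quaternion vector part qx, qy, qz as its three axes) plus `label`,
#' `user_id`, `cohort`, `activity`, `trial`, `start`.
#'
#' @param recordings list of `fall_recording`.
#' @param spec a [window_spec()].
#' @param sensors sensors to include (default accelerometer only, the
#'   deployed configuration).
#' @param target_hz optional reduced rate; `NULL` keeps the source rate.
#' @param median_window optional odd window for [median_filter()].
#' @param vertical if `TRUE`, project the accelerometer onto the vertical
#'   axis before computing features.
#' @return data.frame feature table.
#' @export
feature_table <- function(recordings, spec = window_spec(),
                          sensors = "accelerometer", target_hz = NULL,
                          median_window = NULL, vertical = FALSE) {
  sensors <- match.arg(sensors, SENSORS, several.ok = TRUE)
  rows <- lapply(recordings, function(rec) {
    if (!is.null(median_window) || vertical || !is.null(target_hz)) {
      rec <- preprocess_recording(rec,
        target_hz = target_hz,
        median_window = median_window, vertical = vertical
      )
    }
    wins <- suppressWarnings(extract_windows(rec, spec))
    if (nrow(wins) == 0) {
      return(NULL)
    }
    mats <- lapply(sensors, function(s) {
      tr <- rec$traces[[s]]
      if (is.null(tr)) stop("feature_table: recording lacks sensor ", s, call. = FALSE)
      list(m = as.matrix(tr[axis_columns(s)]), rate = trace_rate(tr))
    })
    names(mats) <- sensors
    feats <- lapply(seq_len(nrow(wins)), function(i) {
      unlist(lapply(sensors, function(s) {
        idx <- window_sample_index(wins$start[i], wins$end[i], mats[[s]]$rate)
        idx <- idx[idx <= nrow(mats[[s]]$m)]
        batch_features(mats[[s]]$m[idx, , drop = FALSE], sensor = s)
      }), use.names = TRUE)
    })
    cbind(
      as.data.frame(do.call(rbind, feats)),
      label = wins$label, user_id = rec$user_id, cohort = rec$cohort,
      activity = rec$activity, trial = rec$trial, start = wins$start,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    stop("feature_table: no recording long enough for the window size", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Metadata (non-feature) columns of a feature table
#' @export
META_COLUMNS <- c("label", "user_id", "cohort", "activity", "trial", "start")

feature_matrix <- function(table, columns = NULL) {
  cols <- setdiff(names(table), META_COLUMNS)
  if (!is.null(columns)) {
    missing <- setdiff(columns, cols)
    if (length(missing) > 0) {
      stop("feature columns absent from table: ", paste(missing, collapse = ","), call. = FALSE)
    }
    cols <- columns
  }
  as.matrix(table[cols])
}
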