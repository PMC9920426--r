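#' @keywords internal
"_PACKAGE"

## Label constants used throughout: Fall is the positive class.
LABEL_FALL <- "Fall"
LABEL_ADL <- "ADL"

FALL_CODES <- sprintf("F%02d", 1:8)
ADL_CODES <- sprintf("D%02d", 1:11)

SENSORS <- c("accelerometer", "gyroscope", "orientation")

#' Standard gravity (m/s^2)
#'
#' Magnitude of the gravity vector assumed by the synthetic generator and the
#' vertical-acceleration projection.
#' @export
GRAVITY <- 9.80665

#' Construct a sensor trace
#'
#' A sensor trace is a time-ordered table of readings from one sensor.
#' Accelerometer (m/s^2) and gyroscope (rad/s) traces have columns
#' `t, x, y, z`; orientation traces hold a unit quaternion per row with
#' columns `t, qw, qx, qy, qz` (scalar-first convention).
#'
#' @param sensor one of `"accelerometer"`, `"gyroscope"`, `"orientation"`.
#' @param data data.frame with column `t` (seconds from recording start,
#'   non-decreasing) plus `x,y,z` or `qw,qx,qy,qz`.
#' @param rate_hz nominal sampling rate in Hz.
#' @return a `sensor_trace`: the data.frame with attributes `sensor` and
#'   `rate_hz`.
#' @export
sensor_trace <- function(sensor, data, rate_hz) {
  sensor <- match.arg(sensor, SENSORS)
  cols <- if (sensor == "orientation") c("t", "qw", "qx", "qy", "qz") else c("t", "x", "y", "z")
  if (!all(cols %in% names(data))) {
    stop("sensor_trace: expected columns ", paste(cols, collapse = ","), call. = FALSE)
  }
  data <- as.data.frame(data)[cols]
  rownames(data) <- NULL
  if (nrow(data) > 0) {
    if (any(!is.finite(as.matrix(data)))) {
      stop("sensor_trace: non-finite values in trace", call. = FALSE)
    }
    if (is.unsorted(data$t)) stop("sensor_trace: timestamps must be non-decreasing", call. = FALSE)
    if (any(data$t < 0)) stop("sensor_trace: negative timestamps", call. = FALSE)
  }
  structure(data,
    sensor = sensor, rate_hz = rate_hz,
    class = c("sensor_trace", "data.frame")
  )
}

trace_sensor <- function(trace) attr(trace, "sensor")

#' Sampling rate of a trace
#' @param trace a `sensor_trace`.
#' @return nominal rate in Hz.
#' @export
trace_rate <- function(trace) attr(trace, "rate_hz")

#' Duration covered by a trace in seconds (sample count / rate, so that a
#' 16.5 s trace at 50 Hz holds exactly 825 samples).
#' @param trace a `sensor_trace`.
#' @export
trace_duration <- function(trace) nrow(trace) / trace_rate(trace)

axis_columns <- function(sensor) {
  if (sensor == "orientation") c("qx", "qy", "qz") else c("x", "y", "z")
}

#' Construct a recording (one activity trial)
#'
#' A recording bundles the per-sensor traces of one trial of one activity by
#' one participant.  Fall recordings (codes F01..F08) carry an `actual_fall`
#' interval: the manually delimited sub-interval, averaging about 3.1 s,
#' containing the fall's four phases (prefall, impact, adjustment, postfall).
#' ADL recordings (D01..D11) never carry one.
#'
#' @param user_id participant identifier.
#' @param cohort `"YP"` (young participants) or `"EP"` (elder participants).
#' @param activity activity code, `F01`..`F08` or `D01`..`D11`.
#' @param trial repetition index (1-based).
#' @param traces named list of `sensor_trace` objects keyed by sensor.
#' @param actual_fall `NULL`, or closed interval `c(start, end)` in seconds.
#' @return an object of class `fall_recording`.
#' @export
recording <- function(user_id, cohort = c("YP", "EP"), activity, trial,
                      traces, actual_fall = NULL) {
  cohort <- match.arg(cohort)
  if (!activity %in% c(FALL_CODES, ADL_CODES)) {
    stop("recording: unknown activity code '", activity, "'", call. = FALSE)
  }
  if (!is.list(traces) || length(traces) == 0) {
    stop("recording: at least one sensor trace required", call. = FALSE)
  }
  dur <- max(vapply(traces, trace_duration, numeric(1)))
  is_fall <- activity %in% FALL_CODES
  if (is_fall) {
    if (is.null(actual_fall)) {
      stop("recording: fall recordings must carry an actual_fall interval", call. = FALSE)
    }
    if (length(actual_fall) != 2 || actual_fall[1] < 0 ||
      actual_fall[1] >= actual_fall[2] || actual_fall[2] > dur) {
      stop("recording: actual_fall must satisfy 0 <= a < b <= duration", call. = FALSE)
    }
  } else if (!is.null(actual_fall)) {
    stop("recording: ADL recordings must not carry an actual_fall interval", call. = FALSE)
  }
  structure(
    list(
      user_id = user_id, cohort = cohort, activity = activity,
      trial = as.integer(trial), traces = traces,
      actual_fall = if (is_fall) as.numeric(actual_fall) else NULL,
      duration_s = dur
    ),
    class = "fall_recording"
  )
}

#' @export
print.fall_recording <- function(x, ...) {
  cat(sprintf(
    "<fall_recording> %s user %s (%s) trial %d: %.2f s, sensors: %s\n",
    x$activity, x$user_id, x$cohort, x$trial, x$duration_s,
    paste(names(x$traces), collapse = ", ")
  ))
  if (!is.null(x$actual_fall)) {
    cat(sprintf("  actual fall: [%.3f, %.3f] s\n", x$actual_fall[1], x$actual_fall[2]))
  }
  invisible(x)
}

#' Is a recording a fall trial?
#' @param rec a `fall_recording`.
#' @export
is_fall_recording <- function(rec) rec$activity %in% FALL_CODES

## ---------------------------------------------------------------------------
## Acquisition protocol bookkeeping

#' Define an acquisition protocol
#'
#' A protocol is a table with one row per (participant, activity) stating how
#' many repetitions that participant performs.
#'
#' @param participants data.frame with columns `user_id`, `cohort`,
#'   `activity`, `reps`.
#' @return a `fall_protocol` data.frame.
#' @export
protocol <- function(participants) {
  req <- c("user_id", "cohort", "activity", "reps")
  if (!all(req %in% names(participants))) {
    stop("protocol: need columns ", paste(req, collapse = ","), call. = FALSE)
  }
  bad <- setdiff(unique(participants$activity), c(FALL_CODES, ADL_CODES))
  if (length(bad) > 0) {
    stop("protocol: unknown activity code(s): ", paste(bad, collapse = ","), call. = FALSE)
  }
  if (any(participants$reps < 0)) stop("protocol: negative repetition count", call. = FALSE)
  structure(as.data.frame(participants), class = c("fall_protocol", "data.frame"))
}

#' Young-participant acquisition protocol
#'
#' 14 young participants each perform falls F01..F08 and ADLs D01..D11 three
#' times, except the lateral sitting fall F08 which is performed four times
#' (twice towards the watch side, twice away), totalling 350 fall and 462 ADL
#' signals.
#'
#' @param n_users number of participants (default 14).
#' @return a `fall_protocol`.
#' @export
yp_protocol <- function(n_users = 14) {
  acts <- c(FALL_CODES, ADL_CODES)
  grid <- expand.grid(
    user_id = if (n_users > 0) paste0("U", seq_len(n_users)) else character(0),
    activity = acts, stringsAsFactors = FALSE
  )
  grid$cohort <- rep("YP", nrow(grid))
  grid$reps <- rep(ifelse(grid$activity == "F08", 4L, 3L), length.out = nrow(grid))
  protocol(grid[c("user_id", "cohort", "activity", "reps")])
}

#' Elder-participant acquisition protocol
#'
#' 11 elder participants perform a safe subset of the ADLs (walking, stairs
#' where able, sit/stand, hitting a table, clapping, opening a door); no
#' falls.  The published total of 157 elder signals reflects repetition
#' counts that varied with each volunteer's mobility and fatigue; it is
#' metadata of the real acquisition, not recomputable from this protocol.
#' The synthetic default uses `reps` repetitions per activity.
#'
#' @param reps repetitions per (participant, activity) for synthesis
#'   (default 2).
#' @return a `fall_protocol` with attribute `reported_total_signals = 157`.
#' @export
ep_protocol <- function(reps = 2) {
  ep_acts <- list(
    U21 = c("D01", "D04", "D09", "D10", "D11"),
    U22 = c("D01", "D04", "D09", "D10", "D11"),
    U23 = c("D01", "D03", "D04", "D09", "D10", "D11"),
    U24 = c("D01", "D03", "D04", "D09", "D10", "D11"),
    U25 = c("D01", "D04", "D09", "D10", "D11"),
    U26 = c("D01", "D03", "D04", "D09", "D10", "D11"),
    U27 = c("D01", "D03", "D04", "D09", "D10", "D11"),
    U28 = c("D01", "D03", "D04", "D09", "D10", "D11"),
    U29 = c("D01", "D03", "D04", "D09", "D10", "D11"),
    U30 = c("D01", "D03", "D04", "D09", "D10", "D11"),
    U31 = c("D01", "D03", "D04", "D09", "D10", "D11")
  )
  df <- do.call(rbind, lapply(names(ep_acts), function(u) {
    data.frame(
      user_id = u, cohort = "EP", activity = ep_acts[[u]],
      reps = as.integer(reps), stringsAsFactors = FALSE
    )
  }))
  p <- protocol(df)
  attr(p, "reported_total_signals") <- 157L
  p
}

#' Expected signal counts under a protocol
#'
#' Fall count = sum over participants of (fall activities x repetitions);
#' ADL count analogous.  For the standard young-participant protocol this
#' gives 350 = 14 x 7 x 3 + 14 x 4 falls and 462 = 14 x 11 x 3 ADLs.
#'
#' @param prot a `fall_protocol`.
#' @return list with `falls` and `adls` (integer totals) and `by_cohort`
#'   (data.frame of per-cohort totals).
#' @export
expected_signal_counts <- function(prot) {
  stopifnot(inherits(prot, "fall_protocol"))
  if (nrow(prot) == 0) {
    return(list(
      falls = 0L, adls = 0L,
      by_cohort = data.frame(cohort = character(0), falls = integer(0), adls = integer(0))
    ))
  }
  is_fall <- prot$activity %in% FALL_CODES
  by <- aggregate(
    cbind(
      falls = ifelse(is_fall, prot$reps, 0L),
      adls = ifelse(is_fall, 0L, prot$reps)
    ),
    by = list(cohort = prot$cohort), FUN = sum
  )
  list(
    falls = as.integer(sum(prot$reps[is_fall])),
    adls = as.integer(sum(prot$reps[!is_fall])),
    by_cohort = by
  )
}

## ---------------------------------------------------------------------------
## CSV I/O

#' Default file layout for recording directories
#'
#' One CSV per sensor per trial with header `t,x,y,z` (orientation:
#' `t,qw,qx,qy,qz`), '.' decimal separator, plus a flat key-value sidecar
#' `meta.txt` holding user, cohort, activity, trial and the manually labeled
#' actual-fall interval.  A layout descriptor can rename files and columns to
#' absorb alternative column namings of public dataset mirrors.
#'
#' @param files named character vector mapping sensor to CSV file name.
#' @param columns named list mapping sensor to its column-name vector
#'   (time column first).
#' @param meta_file sidecar file name.
#' @return a layout descriptor list.
#' @export
default_layout <- function(files = c(
                             accelerometer = "accelerometer.csv",
                             gyroscope = "gyroscope.csv",
                             orientation = "orientation.csv"
                           ),
                           columns = list(
                             accelerometer = c("t", "x", "y", "z"),
                             gyroscope = c("t", "x", "y", "z"),
                             orientation = c("t", "qw", "qx", "qy", "qz")
                           ),
                           meta_file = "meta.txt") {
  list(files = files, columns = columns, meta_file = meta_file)
}

read_numeric_csv <- function(path, expected_cols) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (ncol(raw) != length(expected_cols)) {
    stop(sprintf(
      "%s: expected %d columns (%s), found %d", path,
      length(expected_cols), paste(expected_cols, collapse = ","), ncol(raw)
    ), call. = FALSE)
  }
  out <- vapply(raw, function(col) suppressWarnings(as.numeric(col)), numeric(nrow(raw)))
  out <- matrix(out, nrow = nrow(raw), ncol = length(expected_cols))
  colnames(out) <- expected_cols
  bad <- which(rowSums(is.na(out)) > 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: non-numeric value at data line %d", path, bad[1]
    ), call. = FALSE)
  }
  df <- as.data.frame(out)
  names(df) <- expected_cols
  df
}

infer_rate <- function(t) {
  if (length(t) < 2) {
    return(NA_real_)
  }
  gap <- stats::median(diff(t))
  if (gap <= 0) {
    return(NA_real_)
  }
  round(1 / gap, 6)
}

#' Read a recording from a directory
#'
#' Reads one CSV per sensor plus the metadata sidecar.  A missing sensor file
#' is recorded in the returned object's `missing_sensors` field rather than
#' raising an error; a malformed (non-numeric) cell raises a parse error
#' naming the file and line.
#'
#' @param path recording directory.
#' @param layout layout descriptor from [default_layout()].
#' @return a `fall_recording` (with `missing_sensors` attribute listing any
#'   sensors whose files were absent).
#' @export
read_recording <- function(path, layout = default_layout()) {
  if (!dir.exists(path)) stop("read_recording: no such directory: ", path, call. = FALSE)
  meta <- read_keyvalue(file.path(path, layout$meta_file))
  traces <- list()
  missing <- character(0)
  for (sensor in names(layout$files)) {
    f <- file.path(path, layout$files[[sensor]])
    if (!file.exists(f)) {
      missing <- c(missing, sensor)
      next
    }
    cols <- layout$columns[[sensor]]
    df <- read_numeric_csv(f, cols)
    # normalise to canonical column names
    names(df) <- if (sensor == "orientation") c("t", "qw", "qx", "qy", "qz") else c("t", "x", "y", "z")
    df <- df[order(df$t), , drop = FALSE]
    rownames(df) <- NULL
    rate <- if (!is.null(meta$rate_hz)) as.numeric(meta$rate_hz) else infer_rate(df$t)
    traces[[sensor]] <- sensor_trace(sensor, df, rate)
  }
  if (length(traces) == 0) stop("read_recording: no sensor files found in ", path, call. = FALSE)
  af <- NULL
  if (!is.null(meta$actual_fall_start)) {
    af <- c(as.numeric(meta$actual_fall_start), as.numeric(meta$actual_fall_end))
  }
  rec <- recording(
    user_id = meta$user_id, cohort = meta$cohort, activity = meta$activity,
    trial = as.integer(meta$trial), traces = traces, actual_fall = af
  )
  attr(rec, "missing_sensors") <- missing
  rec
}

#' Write a recording to a directory
#'
#' Writes one CSV per sensor (full double precision, so that re-reading
#' reproduces the recording exactly) and the key-value metadata sidecar, which
#' persists the actual-fall interval.
#'
#' @param rec a `fall_recording`.
#' @param path target directory (created if needed).
#' @param layout layout descriptor from [default_layout()].
#' @return invisibly, the vector of file paths written.
#' @export
write_recording <- function(rec, path, layout = default_layout()) {
  stopifnot(inherits(rec, "fall_recording"))
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE, showWarnings = FALSE)) {
    stop("write_recording: cannot create directory ", path, call. = FALSE)
  }
  written <- character(0)
  for (sensor in names(rec$traces)) {
    tr <- rec$traces[[sensor]]
    f <- file.path(path, layout$files[[sensor]])
    header <- paste(layout$columns[[sensor]], collapse = ",")
    if (nrow(tr) == 0) {
      lines <- header
    } else {
      body <- apply(as.matrix(tr), 1, function(row) {
        paste(sprintf("%.17g", row), collapse = ",")
      })
      lines <- c(header, body)
    }
    writeLines(lines, f)
    written <- c(written, f)
  }
  meta <- c(
    user_id = as.character(rec$user_id), cohort = rec$cohort,
    activity = rec$activity, trial = as.character(rec$trial)
  )
  rates <- vapply(rec$traces, trace_rate, numeric(1))
  if (length(unique(rates)) == 1) meta["rate_hz"] <- sprintf("%.17g", rates[[1]])
  if (!is.null(rec$actual_fall)) {
    meta["actual_fall_start"] <- sprintf("%.17g", rec$actual_fall[1])
    meta["actual_fall_end"] <- sprintf("%.17g", rec$actual_fall[2])
  }
  mf <- file.path(path, layout$meta_file)
  writeLines(paste0(names(meta), ": ", meta), mf)
  invisible(c(written, mf))
}

#' Write a list of recordings under a root directory
#'
#' Each recording goes to `<root>/<activity>_<user>_R<trial>/`.
#'
#' @param recs list of `fall_recording`.
#' @param root output directory.
#' @return invisibly, the recording directories written.
#' @export
write_recordings <- function(recs, root) {
  dirs <- vapply(recs, function(rec) {
    d <- file.path(root, sprintf("%s_%s_R%02d", rec$activity, rec$user_id, rec$trial))
    write_recording(rec, d)
    d
  }, character(1))
  invisible(dirs)
}

#' Read all recordings under a root directory
#' @param root directory containing recording sub-directories.
#' @param layout layout descriptor.
#' @return list of `fall_recording`.
#' @export
read_recordings <- function(root, layout = default_layout()) {
  if (!dir.exists(root)) stop("read_recordings: no such directory: ", root, call. = FALSE)
  dirs <- list.dirs(root, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, layout$meta_file))]
  lapply(dirs, read_recording, layout = layout)
}

read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("missing metadata sidecar: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  out <- lapply(kv, function(p) trimws(p[2]))
  names(out) <- vapply(kv, function(p) trimws(p[1]), character(1))
  out
}
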