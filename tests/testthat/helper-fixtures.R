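# Shared fixtures: built in code, small enough for fast unit tests.

# A minimal protocol: 2 users, one fall and two ADLs (one impulsive).
tiny_protocol <- function(users = 2, reps = 2) {
  protocol(expand.grid(
    user_id = paste0("U", seq_len(users)),
    cohort = "YP",
    activity = c("F01", "D01", "D10"),
    reps = as.integer(reps),
    stringsAsFactors = FALSE
  ))
}

# Cache expensive fixtures across test files within one run.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

tiny_dataset <- function() cached("tiny_dataset", generate_dataset(tiny_protocol(), seed = 404))
tiny_table <- function() cached("tiny_table", feature_table(tiny_dataset()))

# A recording with an exactly known duration and actual-fall interval.
synthetic_recording <- function(duration = 16.5, rate = 50, fall = c(7, 10),
                                activity = if (is.null(fall)) "D01" else "F01") {
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  mk <- function() data.frame(t = t, x = sin(t), y = cos(t), z = GRAVITY + 0.1 * sin(3 * t))
  recording(
    user_id = "U1", cohort = "YP", activity = activity, trial = 1L,
    traces = list(accelerometer = sensor_trace("accelerometer", mk(), rate)),
    actual_fall = fall
  )
}

# Idle 50 Hz stream of a given duration (for detector-cycle arithmetic).
idle_stream <- function(duration_s, rate = 50) {
  n <- round(duration_s * rate)
  structure(
    list(
      t = (seq_len(n) - 1) / rate,
      samples = cbind(rep(0, n), rep(0, n), rep(GRAVITY, n)),
      rate_hz = rate,
      fall_intervals = data.frame(start = numeric(0), end = numeric(0)),
      duration_s = n / rate
    ),
    class = "sensor_stream"
  )
}

# A small labeled dataset in the online-detector layout.
toy_points <- function(n_fall = 3, n_adl = 3, dim = 12) {
  set.seed(1)
  x <- rbind(
    matrix(rnorm(n_fall * dim, mean = 20), ncol = dim),
    matrix(rnorm(n_adl * dim, mean = 0), ncol = dim)
  )
  colnames(x) <- paste0("f", seq_len(dim))
  out <- as.data.frame(x)
  out$label <- c(rep("Fall", n_fall), rep("ADL", n_adl))
  out$provenance <- "seed-dataset"
  out$added <- seq_len(nrow(out))
  out
}

# Independent rotation-matrix oracle for quaternion rotation (scalar-first).
quat_matrix_oracle <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

random_unit_quaternion <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}
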