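## Seeded generator of fall and ADL recordings with the statistical structure
## the detection pipeline assumes: 50 Hz triaxial accelerometer, gyroscope and
## orientation streams; falls with four phases (prefall, impact, adjustment,
## postfall) whose manually-labelable span averages 3.1037 +/- 0.2731 s inside
## files of 8-16.5 s; ADLs in periodic, transitional, impulsive and
## quasi-static families, the impulsive ones (hitting a table, clapping)
## deliberately fall-confusable.

#' Fall shape parameters
#'
#' @param fall_duration_mean mean of the actual-fall duration (s).
#' @param fall_duration_sd standard deviation of the actual-fall duration (s).
#'   The duration is drawn from a Normal truncated below at 1.5 s.
#' @param impact_peak peak impact acceleration (m/s^2); must exceed gravity.
#' @param file_duration_range range (s) of the whole-file duration.
#' @param noise_sd additive Gaussian noise per accelerometer axis (m/s^2).
#' @param amp_scale overall movement amplitude multiplier (per-user jitter).
#' @param freq_scale overall movement frequency multiplier.
#' @return a `fall_shape_params` list.
#' @export
fall_shape_params <- function(fall_duration_mean = 3.1037,
                              fall_duration_sd = 0.2731,
                              impact_peak = 30,
                              file_duration_range = c(8, 16.5),
                              noise_sd = 0.3,
                              amp_scale = 1,
                              freq_scale = 1) {
  if (fall_duration_mean <= 0 || fall_duration_sd <= 0) {
    stop("fall durations must be positive", call. = FALSE)
  }
  if (any(file_duration_range <= 0) || diff(file_duration_range) < 0) {
    stop("file_duration_range must be positive and ordered", call. = FALSE)
  }
  if (impact_peak <= GRAVITY) {
    stop("impact_peak must exceed the gravity magnitude", call. = FALSE)
  }
  structure(
    list(
      fall_duration_mean = fall_duration_mean, fall_duration_sd = fall_duration_sd,
      impact_peak = impact_peak, file_duration_range = file_duration_range,
      noise_sd = noise_sd, amp_scale = amp_scale, freq_scale = freq_scale
    ),
    class = "fall_shape_params"
  )
}

#' ADL shape parameters
#'
#' @param class movement family: `"periodic"` (walking, jogging, stairs),
#'   `"transitional"` (sit/stand transfers), `"impulsive"` (hits, claps,
#'   jumps), or `"quasi-static"` (door handling).
#' @param fundamental_hz dominant movement frequency; capped at 20 Hz, the
#'   maximum frequency of human body movement.
#' @param amplitude movement amplitude (m/s^2).
#' @param duration_range range (s) of the file duration.
#' @param n_spikes number of impulsive spikes (impulsive class, or spike
#'   overlays such as a stumble).
#' @param spike_amp spike amplitude (m/s^2) for spike overlays.
#' @param noise_sd additive Gaussian noise per axis (m/s^2).
#' @param amp_scale,freq_scale per-user jitter multipliers.
#' @return an `adl_shape_params` list.
#' @export
adl_shape_params <- function(class = c("periodic", "transitional", "impulsive", "quasi-static"),
                             fundamental_hz = 2,
                             amplitude = 3,
                             duration_range = c(8, 16.5),
                             n_spikes = 0,
                             spike_amp = 0,
                             noise_sd = 0.3,
                             amp_scale = 1,
                             freq_scale = 1) {
  class <- match.arg(class)
  if (fundamental_hz <= 0 || fundamental_hz > 20) {
    stop("fundamental_hz must lie in (0, 20] Hz", call. = FALSE)
  }
  if (any(duration_range <= 0) || diff(duration_range) < 0) {
    stop("duration_range must be positive and ordered", call. = FALSE)
  }
  structure(
    list(
      class = class, fundamental_hz = fundamental_hz, amplitude = amplitude,
      duration_range = duration_range, n_spikes = n_spikes, spike_amp = spike_amp,
      noise_sd = noise_sd, amp_scale = amp_scale, freq_scale = freq_scale
    ),
    class = "adl_shape_params"
  )
}

#' Default shape parameters for each ADL code
#'
#' D01 walking, D02 jogging, D03 stairs (periodic); D04 sit/stand, D05
#' collapse into chair, D06 crouch (transitional); D07 stumble (walking with
#' one strong spike), D08 gentle jump, D09 hitting a table, D10 clapping
#' (impulsive); D11 opening/closing a door (quasi-static).
#'
#' @param code ADL code `D01`..`D11`.
#' @return an `adl_shape_params`.
#' @export
adl_defaults <- function(code) {
  switch(code,
    D01 = adl_shape_params("periodic", fundamental_hz = 2.0, amplitude = 3.0),
    D02 = adl_shape_params("periodic", fundamental_hz = 2.8, amplitude = 6.0),
    D03 = adl_shape_params("periodic", fundamental_hz = 1.7, amplitude = 4.0),
    D04 = adl_shape_params("transitional", fundamental_hz = 0.4, amplitude = 3.5),
    D05 = adl_shape_params("transitional", fundamental_hz = 0.6, amplitude = 6.0),
    D06 = adl_shape_params("transitional", fundamental_hz = 0.35, amplitude = 4.0),
    D07 = adl_shape_params("periodic",
      fundamental_hz = 2.0, amplitude = 3.0,
      n_spikes = 1, spike_amp = 12
    ),
    D08 = adl_shape_params("impulsive",
      fundamental_hz = 1.0, amplitude = 2.0,
      n_spikes = 1, spike_amp = 10
    ),
    D09 = adl_shape_params("impulsive",
      fundamental_hz = 1.0, amplitude = 1.0,
      n_spikes = 3, spike_amp = 18
    ),
    D10 = adl_shape_params("impulsive",
      fundamental_hz = 1.5, amplitude = 1.0,
      n_spikes = 6, spike_amp = 20
    ),
    D11 = adl_shape_params("quasi-static", fundamental_hz = 0.3, amplitude = 0.8),
    stop("adl_defaults: unknown ADL code '", code, "'", call. = FALSE)
  )
}

## ---------------------------------------------------------------------------
## Signal-building helpers (50 Hz by default)

time_grid <- function(duration, rate) {
  n <- max(1L, round(duration * rate))
  (seq_len(n) - 1) / rate
}

smoothstep <- function(t, a, b) {
  s <- pmin(pmax((t - a) / (b - a), 0), 1)
  s * s * (3 - 2 * s)
}

gauss_bump <- function(t, centre, width) exp(-0.5 * ((t - centre) / width)^2)

## Orientation trace from a single rotation axis and an angle profile.
orientation_from_angle <- function(t, axis, angle, rate) {
  q <- quat_from_axis_angle(axis, angle)
  sensor_trace(
    "orientation",
    data.frame(t = t, qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4]),
    rate
  )
}

## Gyroscope trace: angular speed = d(angle)/dt about `axis`, plus noise.
gyro_from_angle <- function(t, axis, angle, rate, noise_sd = 0.02, extra = NULL) {
  dt <- 1 / rate
  omega <- c(diff(angle), 0) / dt
  m <- outer(omega, axis)
  if (!is.null(extra)) m <- m + extra
  m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), ncol = 3)
  sensor_trace("gyroscope", data.frame(t = t, x = m[, 1], y = m[, 2], z = m[, 3]), rate)
}

## Spike train: short (1-2 sample) high-amplitude bursts at `centres`.
add_spikes <- function(acc, t, centres, amp, rate, axis_factors = c(1, 0.8, 0.6)) {
  for (ct in centres) {
    w <- which(abs(t - ct) <= 1.01 / rate)
    if (length(w) == 0) next
    sgn <- sample(c(-1, 1), 1)
    shape <- stats::runif(length(w), 0.7, 1)
    for (ax in 1:3) {
      acc[w, ax] <- acc[w, ax] + sgn * amp * axis_factors[ax] * shape *
        stats::runif(1, 0.85, 1.15)
    }
  }
  acc
}

rtruncnorm_min <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  while (any(out < lower)) {
    bad <- out < lower
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

## Rotation axis and sense for each fall code (direction of the fall governs
## which body axis ends up carrying gravity while lying).
fall_axis <- function(code) {
  switch(code,
    F01 = c(0, 1, 0), # forward while walking (slip)
    F02 = c(1, 0, 0), # lateral while walking (slip)
    F03 = c(0, -1, 0), # backward while walking (slip)
    F04 = c(0, 1, 0), # forward while walking (trip)
    F05 = c(0, -1, 0), # backward when sitting down
    F06 = c(0, 1, 0), # forward while sitting (fainting)
    F07 = c(0, -1, 0), # backward while sitting (fainting)
    F08 = c(-1, 0, 0), # lateral while sitting (fainting)
    stop("unknown fall code '", code, "'", call. = FALSE)
  )
}

## Context (what the wearer was doing before the fall): walking for F01-F04,
## sitting for F05-F08.
fall_context <- function(code) if (code %in% c("F01", "F02", "F03", "F04")) "walking" else "sitting"

#' Generate a synthetic fall recording
#'
#' Produces a 50 Hz recording containing, in order: a prefall context signal
#' (walking or sitting, per the fall code), an impact spike cluster at the
#' midpoint of the actual-fall interval (where the acceleration variation is
#' greatest), a decaying adjustment oscillation, and a near-static postfall
#' segment with the wearer lying down.  The orientation trace is a slowly
#' varying unit quaternion that tips from upright to lying across the fall,
#' and the postfall body-frame gravity is derived from it, so rotating the
#' resting accelerometer vector by the orientation recovers (0, 0, g) up to
#' noise.  The actual-fall interval is returned in the recording metadata.
#'
#' @param code fall code `F01`..`F08`.
#' @param params a [fall_shape_params()].
#' @param seed integer seed; output is a pure function of
#'   `(code, params, seed)`.
#' @param rate_hz sampling rate (default 50).
#' @return a `fall_recording` with accelerometer, gyroscope and orientation
#'   traces and an `actual_fall` interval.
#' @export
generate_fall <- function(code, params = fall_shape_params(), seed, rate_hz = 50) {
  if (!code %in% FALL_CODES) stop("generate_fall: unknown fall code '", code, "'", call. = FALSE)
  stopifnot(inherits(params, "fall_shape_params"))
  with_seed(seed, {
    g <- GRAVITY
    amp <- params$amp_scale
    fhz <- params$freq_scale
    file_dur <- stats::runif(1, params$file_duration_range[1], params$file_duration_range[2])
    fall_dur <- rtruncnorm_min(1, params$fall_duration_mean, params$fall_duration_sd, 1.5)
    # keep the labeled interval strictly inside the file
    margin <- 0.75
    a <- stats::runif(1, margin, file_dur - fall_dur - margin)
    b <- a + fall_dur
    mid <- (a + b) / 2
    t <- time_grid(file_dur, rate_hz)
    n <- length(t)

    axis <- fall_axis(code)
    # orientation: upright (identity) -> lying (90 deg about `axis`), with a
    # small wobble while moving prefall
    wobble_amp <- if (fall_context(code) == "walking") 0.04 else 0.01
    angle <- (pi / 2) * smoothstep(t, a, b) +
      wobble_amp * sin(2 * pi * 1.8 * fhz * t) * (1 - smoothstep(t, a, b))
    orient <- orientation_from_angle(t, axis, angle, rate_hz)

    # gravity as seen in the body frame, consistent with the orientation
    qm <- as.matrix(orient[c("qw", "qx", "qy", "qz")])
    base <- quat_rotate(quat_conjugate(qm), matrix(rep(c(0, 0, g), each = n), ncol = 3))

    acc <- base
    pre <- t < a
    if (fall_context(code) == "walking") {
      f0 <- 2 * fhz
      ph <- stats::runif(3, 0, 2 * pi)
      acc[pre, 1] <- acc[pre, 1] + 2.5 * amp * sin(2 * pi * f0 * t[pre] + ph[1])
      acc[pre, 2] <- acc[pre, 2] + 1.0 * amp * sin(2 * pi * f0 * t[pre] + ph[2])
      acc[pre, 3] <- acc[pre, 3] + 1.2 * amp * sin(4 * pi * f0 * t[pre] + ph[3])
    } # sitting context: gravity + noise only

    # free-fall deficit between interval start and impact: the measured
    # specific force collapses towards zero
    falling <- t >= a & t < mid
    deficit <- 1 - 0.85 * smoothstep(t[falling], a, mid)
    acc[falling, ] <- acc[falling, ] * deficit +
      matrix(stats::rnorm(3 * sum(falling), 0, 1.2 * amp), ncol = 3)

    # impact cluster at the interval midpoint (greatest variation)
    peak <- params$impact_peak * amp
    imp <- which(abs(t - mid) <= 1.6 / rate_hz)
    sgn <- rep_len(c(1, -1), length(imp)) * sample(c(-1, 1), 1)
    for (ax in 1:3) {
      fac <- c(1, 0.75, 0.9)[ax]
      acc[imp, ax] <- acc[imp, ax] + sgn * peak * fac * stats::runif(length(imp), 0.8, 1)
    }

    # adjustment: decaying oscillation until the end of the interval
    adj <- t > mid & t <= b
    ta <- t[adj] - mid
    tau <- (b - mid) / 2.5
    osc <- 0.30 * peak * exp(-ta / tau) * sin(2 * pi * 5.5 * ta)
    acc[adj, 1] <- acc[adj, 1] + osc
    acc[adj, 2] <- acc[adj, 2] + 0.7 * osc * cos(2 * pi * 4.5 * ta)
    acc[adj, 3] <- acc[adj, 3] + 0.8 * osc

    acc <- acc + matrix(stats::rnorm(3 * n, 0, params$noise_sd), ncol = 3)

    spike <- numeric(n)
    spike[imp] <- 3.5 * sample(c(-1, 1), 1)
    gyro <- gyro_from_angle(t, axis, angle, rate_hz, extra = outer(spike, axis))

    accel <- sensor_trace(
      "accelerometer",
      data.frame(t = t, x = acc[, 1], y = acc[, 2], z = acc[, 3]), rate_hz
    )
    recording(
      user_id = "synthetic", cohort = "YP", activity = code, trial = 1L,
      traces = list(accelerometer = accel, gyroscope = gyro, orientation = orient),
      actual_fall = c(a, b)
    )
  })
}

#' Generate a synthetic ADL recording
#'
#' Produces a 50 Hz recording of the requested activity-of-daily-living code
#' with no actual-fall interval.  Impulsive codes (hitting a table D09,
#' clapping D10) contain short high-amplitude spike trains that are
#' fall-confusable by design; periodic codes carry a dominant spectral peak at
#' their fundamental frequency.
#'
#' @param code ADL code `D01`..`D11`.
#' @param params an [adl_shape_params()]; defaults to [adl_defaults()] for
#'   the code.
#' @param seed integer seed; output is a pure function of
#'   `(code, params, seed)`.
#' @param rate_hz sampling rate (default 50).
#' @return a `fall_recording` (with `actual_fall = NULL`).
#' @export
generate_adl <- function(code, params = NULL, seed, rate_hz = 50) {
  if (!code %in% ADL_CODES) stop("generate_adl: unknown ADL code '", code, "'", call. = FALSE)
  if (is.null(params)) params <- adl_defaults(code)
  stopifnot(inherits(params, "adl_shape_params"))
  with_seed(seed, {
    g <- GRAVITY
    amp <- params$amplitude * params$amp_scale
    f0 <- min(params$fundamental_hz * params$freq_scale, 20)
    dur <- stats::runif(1, params$duration_range[1], params$duration_range[2])
    t <- time_grid(dur, rate_hz)
    n <- length(t)

    # small upright wobble; transitional movements add a modest tilt
    axis <- c(1, 0, 0)
    angle <- 0.04 * sin(2 * pi * max(f0, 0.5) * t)
    if (params$class == "transitional") {
      t1 <- stats::runif(1, 0.15 * dur, 0.4 * dur)
      t2 <- stats::runif(1, 0.6 * dur, 0.85 * dur)
      angle <- angle + 0.25 * (smoothstep(t, t1 - 0.5, t1 + 0.5) - smoothstep(t, t2 - 0.5, t2 + 0.5))
    }
    orient <- orientation_from_angle(t, axis, angle, rate_hz)
    qm <- as.matrix(orient[c("qw", "qx", "qy", "qz")])
    acc <- quat_rotate(quat_conjugate(qm), matrix(rep(c(0, 0, g), each = n), ncol = 3))

    ph <- stats::runif(3, 0, 2 * pi)
    if (params$class == "periodic") {
      acc[, 1] <- acc[, 1] + amp * sin(2 * pi * f0 * t + ph[1])
      acc[, 2] <- acc[, 2] + 0.4 * amp * sin(2 * pi * f0 * t + ph[2])
      acc[, 3] <- acc[, 3] + 0.5 * amp * sin(4 * pi * f0 * t + ph[3])
    } else if (params$class == "transitional") {
      acc[, 3] <- acc[, 3] + amp * (gauss_bump(t, t1, 0.4) - 0.7 * gauss_bump(t, t2, 0.4))
      acc[, 1] <- acc[, 1] + 0.3 * amp * gauss_bump(t, t1, 0.5)
    } else if (params$class == "quasi-static") {
      acc[, 1] <- acc[, 1] + amp * sin(2 * pi * f0 * t + ph[1])
      acc[, 2] <- acc[, 2] + 0.3 * amp * sin(2 * pi * f0 * t + ph[2])
    } else { # impulsive: near-static baseline, spikes added below
      acc[, 1] <- acc[, 1] + 0.3 * amp * sin(2 * pi * f0 * t + ph[1])
    }

    n_spk <- params$n_spikes
    if (params$class == "impulsive" && n_spk == 0) n_spk <- 3
    if (n_spk > 0) {
      spk_amp <- if (params$spike_amp > 0) params$spike_amp * params$amp_scale else amp
      centres <- sort(stats::runif(n_spk, 0.08 * dur, 0.92 * dur))
      acc <- add_spikes(acc, t, centres, spk_amp, rate_hz)
      gy_extra <- matrix(0, n, 3)
      for (ct in centres) {
        w <- which(abs(t - ct) <= 1.01 / rate_hz)
        gy_extra[w, ] <- gy_extra[w, ] + stats::runif(1, 0.5, 1.5)
      }
    } else {
      gy_extra <- NULL
    }

    acc <- acc + matrix(stats::rnorm(3 * n, 0, params$noise_sd), ncol = 3)
    gyro <- gyro_from_angle(t, axis, angle, rate_hz, extra = gy_extra)
    accel <- sensor_trace(
      "accelerometer",
      data.frame(t = t, x = acc[, 1], y = acc[, 2], z = acc[, 3]), rate_hz
    )
    recording(
      user_id = "synthetic", cohort = "YP", activity = code, trial = 1L,
      traces = list(accelerometer = accel, gyroscope = gyro, orientation = orient)
    )
  })
}

#' Generate a full synthetic dataset under an acquisition protocol
#'
#' One recording per (participant, activity, repetition).  Movement amplitude
#' and cadence are jittered per participant (so that two participants differ
#' more than two repetitions by the same participant, mirroring the
#' participant bias of acted datasets), and elder-cohort participants move
#' with lower amplitudes and frequencies.
#'
#' @param prot a `fall_protocol` (e.g. [yp_protocol()]).
#' @param seed integer seed; output is a pure function of `(prot, seed)`.
#' @param rate_hz sampling rate (default 50).
#' @return list of `fall_recording`.
#' @export
generate_dataset <- function(prot, seed, rate_hz = 50) {
  stopifnot(inherits(prot, "fall_protocol"))
  if (nrow(prot) == 0) {
    return(list())
  }
  users <- unique(prot$user_id)
  user_seeds <- derive_seeds(seed, length(users) + 1)
  jitter <- lapply(seq_along(users), function(i) {
    with_seed(user_seeds[i], list(
      amp = stats::runif(1, 0.85, 1.15),
      freq = stats::runif(1, 0.92, 1.08)
    ))
  })
  names(jitter) <- users

  total <- sum(prot$reps)
  rec_seeds <- derive_seeds(user_seeds[length(user_seeds)], total)
  out <- vector("list", total)
  k <- 0L
  for (i in seq_len(nrow(prot))) {
    row <- prot[i, ]
    jt <- jitter[[row$user_id]]
    elder <- row$cohort == "EP"
    amp_scale <- jt$amp * if (elder) 0.6 else 1
    freq_scale <- jt$freq * if (elder) 0.85 else 1
    for (rep_idx in seq_len(row$reps)) {
      k <- k + 1L
      if (row$activity %in% FALL_CODES) {
        p <- fall_shape_params(amp_scale = amp_scale, freq_scale = freq_scale)
        rec <- generate_fall(row$activity, p, seed = rec_seeds[k], rate_hz = rate_hz)
      } else {
        p <- adl_defaults(row$activity)
        p$amp_scale <- amp_scale
        p$freq_scale <- freq_scale
        rec <- generate_adl(row$activity, p, seed = rec_seeds[k], rate_hz = rate_hz)
      }
      rec$user_id <- row$user_id
      rec$cohort <- row$cohort
      rec$trial <- rep_idx
      out[[k]] <- rec
    }
  }
  out
}
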