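#' Per-subject simulation parameters
#'
#' Describes one simulated wearer of the instrumented eyeglasses. Chewing
#' frequency is constrained to the physiological 0.94-2.17 Hz range; the step
#' rate defaults near the ~2 Hz cadence of 3 mph walking.
#'
#' @param subject_id character identifier, e.g. `"S01"`.
#' @param chew_rate chewing fundamental frequency in Hz, in \[0.94, 2.17\].
#' @param step_rate walking step frequency in Hz.
#' @param chew_amplitude peak amplitude of the chewing oscillation on the
#'   piezoelectric channel (sensor units).
#' @param gait_amplitude peak amplitude of the gait oscillation on the
#'   accelerometer vertical axis, in g.
#' @param noise_sd standard deviation of white sensor noise on the
#'   piezoelectric channel (sensor units).
#' @param accel_noise_sd standard deviation of white accelerometer noise per
#'   axis, in g; sedentary posture-shift transients scale with it.
#' @param crosstalk_gain fraction of the gait oscillation that leaks
#'   mechanically into the piezoelectric channel during walking (>= 0).
#' @param gravity unit 3-vector giving the orientation of gravity in the
#'   accelerometer frame.
#' @param rng_seed integer seed for this subject's random stream.
#' @return a list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id,
                            chew_rate = 1.5,
                            step_rate = 2.0,
                            chew_amplitude = 1.0,
                            gait_amplitude = 0.3,
                            noise_sd = 0.05,
                            accel_noise_sd = 0.02,
                            crosstalk_gain = 0.15,
                            gravity = c(0, 0, 1),
                            rng_seed = 1L) {
  for (nm in c("chew_rate", "step_rate", "chew_amplitude", "gait_amplitude",
               "noise_sd", "accel_noise_sd", "crosstalk_gain")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (chew_rate < 0.94 || chew_rate > 2.17) {
    stop("'chew_rate' must lie in [0.94, 2.17] Hz", call. = FALSE)
  }
  if (chew_amplitude < 0 || gait_amplitude <= 0 || noise_sd <= 0 ||
      accel_noise_sd <= 0) {
    stop("amplitudes and noise standard deviations must be positive",
         call. = FALSE)
  }
  if (crosstalk_gain < 0) stop("'crosstalk_gain' must be >= 0", call. = FALSE)
  if (length(gravity) != 3L || abs(sqrt(sum(gravity^2)) - 1) > 1e-6) {
    stop("'gravity' must be a unit 3-vector", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), chew_rate = chew_rate,
         step_rate = step_rate, chew_amplitude = chew_amplitude,
         gait_amplitude = gait_amplitude, noise_sd = noise_sd,
         accel_noise_sd = accel_noise_sd, crosstalk_gain = crosstalk_gain,
         gravity = as.numeric(gravity), rng_seed = as.integer(rng_seed)),
    class = "subject_profile"
  )
}

# Alternating chew-bout / pause intervals covering [0, duration).
# Bouts last 10-30 s, pauses (bite preparation, swallowing) 2-5 s.
draw_bouts <- function(duration, bout_range = c(10, 30),
                       pause_range = c(2, 5)) {
  t <- 0
  starts <- numeric(0)
  ends <- numeric(0)
  while (t < duration) {
    len <- runif(1, bout_range[1], bout_range[2])
    end <- min(t + len, duration)
    starts <- c(starts, t)
    ends <- c(ends, end)
    t <- end + runif(1, pause_range[1], pause_range[2])
  }
  cbind(start = starts, end = ends)
}

#' Simulate the piezoelectric chewing signal
#'
#' Generates the strain-sensor voltage produced by rhythmic chewing: an
#' amplitude-modulated oscillation at the subject's chewing rate (fundamental
#' plus an attenuated second harmonic), organized in chewing bouts of 10-30 s
#' separated by 2-5 s pauses, on top of white sensor noise. Uses the current
#' RNG state; seed it for reproducibility.
#'
#' @param duration signal duration in seconds (> 0).
#' @param profile a [subject_profile()].
#' @param fs sampling rate in Hz (device default 1000).
#' @return numeric vector of `round(duration * fs)` samples, with a `"bouts"`
#'   attribute: a two-column matrix of chewing-bout start/end times (s).
#' @export
synth_chew_signal <- function(duration, profile, fs = 1000) {
  stop_if_not_scalar_number(duration, "duration")
  if (duration <= 0) stop("'duration' must be > 0", call. = FALSE)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  bouts <- draw_bouts(duration)
  env <- numeric(n)
  for (k in seq_len(nrow(bouts))) {
    idx <- t >= bouts[k, 1] & t < bouts[k, 2]
    env[idx] <- runif(1, 0.85, 1.15)  # per-bout vigor
  }
  ph <- runif(2, 0, 2 * pi)
  f0 <- profile$chew_rate
  carrier <- sin(2 * pi * f0 * t + ph[1]) +
    0.4 * sin(4 * pi * f0 * t + ph[2])
  # slow jaw-effort modulation within bouts
  am <- 1 + 0.2 * sin(2 * pi * 0.15 * t + runif(1, 0, 2 * pi))
  x <- profile$chew_amplitude * env * am * carrier +
    rnorm(n, 0, profile$noise_sd)
  attr(x, "bouts") <- bouts
  x
}

# Smooth posture-shift transient (gaussian bump) added to one axis.
add_posture_shifts <- function(mat, fs, duration, accel_noise_sd) {
  n_events <- stats::rpois(1, duration / 25)
  if (n_events == 0) return(mat)
  n <- nrow(mat)
  t <- (seq_len(n) - 1) / fs
  for (k in seq_len(n_events)) {
    centre <- runif(1, 0, duration)
    width <- runif(1, 0.3, 0.8)
    amp <- runif(1, 1, 3) * accel_noise_sd
    axis <- sample.int(3, 1)
    mat[, axis] <- mat[, axis] + amp * exp(-((t - centre)^2) / (2 * width^2))
  }
  mat
}

#' Simulate the three-axis accelerometer signal
#'
#' Each axis carries the projection of gravity, white noise, and -- when
#' walking -- a gait oscillation at the subject's step rate with harmonics
#' (strongest on the vertical axis, attenuated fore-aft and mediolateral
#' components). Sedentary stretches instead get sparse low-amplitude
#' posture-shift transients. Uses the current RNG state.
#'
#' @param duration signal duration in seconds (> 0).
#' @param walking logical; is the subject walking?
#' @param profile a [subject_profile()].
#' @param fs sampling rate in Hz (device default 100).
#' @return numeric matrix with `round(duration * fs)` rows and columns
#'   `ax`, `ay`, `az`, in g.
#' @export
synth_accel <- function(duration, walking, profile, fs = 100) {
  stop_if_not_scalar_number(duration, "duration")
  if (duration <= 0) stop("'duration' must be > 0", call. = FALSE)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  g <- profile$gravity
  mat <- cbind(ax = rep(g[1], n), ay = rep(g[2], n), az = rep(g[3], n))
  if (isTRUE(walking)) {
    f <- profile$step_rate
    ga <- profile$gait_amplitude
    ph <- runif(4, 0, 2 * pi)
    mat[, "az"] <- mat[, "az"] + ga * sin(2 * pi * f * t + ph[1]) +
      0.3 * ga * sin(4 * pi * f * t + ph[2])
    mat[, "ax"] <- mat[, "ax"] + 0.5 * ga * sin(2 * pi * f * t + ph[3])
    # mediolateral sway alternates with the stride (half the step rate)
    mat[, "ay"] <- mat[, "ay"] + 0.25 * ga * sin(pi * f * t + ph[4])
  } else {
    mat <- add_posture_shifts(mat, fs, duration, profile$accel_noise_sd)
  }
  mat + matrix(rnorm(3 * n, 0, profile$accel_noise_sd), ncol = 3)
}

# Speech / head-motion artifact on the piezo channel: utterance bursts of a
# weak jaw oscillation around 3 Hz with on/off structure.
synth_speech_artifact <- function(duration, profile, fs = 1000) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  env <- numeric(n)
  tm <- 0
  while (tm < duration) {
    on <- runif(1, 1, 4)
    idx <- t >= tm & t < min(tm + on, duration)
    env[idx] <- runif(1, 0.5, 1)
    tm <- tm + on + runif(1, 0.5, 2)
  }
  f <- runif(1, 2.5, 4)
  0.12 * profile$chew_amplitude * env * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
}

#' Simulate one subject's full recording
#'
#' Plays the activity schedule through the signal generators: chewing bursts
#' on the piezoelectric channel during eating segments, speech artifacts while
#' talking, gait crosstalk (scaled by `crosstalk_gain`) whenever walking, and
#' the matching accelerometer behavior per segment. The pushbutton annotation
#' channel is 1 exactly during chewing bouts. The subject's `rng_seed` makes
#' the recording reproducible.
#'
#' @param profile a [subject_profile()].
#' @param schedule an [activity_schedule()]; defaults to [default_protocol()].
#' @param fs_piezo piezoelectric sampling rate in Hz.
#' @param fs_acc accelerometer/annotation sampling rate in Hz.
#' @return a list of class `sensor_recording` with elements `subject_id`,
#'   `piezo` (numeric vector @ `fs_piezo`), `accel` (matrix `ax`,`ay`,`az`
#'   @ `fs_acc`), `annotation` (0/1 integer vector @ `fs_acc`), `schedule`,
#'   and `metadata` (sampling rates plus generator parameters).
#' @export
generate_subject <- function(profile, schedule = default_protocol(),
                             fs_piezo = 1000, fs_acc = 100) {
  if (!inherits(profile, "subject_profile")) {
    stop("'profile' must be a subject_profile", call. = FALSE)
  }
  validate_schedule(schedule)
  set.seed(profile$rng_seed)
  piezo <- numeric(0)
  accel <- NULL
  annotation <- integer(0)
  for (k in seq_len(nrow(schedule))) {
    lab <- schedule$label[k]
    dur <- schedule$duration[k]
    n_p <- round(dur * fs_piezo)
    n_a <- round(dur * fs_acc)
    walking <- lab %in% c("walk", "eat_walk")
    eating <- lab %in% c("eat_sit", "eat_walk")

    if (eating) {
      seg <- synth_chew_signal(dur, profile, fs_piezo)
      bouts <- attr(seg, "bouts")
      ta <- (seq_len(n_a) - 1) / fs_acc
      ann <- integer(n_a)
      for (b in seq_len(nrow(bouts))) {
        ann[ta >= bouts[b, 1] & ta < bouts[b, 2]] <- 1L
      }
    } else {
      seg <- rnorm(n_p, 0, profile$noise_sd)
      if (lab == "talk") seg <- seg + synth_speech_artifact(dur, profile, fs_piezo)
      ann <- integer(n_a)
    }
    if (walking) {
      tp <- (seq_len(n_p) - 1) / fs_piezo
      xt <- profile$crosstalk_gain * profile$gait_amplitude
      seg <- seg + xt * (sin(2 * pi * profile$step_rate * tp) +
                           0.3 * sin(4 * pi * profile$step_rate * tp))
    }
    acc <- synth_accel(dur, walking, profile, fs_acc)

    piezo <- c(piezo, as.numeric(seg))
    accel <- rbind(accel, acc)
    annotation <- c(annotation, ann)
  }
  rec <- structure(
    list(subject_id = profile$subject_id,
         piezo = piezo,
         accel = accel,
         annotation = annotation,
         schedule = schedule,
         metadata = list(fs_piezo = fs_piezo, fs_acc = fs_acc,
                         profile = unclass(profile))),
    class = "sensor_recording"
  )
  validate_recording(rec)
  rec
}

#' Validate a sensor recording's structural invariants
#'
#' Checks the fixed 10:1 sample-count ratio between the piezoelectric channel
#' and the accelerometer/annotation channels, and that the channels span the
#' schedule's total duration.
#'
#' @param rec a `sensor_recording`.
#' @return `rec`, invisibly; errors if an invariant is violated.
#' @export
validate_recording <- function(rec) {
  md <- rec$metadata
  ratio <- md$fs_piezo / md$fs_acc
  if (length(rec$piezo) != ratio * nrow(rec$accel) ||
      nrow(rec$accel) != length(rec$annotation)) {
    stop("channel lengths violate the fs_piezo : fs_acc sample ratio",
         call. = FALSE)
  }
  dur <- schedule_duration(rec$schedule)
  if (abs(length(rec$piezo) / md$fs_piezo - dur) > 1 / md$fs_acc) {
    stop("recording length does not match schedule duration", call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.sensor_recording <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<sensor_recording> subject %s: %.0f s (%d piezo @ %g Hz, %d accel @ %g Hz)\n",
              x$subject_id, length(x$piezo) / md$fs_piezo, length(x$piezo),
              md$fs_piezo, nrow(x$accel), md$fs_acc))
  cat("  schedule: ",
      paste(sprintf("%s %gs", x$schedule$label, x$schedule$duration),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate a multi-subject cohort
#'
#' Draws per-subject physiological parameters (chewing rate within the
#' 0.94-2.17 Hz range, step rate near 2 Hz, amplitudes, noise and crosstalk
#' levels, device tilt) from the master seed, then generates each subject's
#' recording from an independent per-subject substream so cohorts are
#' reproducible bit-for-bit.
#'
#' @param n_subjects number of subjects (>= 2; leave-one-subject-out
#'   evaluation needs at least two). Default 10.
#' @param master_seed integer seed for the cohort.
#' @param schedule an [activity_schedule()] applied to every subject.
#' @return list of `sensor_recording`, one per subject.
#' @export
generate_cohort <- function(n_subjects = 10, master_seed = 42,
                            schedule = default_protocol()) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop("'n_subjects' must be >= 2 (one-subject cohorts cannot be cross-validated)",
         call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  profiles <- draw_profiles(n_subjects, master_seed)
  lapply(profiles, generate_subject, schedule = schedule)
}

#' Draw per-subject profiles for a cohort
#'
#' @inheritParams generate_cohort
#' @return list of [subject_profile()] objects with seeds derived from
#'   `master_seed`.
#' @export
draw_profiles <- function(n_subjects, master_seed = 42) {
  set.seed(master_seed)
  lapply(seq_len(n_subjects), function(i) {
    tilt <- runif(1, 0, 8) * pi / 180
    azim <- runif(1, 0, 2 * pi)
    subject_profile(
      subject_id = sprintf("S%02d", i),
      chew_rate = runif(1, 0.94, 2.17),
      step_rate = runif(1, 1.8, 2.2),
      chew_amplitude = runif(1, 0.8, 1.2),
      gait_amplitude = runif(1, 0.25, 0.35),
      noise_sd = runif(1, 0.03, 0.07),
      accel_noise_sd = runif(1, 0.015, 0.025),
      crosstalk_gain = runif(1, 0.10, 0.20),
      gravity = c(sin(tilt) * cos(azim), sin(tilt) * sin(azim), cos(tilt)),
      rng_seed = (as.integer(master_seed) + 10007L * i) %% 2147483647L
    )
  })
}
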