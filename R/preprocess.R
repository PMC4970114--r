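# Zero-phase filtering via forward-backward application of `bf` with odd
# reflection padding at both ends; padding absorbs startup transients so DC
# offsets and epoch boundaries are preserved.
zero_phase_filter <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad > 0) {
    left <- 2 * x[1] - x[(pad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - pad)]
    xe <- c(left, x, right)
  } else {
    xe <- x
  }
  y <- as.numeric(signal::filter(bf, xe))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(pad + 1):(pad + n)]
}

#' Low-pass filter the piezoelectric channel
#'
#' Chewing occupies 0.94-2.17 Hz, so the strain signal is low-pass filtered at
#' 3.0 Hz before feature extraction. A 4th-order Butterworth filter is applied
#' forward and backward (zero phase), so chew peaks stay aligned with the
#' annotation channel. Reflection padding of about two seconds suppresses edge
#' transients; DC gain is unity.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz; must exceed twice the cutoff.
#' @param cutoff filter cutoff in Hz (default 3.0).
#' @return filtered signal, same length as `x`.
#' @export
lowpass_piezo <- function(x, fs = 1000, cutoff = 3.0) {
  if (length(x) == 0L) stop("'x' must be non-empty", call. = FALSE)
  if (fs <= 2 * cutoff) {
    stop("'fs' must exceed twice the cutoff (Nyquist)", call. = FALSE)
  }
  bf <- signal::butter(4, cutoff / (fs / 2))
  zero_phase_filter(bf, as.numeric(x), pad = round(2 * fs))
}

#' Net acceleration
#'
#' Element-wise Euclidean magnitude of the three accelerometer axes, gravity
#' included.
#'
#' @param ax,ay,az numeric vectors of equal length, in g.
#' @return numeric vector `sqrt(ax^2 + ay^2 + az^2)`.
#' @export
net_acceleration <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az)) {
    stop("axis vectors must have equal length", call. = FALSE)
  }
  sqrt(ax^2 + ay^2 + az^2)
}

#' Assign the activity class of one epoch
#'
#' The schedule segment with the largest wall-clock overlap with the epoch
#' wins (majority rule; ties go to the earlier segment). Quiet sitting and
#' talking both map to the sedentary class.
#'
#' @param start,end epoch interval in seconds, `start < end`, inside the
#'   schedule span.
#' @param schedule an [activity_schedule()].
#' @return integer class code (see [class_levels()]).
#' @export
assign_label <- function(start, end, schedule) {
  seg_end <- schedule$start + schedule$duration
  if (start < schedule$start[1] - 1e-9 || end > seg_end[nrow(schedule)] + 1e-9) {
    stop("epoch interval lies outside the schedule", call. = FALSE)
  }
  overlap <- pmax(0, pmin(end, seg_end) - pmax(start, schedule$start))
  lab <- schedule$label[which.max(overlap)]  # which.max: earlier segment on ties
  code <- switch(lab,
                 eat_sit = 1L, quiet_sit = 2L, talk = 2L,
                 eat_walk = 3L, walk = 4L)
  code
}

#' Cut a recording into aligned 3-s epochs
#'
#' Conditions both channels (piezoelectric low-pass at 3 Hz, accelerometer to
#' net acceleration), then cuts them into non-overlapping epochs anchored at
#' t = 0 and aligned across channels by wall-clock time. A trailing partial
#' epoch is discarded. Each epoch is labeled from the ground-truth schedule by
#' majority overlap.
#'
#' @param recording a `sensor_recording`.
#' @param epoch_s epoch length in seconds (default 3).
#' @return list of epochs; each epoch is a list with `index` (0-based),
#'   `start`/`end` (s), `piezo` (filtered samples, `epoch_s * fs_piezo`),
#'   `acc` (net-acceleration samples, `epoch_s * fs_acc`), and integer
#'   `label`.
#' @export
epoch_segment <- function(recording, epoch_s = 3) {
  validate_recording(recording)
  md <- recording$metadata
  dur <- length(recording$piezo) / md$fs_piezo
  if (dur < epoch_s) {
    stop("recording shorter than one epoch", call. = FALSE)
  }
  n_epochs <- floor(dur / epoch_s)
  piezo_f <- lowpass_piezo(recording$piezo, md$fs_piezo)
  net <- net_acceleration(recording$accel[, "ax"], recording$accel[, "ay"],
                          recording$accel[, "az"])
  np <- epoch_s * md$fs_piezo
  na <- epoch_s * md$fs_acc
  lapply(seq_len(n_epochs) - 1L, function(i) {
    list(index = i,
         start = i * epoch_s,
         end = (i + 1) * epoch_s,
         piezo = piezo_f[(i * np + 1):((i + 1) * np)],
         acc = net[(i * na + 1):((i + 1) * na)],
         label = assign_label(i * epoch_s, (i + 1) * epoch_s,
                              recording$schedule))
  })
}
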