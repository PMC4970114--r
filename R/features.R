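#' Time-domain epoch features
#'
#' Four scalar features summarize each 3-s epoch of each channel: the range of
#' values, the sample standard deviation, the signal energy, and the waveform
#' length. All four grow with chewing on the strain channel and with gait on
#' the net-acceleration channel, which is what makes the activity classes
#' linearly separable.
#'
#' @param x numeric vector of epoch samples.
#' @return a single number.
#' @name epoch_features
NULL

#' @rdname epoch_features
#' @details `range_of(x)`: `max(x) - min(x)`.
#' @export
range_of <- function(x) {
  if (length(x) == 0L) stop("'x' must be non-empty", call. = FALSE)
  max(x) - min(x)
}

#' @rdname epoch_features
#' @details `std_of(x)`: sample standard deviation with the N-1 denominator.
#' @export
std_of <- function(x) {
  if (length(x) < 2L) stop("'x' must have length >= 2", call. = FALSE)
  sd(x)
}

#' @rdname epoch_features
#' @details `energy_of(x)`: sum of squared samples (no mean removal, so a DC
#'   component such as gravity contributes).
#' @export
energy_of <- function(x) {
  if (length(x) == 0L) stop("'x' must be non-empty", call. = FALSE)
  sum(x^2)
}

#' @rdname epoch_features
#' @details `waveform_length(x)`: sum of absolute successive differences.
#' @export
waveform_length <- function(x) {
  if (length(x) < 2L) stop("'x' must have length >= 2", call. = FALSE)
  sum(abs(diff(x)))
}

feature_vector <- function(x) {
  c(rng = range_of(x), std = std_of(x), eng = energy_of(x),
    wl = waveform_length(x))
}

#' Feature table column names
#' @return character vector: the eight feature columns, piezo first.
#' @export
feature_columns <- function() {
  c("p_rng", "p_std", "p_eng", "p_wl", "a_rng", "a_std", "a_eng", "a_wl")
}

#' Compute the per-epoch feature table
#'
#' For each epoch, the four features of the filtered piezoelectric samples
#' (`f_chew`) and of the net-acceleration samples (`f_acc`) are concatenated
#' into the fused 8-vector, piezo features first.
#'
#' @param epochs list of epochs from [epoch_segment()].
#' @param subject_id identifier stored in the `subject` column.
#' @return data.frame with one row per epoch and columns `subject`, `epoch`,
#'   `label`, then `p_rng, p_std, p_eng, p_wl, a_rng, a_std, a_eng, a_wl`.
#' @export
featurize <- function(epochs, subject_id = "S01") {
  if (length(epochs) == 0L) stop("'epochs' must be non-empty", call. = FALSE)
  rows <- vapply(epochs, function(e) {
    c(feature_vector(e$piezo), feature_vector(e$acc))
  }, numeric(8))
  out <- data.frame(
    subject = rep(as.character(subject_id), length(epochs)),
    epoch = vapply(epochs, function(e) e$index, numeric(1)),
    label = vapply(epochs, function(e) as.integer(e$label), integer(1)),
    t(rows),
    stringsAsFactors = FALSE
  )
  names(out)[-(1:3)] <- feature_columns()
  stopifnot(!anyNA(out))
  out
}

#' Featurize a whole cohort
#'
#' Runs [epoch_segment()] and [featurize()] on every recording and binds the
#' results.
#'
#' @param cohort list of `sensor_recording` from [generate_cohort()].
#' @param epoch_s epoch length in seconds.
#' @return combined feature table (see [featurize()]).
#' @export
featurize_cohort <- function(cohort, epoch_s = 3) {
  do.call(rbind, lapply(cohort, function(rec) {
    featurize(epoch_segment(rec, epoch_s), rec$subject_id)
  }))
}
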