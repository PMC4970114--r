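activity_labels <- c("quiet_sit", "eat_sit", "talk", "eat_walk", "walk")

#' Build an activity schedule
#'
#' A schedule is an ordered sequence of contiguous, non-overlapping activity
#' segments starting at t = 0. Each segment has an activity label and a
#' positive duration in seconds.
#'
#' @param labels character vector of activity labels, each one of
#'   `"quiet_sit"`, `"eat_sit"`, `"talk"`, `"eat_walk"`, `"walk"`.
#' @param durations numeric vector of segment durations in seconds, same
#'   length as `labels`, all > 0.
#' @return a data.frame of class `activity_schedule` with columns `label`,
#'   `start`, `duration` (seconds).
#' @export
activity_schedule <- function(labels, durations) {
  if (length(labels) != length(durations) || length(labels) == 0L) {
    stop("'labels' and 'durations' must be non-empty and of equal length",
         call. = FALSE)
  }
  bad <- setdiff(labels, activity_labels)
  if (length(bad)) {
    stop("unknown activity label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(durations) || any(!is.finite(durations)) ||
      any(durations <= 0)) {
    stop("all segment durations must be finite and > 0", call. = FALSE)
  }
  sched <- data.frame(
    label = as.character(labels),
    start = cumsum(c(0, durations[-length(durations)])),
    duration = as.numeric(durations),
    stringsAsFactors = FALSE
  )
  class(sched) <- c("activity_schedule", "data.frame")
  sched
}

#' Default in-lab activity protocol
#'
#' The five-activity session layout: an initial quiet rest, then eating while
#' sitting, talking, eating while walking, and walking. The default durations
#' (165, 96, 180, 81, 132 s; 654 s total) are chosen so that a ten-subject
#' cohort cut into 3-s epochs yields a class balance close to the study's
#' reported epoch counts. Durations are configurable.
#'
#' @param durations named numeric vector of segment durations in seconds, with
#'   names `quiet_sit`, `eat_sit`, `talk`, `eat_walk`, `walk`.
#' @return an [activity_schedule()] with the five segments in protocol order.
#' @export
#' @examples
#' sched <- default_protocol()
#' sum(sched$duration)  # 654 s
default_protocol <- function(durations = c(quiet_sit = 165, eat_sit = 96,
                                           talk = 180, eat_walk = 81,
                                           walk = 132)) {
  want <- c("quiet_sit", "eat_sit", "talk", "eat_walk", "walk")
  if (is.null(names(durations)) || !setequal(names(durations), want)) {
    stop("'durations' must be named with exactly: ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  activity_schedule(want, unname(durations[want]))
}

schedule_duration <- function(schedule) {
  sum(schedule$duration)
}

validate_schedule <- function(schedule) {
  if (!inherits(schedule, "activity_schedule")) {
    schedule <- activity_schedule(schedule$label, schedule$duration)
  }
  ends <- schedule$start + schedule$duration
  if (nrow(schedule) > 1L &&
      any(abs(schedule$start[-1] - ends[-nrow(schedule)]) > 1e-9)) {
    stop("schedule segments must be contiguous", call. = FALSE)
  }
  invisible(schedule)
}
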