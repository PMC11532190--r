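#' Laboratory stressor protocol specification
#'
#' A protocol is an ordered list of recording *sessions*, one per activity.
#' Each session is a contiguous recording consisting of phases: a pre-activity
#' rest, one or more activity blocks (with pauses between repetitions), and a
#' short recovery. The default day-1 protocol has three sessions:
#'
#' * isometric handgrip: 4-min rest, 3 x 2-min grip at 30% of maximal
#'   voluntary contraction with 2-min pauses, 1-min recovery;
#' * mental stress (serial subtraction): 4-min rest, 5-min task, 1-min
#'   recovery;
#' * cold pressor: 4-min rest, 2-min hand immersion in 2-5 degC water,
#'   1-min recovery.
#'
#' @param sessions list of session specs built with [protocol_session()].
#' @return An object of class `bp_protocol`.
#' @seealso [default_protocol()], [day2_protocol()]
#' @export
bp_protocol <- function(sessions) {
  stopifnot(is.list(sessions), length(sessions) >= 1L)
  for (s in sessions) {
    if (!inherits(s, "bp_protocol_session"))
      stop_cf("every element of `sessions` must come from protocol_session()")
  }
  acts <- vapply(sessions, `[[`, "", "activity")
  if (anyDuplicated(acts))
    stop_cf("duplicate activity labels in protocol: %s",
            paste(acts[duplicated(acts)], collapse = ", "))
  structure(list(sessions = sessions), class = "bp_protocol")
}

ACTIVITY_LABELS <- c("rest", "handgrip", "mental_stress", "cold_pressor", "recovery")

#' Build one protocol session
#'
#' @param activity activity label: one of `"rest"`, `"handgrip"`,
#'   `"mental_stress"`, `"cold_pressor"`.
#' @param duration duration of one activity block, seconds.
#' @param reps number of repetitions of the activity block.
#' @param pause pause between repetitions, seconds.
#' @param rest pre-activity rest, seconds (default 240 s = 4 min).
#' @param recovery post-activity recovery, seconds (default 60 s).
#' @return A `bp_protocol_session`: the activity label, a phase table
#'   (`label`, `start`, `duration` in session seconds) and the total session
#'   duration.
#' @export
protocol_session <- function(activity, duration, reps = 1L, pause = 0,
                             rest = 240, recovery = 60) {
  activity <- match.arg(activity, setdiff(ACTIVITY_LABELS, c("rest", "recovery")))
  stopifnot(duration > 0, reps >= 1L, pause >= 0, rest >= 0, recovery >= 0)
  lab <- character(0); dur <- numeric(0)
  if (rest > 0) { lab <- "rest"; dur <- rest }
  for (r in seq_len(reps)) {
    lab <- c(lab, activity); dur <- c(dur, duration)
    if (r < reps && pause > 0) { lab <- c(lab, "rest"); dur <- c(dur, pause) }
  }
  if (recovery > 0) { lab <- c(lab, "recovery"); dur <- c(dur, recovery) }
  phases <- data.frame(label = lab, start = cumsum(c(0, dur[-length(dur)])),
                       duration = dur, stringsAsFactors = FALSE)
  structure(list(activity = activity, phases = phases,
                 total_duration = sum(dur), rest = rest),
            class = "bp_protocol_session")
}

#' Default day-1 three-activity protocol
#' @return A `bp_protocol` with handgrip, mental-stress and cold-pressor
#'   sessions (900 s, 600 s and 420 s respectively).
#' @export
default_protocol <- function() {
  bp_protocol(list(
    protocol_session("handgrip",      120, reps = 3L, pause = 120),
    protocol_session("mental_stress", 300),
    protocol_session("cold_pressor",  120)
  ))
}

#' Day-2 follow-up protocol (handgrip only)
#' @return A `bp_protocol` with the single repeated-handgrip session.
#' @export
day2_protocol <- function() {
  bp_protocol(list(protocol_session("handgrip", 120, reps = 3L, pause = 120)))
}

#' @export
print.bp_protocol <- function(x, ...) {
  cat("<bp_protocol> ", length(x$sessions), " session(s)\n", sep = "")
  for (s in x$sessions)
    cat(sprintf("  %-14s %4.0f s (%d phases)\n",
                s$activity, s$total_duration, nrow(s$phases)))
  invisible(x)
}

# Fraction-of-full-response curve for the activity phases of one session:
# linear onset over `ramp` seconds from each activity-phase start, sustained
# during the phase, linear offset over `ramp` seconds after it ends.
session_response <- function(session, t, ramp = 20) {
  r <- numeric(length(t))
  ph <- session$phases
  act <- ph[ph$label == session$activity, , drop = FALSE]
  for (i in seq_len(nrow(act))) {
    a <- act$start[i]; b <- a + act$duration[i]
    up   <- pmin(pmax((t - a) / min(ramp, act$duration[i]), 0), 1)
    down <- pmin(pmax((t - b) / ramp, 0), 1)
    r <- pmax(r, up - down)
  }
  r
}
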