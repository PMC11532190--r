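#' Brachial calibration value from a cuff triplet
#'
#' The calibration value is the mean of the last two of the three cuff
#' readings taken during the pre-activity rest (the first reading is
#' discarded).
#'
#' @param triplet a `bp_brachial_triplet` or data.frame with exactly three
#'   rows and a column for `parameter`.
#' @param parameter `"sbp"` (default, the value used to shift the reference
#'   waveform) or `"dbp"`.
#' @return the calibration value, mmHg.
#' @export
brachial_calibration_value <- function(triplet, parameter = c("sbp", "dbp")) {
  parameter <- match.arg(parameter)
  if (!is.data.frame(triplet) || nrow(triplet) != 3L)
    stop_cf("a brachial triplet must contain exactly 3 readings, got %s",
            if (is.data.frame(triplet)) nrow(triplet) else "a non-table")
  if (is.unsorted(triplet$time, strictly = TRUE))
    stop_cf("brachial reading timestamps must be strictly increasing")
  mean(triplet[[parameter]][2:3])
}

#' Recalibrate a reference waveform against its brachial triplet
#'
#' Computes the additive offset `brachial SBP value - mean accepted cycle
#' maxima in the rest window` and shifts every sample of the record by it, so
#' the waveform peaks align with the cuff calibration value. Because the
#' whole waveform is shifted, DBP and MAP of every beat shift by the same
#' constant.
#'
#' @param record a `bp_waveform` for one activity session.
#' @param triplet the session's brachial triplet.
#' @param rest_window numeric length-2, the pre-activity rest in session
#'   seconds.
#' @param mask optional sample artifact mask (see [filter_artifacts()]).
#' @return list with `record` (shifted `bp_waveform`) and `offset` (mmHg).
#' @export
calibrate_reference_waveform <- function(record, triplet,
                                         rest_window = c(0, 240),
                                         mask = NULL) {
  beats <- extract_beats(record, mask = mask)
  off <- reference_calibration_offset(beats, triplet, rest_window)
  record$pressure <- record$pressure + off
  list(record = record, offset = off)
}

#' Reference calibration offset from an extracted beat series
#'
#' Same arithmetic as [calibrate_reference_waveform()], operating on an
#' already-extracted beat series: shifting the record by `+c` shifts every
#' beat's SBP/DBP/MAP by exactly `+c`, so the offset may equivalently be
#' added to derived beat or segment values.
#'
#' @param beats a `bp_beats` data.frame.
#' @inheritParams calibrate_reference_waveform
#' @return the additive offset, mmHg.
#' @export
reference_calibration_offset <- function(beats, triplet,
                                         rest_window = c(0, 240)) {
  cal <- brachial_calibration_value(triplet, "sbp")
  sel <- beats$ok & beats$start >= rest_window[1] & beats$start < rest_window[2]
  if (!any(sel))
    stop_cf("no accepted beats in the rest window [%.0f, %.0f) s",
            rest_window[1], rest_window[2])
  cal - mean(beats$sbp[sel])
}

#' One-time offset calibration of the device estimates
#'
#' Per BP parameter, the offset `reference anchor value - device anchor
#' value` is computed over the anchor window of the subject's first session
#' (by default the last 60 s of the initial 4-min rest before the handgrip
#' activity) and applied additively to **all** of the subject's device
#' segments, across every session and day. The calibration is performed
#' exactly once per subject: a second call on already-calibrated segments is
#' rejected.
#'
#' @param device data.frame of the subject's device segment estimates:
#'   columns `window_start`, `sbp`, `dbp`, `map`, and `session_key`
#'   identifying the session (the smallest key is the anchor session; if
#'   absent, all rows are assumed to belong to the first session).
#' @param reference matching data.frame of calibrated reference segment
#'   values (same columns; joined on `session_key` + `window_start`).
#' @param anchor_window numeric length-2, anchor window in session seconds.
#' @return list with `offset` (named mmHg vector, one per parameter),
#'   `anchor_n` (segments used) and `device` (the shifted table, flagged
#'   calibrated).
#' @export
calibrate_device_once <- function(device, reference,
                                  anchor_window = c(180, 240)) {
  if (isTRUE(attr(device, "calibrated")))
    stop_cf("device segments are already calibrated; the one-point calibration is never repeated")
  if (is.null(device$session_key)) device$session_key <- 1L
  if (is.null(reference$session_key)) reference$session_key <- 1L
  first <- min(device$session_key)
  key <- paste(device$session_key, device$window_start)
  rkey <- paste(reference$session_key, reference$window_start)
  m <- match(key, rkey)
  anchor <- device$session_key == first &
    device$window_start >= anchor_window[1] &
    device$window_start < anchor_window[2] & !is.na(m)
  offset <- c(sbp = NA_real_, dbp = NA_real_, map = NA_real_)
  for (p in names(offset)) {
    ok <- anchor & is.finite(device[[p]]) & is.finite(reference[[p]][m])
    if (!any(ok))
      stop_cf("subject uncalibratable: no anchor segments with both device and reference %s", p)
    offset[[p]] <- mean(reference[[p]][m[ok]]) - mean(device[[p]][ok])
  }
  for (p in names(offset)) device[[p]] <- device[[p]] + offset[[p]]
  attr(device, "calibrated") <- TRUE
  list(offset = offset, anchor_n = sum(anchor), device = device)
}
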