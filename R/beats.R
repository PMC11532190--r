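#' Waveform record container
#'
#' One activity session's uniformly sampled pressure trace with its ECG R-peak
#' times. Sample `i` is at time `(i-1)/sampling_rate` in session seconds.
#'
#' @param pressure numeric vector of pressure samples, mmHg.
#' @param sampling_rate sampling rate, Hz (> 0).
#' @param rpeaks strictly increasing R-peak times, seconds, within the
#'   sampled span.
#' @param activity,subject,day session labels.
#' @return A `bp_waveform` object.
#' @export
bp_waveform <- function(pressure, sampling_rate, rpeaks,
                        activity = "rest", subject = "s", day = 1L) {
  stopifnot(is.numeric(pressure), length(pressure) >= 2L, sampling_rate > 0)
  if (length(rpeaks) && any(diff(rpeaks) <= 0))
    stop_cf("R-peak times must be strictly increasing")
  # the final R-peak may sit one sample step past the last sample: it closes
  # the last cycle's half-open window
  span <- length(pressure) / sampling_rate
  if (length(rpeaks) && (min(rpeaks) < 0 || max(rpeaks) > span + 1 / sampling_rate + 1e-9))
    stop_cf("R-peak times must lie within the sampled span [0, %.3f] s", span)
  structure(list(pressure = as.numeric(pressure),
                 sampling_rate = sampling_rate,
                 rpeaks = as.numeric(rpeaks),
                 activity = activity, subject = as.character(subject),
                 day = as.integer(day), artifact = NULL),
            class = "bp_waveform")
}

#' @export
print.bp_waveform <- function(x, ...) {
  cat(sprintf("<bp_waveform> %s day %d %s: %.1f s @ %g Hz, %d R-peaks\n",
              x$subject, x$day, x$activity,
              length(x$pressure) / x$sampling_rate, x$sampling_rate,
              length(x$rpeaks)))
  invisible(x)
}

#' Split a record into cardiac-cycle windows
#'
#' One half-open window `[R_i, R_{i+1})` per consecutive R-peak pair; the
#' trailing partial cycle (after the last R-peak) is discarded.
#'
#' @param record a `bp_waveform`.
#' @return data.frame with `start`, `end` (seconds); zero rows with a warning
#'   when fewer than 2 R-peaks are present.
#' @export
segment_cycles <- function(record) {
  stopifnot(inherits(record, "bp_waveform"))
  r <- record$rpeaks
  if (length(r) < 2L) {
    warning("fewer than 2 R-peaks: no complete cardiac cycle")
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  data.frame(start = r[-length(r)], end = r[-1L])
}

#' Per-beat heart rate from R-peak times
#'
#' @param rpeaks strictly increasing R-peak times, seconds (>= 2).
#' @return numeric vector, `60 / diff(rpeaks)` beats/min.
#' @export
compute_hr <- function(rpeaks) {
  if (length(rpeaks) < 2L) stop_cf("need at least 2 R-peaks")
  if (any(diff(rpeaks) <= 0)) stop_cf("R-peak times must be strictly increasing")
  60 / diff(rpeaks)
}

#' Beat-level blood pressure from one cycle's samples
#'
#' SBP is the cycle maximum, DBP the minimum, and MAP the time-weighted
#' (trapezoidal) integral of pressure over the cycle divided by the sampled
#' cycle duration.
#'
#' @param samples pressure samples of one cardiac cycle (uniform spacing).
#' @param sampling_rate sampling rate, Hz.
#' @return list with `sbp`, `dbp`, `map`, `ok` (FALSE when any sample is
#'   non-finite).
#' @export
compute_beat_bp <- function(samples, sampling_rate) {
  if (length(samples) < 2L) stop_cf("a cycle needs at least 2 samples")
  if (!all(is.finite(samples)))
    return(list(sbp = NA_real_, dbp = NA_real_, map = NA_real_, ok = FALSE))
  n <- length(samples)
  map <- (sum(samples) - (samples[1] + samples[n]) / 2) / (n - 1)
  list(sbp = max(samples), dbp = min(samples), map = map, ok = TRUE)
}

#' Extract the full per-beat series from a record
#'
#' Vectorized beat extraction: every sample is assigned to its half-open
#' cycle `[R_i, R_{i+1})`; per cycle, SBP/DBP/MAP follow [compute_beat_bp()]
#' and HR is `60 / (R_{i+1} - R_i)`. A beat fails quality (`ok = FALSE`) if
#' it contains a non-finite or masked sample or fewer than 2 samples.
#'
#' @param record a `bp_waveform`.
#' @param mask optional logical vector over samples (`TRUE` = artifact), as
#'   from [filter_artifacts()].
#' @return A `bp_beats` data.frame: `start`, `end`, `sbp`, `dbp`, `map`,
#'   `hr`, `n_samples`, `ok`.
#' @export
extract_beats <- function(record, mask = NULL) {
  cycles <- segment_cycles(record)
  empty <- data.frame(start = numeric(0), end = numeric(0), sbp = numeric(0),
                      dbp = numeric(0), map = numeric(0), hr = numeric(0),
                      n_samples = integer(0), ok = logical(0))
  class(empty) <- c("bp_beats", "data.frame")
  if (nrow(cycles) == 0L) return(empty)
  p <- record$pressure
  t <- (seq_along(p) - 1) / record$sampling_rate
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(p))
    p[mask] <- NA_real_
  }
  cyc <- findInterval(t, record$rpeaks)
  keep <- cyc >= 1L & cyc <= nrow(cycles) & t < record$rpeaks[length(record$rpeaks)]
  dtb <- data.table(cyc = cyc[keep], p = p[keep])
  agg <- dtb[, {
    fin <- all(is.finite(p)) && .N >= 2L
    if (fin) {
      m <- (sum(p) - (p[1L] + p[.N]) / 2) / (.N - 1L)
      list(sbp = max(p), dbp = min(p), map = m, n_samples = .N, ok = TRUE)
    } else {
      list(sbp = NA_real_, dbp = NA_real_, map = NA_real_,
           n_samples = .N, ok = FALSE)
    }
  }, by = cyc]
  out <- data.frame(start = cycles$start[agg$cyc], end = cycles$end[agg$cyc])
  out$sbp <- agg$sbp; out$dbp <- agg$dbp; out$map <- agg$map
  out$hr <- 60 / (out$end - out$start)
  out$n_samples <- agg$n_samples
  out$ok <- agg$ok & agg$n_samples >= 2L
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bp_beats", "data.frame")
  out
}

#' Artifact mask over waveform samples
#'
#' Flags (a) flat-line runs — absolute sample-to-sample change below
#' `flat_eps` for at least `flat_run` seconds, mimicking the finger cuff's
#' self-calibration gaps; (b) physiologically impossible samples outside
#' `range`; and (c) 1-second windows whose high-frequency band power (above
#' `hf_cutoff` Hz, via moving-average high-pass) exceeds `hf_ratio` of the
#' window's total variance. The high-frequency rule is skipped when the
#' sampling rate cannot resolve the band.
#'
#' @param record a `bp_waveform`.
#' @param flat_run minimum flat-line duration, seconds.
#' @param flat_eps flat-line derivative tolerance, mmHg per sample.
#' @param range plausible pressure range, mmHg.
#' @param hf_cutoff high-frequency cutoff, Hz.
#' @param hf_ratio band-power ratio threshold.
#' @param hf_window window for the band-power rule, seconds.
#' @return logical vector over samples; `TRUE` marks an artifact.
#' @export
filter_artifacts <- function(record, flat_run = 0.5, flat_eps = 1e-3,
                             range = c(20, 300), hf_cutoff = 20,
                             hf_ratio = 0.3, hf_window = 1) {
  stopifnot(inherits(record, "bp_waveform"))
  p <- record$pressure
  fs <- record$sampling_rate
  n <- length(p)
  bad <- !is.finite(p) | p < range[1] | p > range[2]

  # flat-line runs
  flat_diff <- abs(diff(p)) < flat_eps
  r <- rle(flat_diff)
  min_d <- ceiling(flat_run * fs) - 1L      # diffs spanning >= flat_run s
  pos <- cumsum(c(1L, r$lengths))
  for (k in which(r$values & r$lengths >= min_d)) {
    bad[pos[k]:(pos[k] + r$lengths[k])] <- TRUE   # +1 sample closes the run
  }

  # high-frequency band power per non-overlapping window
  if (fs > 2 * hf_cutoff) {
    w <- max(3L, round(fs / hf_cutoff))
    if (w %% 2L == 0L) w <- w + 1L
    ma <- stats::filter(p, rep(1 / w, w), sides = 2)
    hp <- p - ma
    hp[is.na(hp)] <- 0
    wlen <- max(2L, round(hf_window * fs))
    starts <- seq(1L, n, by = wlen)
    for (s0 in starts) {
      span <- s0:min(s0 + wlen - 1L, n)
      tot <- sum((p[span] - mean(p[span]))^2)
      if (tot > 1e-8 && sum(hp[span]^2) / tot > hf_ratio) bad[span] <- TRUE
    }
  }
  bad
}

#' Aggregate a beat series into non-overlapping 15-second segments
#'
#' Each accepted beat is assigned to the window containing its cycle start;
#' the window value is the unweighted mean over accepted beats. Windows are
#' aligned to session start (exact multiples of `window` seconds) and a final
#' partial window is dropped. A window with no accepted beat is flagged
#' missing (values `NA`), never zero.
#'
#' A window is also flagged missing when fewer than `min_beat_fraction` of
#' its beats are accepted: a 15-s mean computed from a small minority of the
#' window's cardiac cycles is not a credible segment value.
#'
#' @param beats a `bp_beats` data.frame (or truth beats with the same
#'   columns; a missing `ok` column is treated as all-accepted).
#' @param session_duration session length, seconds; defaults to the last
#'   beat's end time.
#' @param window segment length, seconds (default 15).
#' @param min_beat_fraction minimum fraction of a window's beats that must
#'   be accepted for the window to count (default 0.5).
#' @return A `bp_segments` data.frame: `window_start`, `sbp`, `dbp`, `map`,
#'   `hr`, `n_beats`, `missing`.
#' @export
aggregate_segments <- function(beats, session_duration = NULL, window = 15,
                               min_beat_fraction = 0.5) {
  stopifnot(is.data.frame(beats))
  if (is.null(beats$ok)) beats$ok <- TRUE
  if (nrow(beats) && is.unsorted(beats$start)) beats <- beats[order(beats$start), ]
  dur <- session_duration %||% if (nrow(beats)) max(beats$end) else 0
  n_win <- floor(dur / window + 1e-9)
  starts <- (seq_len(n_win) - 1L) * window
  out <- data.frame(window_start = starts, sbp = NA_real_, dbp = NA_real_,
                    map = NA_real_, hr = NA_real_, n_beats = 0L,
                    missing = TRUE)
  w_all <- floor(beats$start / window) + 1L
  total <- tabulate(w_all[w_all >= 1L & w_all <= n_win], nbins = n_win)
  acc <- beats[beats$ok & is.finite(beats$sbp), , drop = FALSE]
  if (nrow(acc)) {
    w <- floor(acc$start / window) + 1L
    sel <- w >= 1L & w <= n_win
    acc <- acc[sel, , drop = FALSE]; w <- w[sel]
    if (nrow(acc)) {
      dtb <- data.table(w = w, sbp = acc$sbp, dbp = acc$dbp,
                        map = acc$map, hr = acc$hr)
      agg <- dtb[, .(sbp = mean(sbp), dbp = mean(dbp), map = mean(map),
                     hr = mean(hr), n_beats = .N), by = w]
      enough <- agg$n_beats >= min_beat_fraction * total[agg$w]
      agg <- agg[enough, ]
      if (nrow(agg)) {
        out$sbp[agg$w] <- agg$sbp; out$dbp[agg$w] <- agg$dbp
        out$map[agg$w] <- agg$map; out$hr[agg$w] <- agg$hr
        out$n_beats[agg$w] <- agg$n_beats
        out$missing[agg$w] <- FALSE
      }
    }
  }
  class(out) <- c("bp_segments", "data.frame")
  out
}

#' Subject-level exclusion rule
#'
#' A subject is excluded when strictly more than 50% of their reference data
#' (counted in 15-second segments, the analysis unit) had to be removed.
#'
#' @param segments optional `bp_segments` (or list of them) from which
#'   removed/total counts are taken (`missing` segments count as removed).
#' @param removed,total alternatively, the counts directly.
#' @param threshold removal fraction above which the subject is excluded.
#' @return list with `excluded` (logical), `fraction_removed`, `removed`,
#'   `total` and `reason` (`"ok"`, `"removed_fraction"`, `"no_data"`).
#' @export
subject_exclusion <- function(segments = NULL, removed = NULL, total = NULL,
                              threshold = 0.5) {
  if (!is.null(segments)) {
    if (is.data.frame(segments)) segments <- list(segments)
    total <- sum(vapply(segments, nrow, 0L))
    removed <- sum(vapply(segments, function(s) sum(s$missing), 0L))
  }
  stopifnot(!is.null(removed), !is.null(total))
  if (total == 0L)
    return(list(excluded = TRUE, fraction_removed = NA_real_,
                removed = 0L, total = 0L, reason = "no_data"))
  frac <- removed / total
  excl <- frac > threshold           # strictly greater: exactly 50% retained
  list(excluded = excl, fraction_removed = frac,
       removed = as.integer(removed), total = as.integer(total),
       reason = if (excl) "removed_fraction" else "ok")
}
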