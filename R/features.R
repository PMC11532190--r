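FEATURE_NAMES <- c("pulse_amp", "width50", "rise_time", "decay_time",
                   "max_slope", "refl_index", "hr_mean")

#' Morphological features of a single pulse
#'
#' @param samples one pulse's samples (uniform spacing, >= 3).
#' @param sampling_rate sampling rate, Hz.
#' @return named numeric vector: `pulse_amp` (signal units), `width50` (s,
#'   width at half amplitude via linear interpolation), `rise_time` (s, foot
#'   to peak), `decay_time` (s, peak to end), `max_slope` (units/s),
#'   `refl_index` (late-half amplitude ratio). A constant pulse (amplitude
#'   ~0) returns all-`NA`.
#' @export
pulse_features <- function(samples, sampling_rate) {
  n <- length(samples)
  if (n < 3L) stop_cf("a pulse needs at least 3 samples")
  dt <- 1 / sampling_rate
  lo <- min(samples); hi <- max(samples); amp <- hi - lo
  if (!is.finite(amp) || amp < 1e-9)
    return(setNames(rep(NA_real_, 6L), FEATURE_NAMES[1:6]))
  k <- which.max(samples)
  half <- lo + amp / 2
  cross_up <- function() {
    for (i in seq_len(k - 1L)) {
      if (samples[i] <= half && samples[i + 1L] > half)
        return((i - 1L + (half - samples[i]) / (samples[i + 1L] - samples[i])) * dt)
    }
    0
  }
  cross_down <- function() {
    for (i in seq(n - 1L, k)) {
      if (samples[i] >= half && samples[i + 1L] < half)
        return((i - 1L + (samples[i] - half) / (samples[i] - samples[i + 1L])) * dt)
    }
    (n - 1L) * dt
  }
  second_half <- samples[seq.int(ceiling(n / 2), n)]
  c(pulse_amp = amp,
    width50 = cross_down() - cross_up(),
    rise_time = (k - 1L) * dt,
    decay_time = (n - k) * dt,
    max_slope = max(diff(samples)) / dt,
    refl_index = (max(second_half) - lo) / amp)
}

#' Extract per-segment PPG-style features
#'
#' Two input forms are accepted, matching the two device dialects:
#'
#' * a `bp_waveform` (a PPG-like pulse train): per-cycle morphological
#'   features ([pulse_features()]) plus heart rate, averaged over accepted
#'   pulses within each non-overlapping 15-s segment;
#' * a generator feature stream (data.frame with `window_start` plus feature
#'   columns, as from [simulate_ppg_features()]): validated and flagged.
#'
#' Segments with no accepted pulse, or any non-finite feature, are flagged
#' unusable (`missing = TRUE`).
#'
#' @param x a `bp_waveform` or feature-stream data.frame.
#' @param mask optional sample artifact mask (waveform path only).
#' @param window segment length, seconds.
#' @param session_duration session length, seconds (waveform path; defaults
#'   to the sampled span).
#' @return data.frame: `window_start`, the feature columns, `missing`.
#' @export
extract_features <- function(x, mask = NULL, window = 15,
                             session_duration = NULL) {
  if (is.data.frame(x)) {
    if (!"window_start" %in% names(x))
      stop_cf("a feature stream needs a `window_start` column")
    feat <- setdiff(names(x), c("window_start", "missing"))
    x$missing <- !apply(is.finite(as.matrix(x[, feat, drop = FALSE])), 1L, all)
    return(x[, c("window_start", feat, "missing")])
  }
  stopifnot(inherits(x, "bp_waveform"))
  cycles <- segment_cycles(x)
  dur <- session_duration %||% (length(x$pressure) / x$sampling_rate)
  n_win <- floor(dur / window + 1e-9)
  out <- data.frame(window_start = (seq_len(n_win) - 1L) * window)
  for (f in FEATURE_NAMES) out[[f]] <- NA_real_
  out$missing <- TRUE
  if (nrow(cycles) == 0L || n_win == 0L) return(out)
  p <- x$pressure
  if (!is.null(mask)) p[mask] <- NA_real_
  t <- (seq_along(p) - 1) / x$sampling_rate
  cyc <- findInterval(t, x$rpeaks)
  feats <- matrix(NA_real_, nrow(cycles), 6L,
                  dimnames = list(NULL, FEATURE_NAMES[1:6]))
  for (i in seq_len(nrow(cycles))) {
    s <- p[cyc == i]
    if (length(s) >= 3L && all(is.finite(s)))
      feats[i, ] <- pulse_features(s, x$sampling_rate)
  }
  hr <- 60 / (cycles$end - cycles$start)
  w <- floor(cycles$start / window) + 1L
  accepted <- apply(is.finite(feats), 1L, all)
  for (wi in seq_len(n_win)) {
    sel <- accepted & w == wi
    if (!any(sel)) next
    out[wi, FEATURE_NAMES[1:6]] <- colMeans(feats[sel, , drop = FALSE])
    out[wi, "hr_mean"] <- mean(hr[sel])
    out[wi, "missing"] <- FALSE
  }
  out
}
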