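# Parametric pulse template: raised-cosine systolic upstroke over the first
# 30% of the cycle, exponential decay (rate constant DECAY_RATE over the
# remaining 70%) returning exactly to diastolic pressure at cycle end.
UPSTROKE_FRAC <- 0.3
DECAY_RATE <- 3

pulse_template <- function(u, sbp, dbp) {
  pp <- sbp - dbp
  out <- numeric(length(u))
  up <- u < UPSTROKE_FRAC
  out[up] <- dbp[up] + pp[up] * (1 - cos(pi * u[up] / UPSTROKE_FRAC)) / 2
  v <- (u[!up] - UPSTROKE_FRAC) / (1 - UPSTROKE_FRAC)
  out[!up] <- dbp[!up] + pp[!up] *
    (exp(-DECAY_RATE * v) - exp(-DECAY_RATE)) / (1 - exp(-DECAY_RATE))
  out
}

# Analytic time-weighted mean of the template as a fraction of pulse pressure
# above DBP; used by the trajectory stage before any waveform exists.
template_form_factor <- function() {
  s <- DECAY_RATE
  decay_mean <- ((1 - exp(-s)) / s - exp(-s)) / (1 - exp(-s))
  UPSTROKE_FRAC * 0.5 + (1 - UPSTROKE_FRAC) * decay_mean
}

# Stationary AR(1) noise, coefficient `phi`, marginal SD `sd`.
ar1_noise <- function(n, sd, phi = 0.7) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(numeric(n))
  z <- rnorm(n)
  e <- numeric(n)
  e[1] <- z[1]
  innov <- sqrt(1 - phi^2)
  for (k in seq_len(n - 1L)) e[k + 1L] <- phi * e[k] + innov * z[k + 1L]
  sd * e
}

#' Simulate a beat-to-beat true blood-pressure trajectory
#'
#' Generates per-beat true SBP/DBP/MAP/HR series for every session of a
#' protocol. Beat times follow the instantaneous heart rate; each activity
#' adds a smooth (linear 20-s onset/offset) response ramp on top of the
#' subject's baseline; beat-level noise is stationary AR(1) (coefficient 0.7).
#' Handgrip raises SBP and DBP together, mental stress predominantly SBP and
#' HR, the cold pressor ramps SBP rapidly within the immersion — all governed
#' by the per-activity amplitudes in `params`.
#'
#' @param params a [subject_params()] object.
#' @param protocol a [bp_protocol()] object.
#' @param day day index attached to the sessions (1 or 2).
#' @param seed RNG seed; defaults to the subject's own seed.
#' @return A `bp_trajectory`: list of sessions, each with `activity`, `day`,
#'   `duration` and a `beats` data.frame (`start`, `end`, `sbp`, `dbp`,
#'   `map`, `hr`). MAP here is the analytic template mean
#'   `dbp + 0.347 * (sbp - dbp)`; [simulate_waveform()] replaces it with the
#'   time-weighted mean of the emitted samples.
#' @export
simulate_bp_trajectory <- function(params, protocol, day = 1L,
                                   seed = params$seed) {
  stopifnot(inherits(params, "bp_subject_params"),
            inherits(protocol, "bp_protocol"))
  if (sum(vapply(protocol$sessions, `[[`, 0, "total_duration")) <= 0)
    stop_cf("protocol has zero total duration: nothing to simulate")
  ff <- template_form_factor()
  seeds <- derive_seeds(seed, length(protocol$sessions))
  sessions <- vector("list", length(protocol$sessions))
  for (i in seq_along(protocol$sessions)) {
    ses <- protocol$sessions[[i]]
    amp <- params$amplitudes[[ses$activity]]
    if (is.null(amp))
      stop_cf("no response amplitudes for activity '%s'", ses$activity)
    sessions[[i]] <- with_seed(seeds[i], {
      dur <- ses$total_duration
      # beat onsets from instantaneous HR (upper-bound allocation, then trim)
      n_max <- ceiling(dur / (60 / (params$hr_base + amp[["hr"]] + 40))) + 8L
      hr_noise <- ar1_noise(n_max, params$hr_noise_sd)
      t_beat <- numeric(n_max)
      k <- 1L
      while (t_beat[k] < dur && k < n_max) {
        hr_k <- params$hr_base + amp[["hr"]] * session_response(ses, t_beat[k]) +
          hr_noise[k]
        hr_k <- max(hr_k, 30)
        t_beat[k + 1L] <- t_beat[k] + 60 / hr_k
        k <- k + 1L
      }
      onsets <- t_beat[seq_len(k)]        # last onset is >= dur: cycle ends
      nb <- k - 1L
      if (nb < 1L) stop_cf("session too short for a single beat")
      start <- onsets[seq_len(nb)]; end <- onsets[seq_len(nb) + 1L]
      resp <- session_response(ses, start)
      sbp <- params$sbp_base + amp[["sbp"]] * resp +
        ar1_noise(nb, params$noise_sd)
      dbp <- params$dbp_base + amp[["dbp"]] * resp +
        ar1_noise(nb, params$dbp_noise_frac * params$noise_sd)
      dbp <- pmin(dbp, sbp - 5)           # keep pulse pressure physiological
      beats <- data.frame(start = start, end = end, sbp = sbp, dbp = dbp,
                          map = dbp + ff * (sbp - dbp), hr = 60 / (end - start))
      list(activity = ses$activity, day = as.integer(day), duration = dur,
           rest = ses$rest, beats = beats)
    })
  }
  structure(list(sessions = sessions, subject = params$id),
            class = "bp_trajectory")
}

#' Synthesize a continuous pressure waveform from a beat series
#'
#' Emits uniformly sampled pressure for one session using the parametric pulse
#' template. Within each cardiac cycle the sample closest to the template peak
#' is set to that beat's true SBP and the minimum sample to its true DBP, so
#' the sampled extrema equal the truth exactly at any rate. R-peak times (the
#' cycle onsets) are emitted alongside.
#'
#' @param beats data.frame with `start`, `end`, `sbp`, `dbp` (one session),
#'   as produced by [simulate_bp_trajectory()].
#' @param sampling_rate sampling rate in Hz, >= 100.
#' @param activity,subject,day labels stored on the record.
#' @return A list: `record` (a `bp_waveform`) and `beats` (the input with
#'   `map` replaced by the time-weighted trapezoidal mean of the emitted
#'   samples per cycle).
#' @export
simulate_waveform <- function(beats, sampling_rate = 250,
                              activity = "rest", subject = "s", day = 1L) {
  stopifnot(is.data.frame(beats), nrow(beats) >= 1L)
  if (sampling_rate < 100) stop_cf("sampling_rate must be >= 100 Hz")
  dt <- 1 / sampling_rate
  if (any(beats$end - beats$start < 2 * dt))
    stop_cf("beat shorter than 2 samples at %.0f Hz", sampling_rate)
  t_end <- beats$end[nrow(beats)]
  t <- seq(0, t_end - dt / 2, by = dt)
  idx <- findInterval(t, beats$start)          # cycle index per sample
  idx[idx < 1L] <- 1L
  u <- (t - beats$start[idx]) / (beats$end[idx] - beats$start[idx])
  u <- pmin(pmax(u, 0), 1 - 1e-12)
  p <- pulse_template(u, beats$sbp[idx], beats$dbp[idx])

  dtb <- data.table(i = seq_along(p), cyc = idx, p = p, u = u)
  # snap per-cycle extrema to the exact truth values
  peaks <- dtb[, .(imax = .I[which.max(p)][1], imin = .I[which.min(p)][1]),
               by = cyc]
  p[peaks$imax] <- beats$sbp[peaks$cyc]
  p[peaks$imin] <- beats$dbp[peaks$cyc]

  rpeaks <- c(beats$start, t_end)
  record <- bp_waveform(pressure = p, sampling_rate = sampling_rate,
                        rpeaks = rpeaks, activity = activity,
                        subject = subject, day = day)
  extracted <- extract_beats(record)
  out <- beats
  if (nrow(extracted) == nrow(beats)) out$map <- extracted$map
  list(record = record, beats = out)
}

#' Simulate a triplet of brachial cuff readings during a rest window
#'
#' Three (SBP, DBP) readings spaced 1 min apart within the pre-activity rest;
#' each reading is the mean of the true beat series over the 30 s preceding
#' its timestamp, plus independent reading noise.
#'
#' @param beats session truth beat data.frame (`start`, `sbp`, `dbp`).
#' @param rest_window numeric length-2, rest start/end in session seconds;
#'   must span at least 3 minutes.
#' @param noise_sd cuff reading noise SD, mmHg.
#' @param seed RNG seed.
#' @return A `bp_brachial_triplet`: data.frame with `time`, `sbp`, `dbp`.
#' @export
simulate_brachial_readings <- function(beats, rest_window = c(0, 240),
                                       noise_sd = 2, seed = NULL) {
  stopifnot(length(rest_window) == 2L)
  if (diff(rest_window) < 180)
    stop_cf("rest window must span at least 3 minutes for three 1-min-spaced readings")
  times <- rest_window[1] + c(60, 120, 180)
  with_seed(seed, {
    vals <- vapply(times, function(tt) {
      sel <- beats$start >= tt - 30 & beats$start < tt
      if (!any(sel)) stop_cf("no beats in the 30-s averaging window before t=%.0f s", tt)
      c(mean(beats$sbp[sel]), mean(beats$dbp[sel]))
    }, numeric(2))
    out <- data.frame(time = times,
                      sbp = vals[1, ] + rnorm(3, 0, noise_sd),
                      dbp = vals[2, ] + rnorm(3, 0, noise_sd))
    class(out) <- c("bp_brachial_triplet", "data.frame")
    out
  })
}

#' Default linear map from segment BP/HR state to PPG-style features
#'
#' Each of the seven features is an affine function of the segment-mean state
#' `(sbp, dbp, map, hr)`; coefficients carry plausible physiological signs
#' (pulse amplitude tracks pulse pressure, widths shorten with heart rate,
#' rise time shortens with systolic pressure, the reflection-index surrogate
#' falls with mean pressure). The map has rank 4, so a linear regressor can in
#' principle recover all three pressures and heart rate.
#'
#' @return list with `intercept` (length 7) and `M` (7 x 4 matrix, columns
#'   sbp, dbp, map, hr).
#' @export
default_feature_map <- function() {
  M <- rbind(
    pulse_amp  = c(sbp =  0.012, dbp = -0.012, map =  0,      hr =  0),
    width50    = c(sbp =  0,     dbp =  0,     map = -5e-4,   hr = -0.002),
    rise_time  = c(sbp = -6e-4,  dbp =  0,     map =  0,      hr =  0),
    decay_time = c(sbp =  0,     dbp = -4e-4,  map =  0,      hr = -0.002),
    max_slope  = c(sbp =  0.004, dbp = -0.002, map =  0,      hr =  0),
    refl_index = c(sbp =  0,     dbp =  0,     map = -0.003,  hr =  0),
    hr_mean    = c(sbp =  0,     dbp =  0,     map =  0,      hr =  1)
  )
  list(intercept = c(pulse_amp = 0, width50 = 0.45, rise_time = 0.2,
                     decay_time = 0.55, max_slope = 0, refl_index = 0.8,
                     hr_mean = 0),
       M = M,
       noise_sd = c(pulse_amp = 0.005, width50 = 0.005, rise_time = 0.002,
                    decay_time = 0.005, max_slope = 0.002, refl_index = 0.005,
                    hr_mean = 0.5))
}

#' Simulate a per-segment PPG-style feature stream
#'
#' Applies a linear (affine) feature map to the per-segment BP/HR state and
#' adds independent Gaussian feature noise. With zero noise and an
#' identity-like map, a feature reproduces the segment-mean state exactly.
#'
#' @param segments data.frame with `window_start`, `sbp`, `dbp`, `map`, `hr`
#'   (segment means of the state driving the device).
#' @param feature_map list as from [default_feature_map()].
#' @param noise_sd per-feature noise SD; scalar, named vector matching the
#'   feature names, or `NULL` for the map's own defaults.
#' @param seed RNG seed.
#' @return data.frame: `window_start` plus one column per feature.
#' @export
simulate_ppg_features <- function(segments, feature_map = default_feature_map(),
                                  noise_sd = NULL, seed = NULL) {
  M <- feature_map$M
  stopifnot(is.matrix(M), ncol(M) == 4L)
  need <- c("sbp", "dbp", "map", "hr")
  if (!all(need %in% names(segments)))
    stop_cf("segments must contain columns %s", paste(need, collapse = ", "))
  noise_sd <- noise_sd %||% feature_map$noise_sd
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, nrow(M))
  if (length(noise_sd) != nrow(M))
    stop_cf("noise_sd length (%d) does not match the %d features",
            length(noise_sd), nrow(M))
  X <- as.matrix(segments[, need])
  F0 <- sweep(X %*% t(M), 2L, feature_map$intercept, `+`)
  with_seed(seed, {
    E <- matrix(rnorm(length(F0)), nrow(F0)) %*% diag(noise_sd, nrow(M))
    out <- data.frame(window_start = segments$window_start, F0 + E)
    names(out) <- c("window_start", rownames(M))
    out
  })
}

#' Inject artifacts into a waveform record
#'
#' The test-side inverse of artifact filtering: replaces a stated fraction of
#' samples with flat-line runs (mimicking the finger-cuff's periodic
#' self-calibration gaps) and/or additive high-frequency noise bursts. The
#' affected sample indices and their type are recorded on the returned object
#' (`$artifact`), so filter recall is computable against ground truth.
#'
#' @param record a `bp_waveform`.
#' @param fraction fraction of samples to corrupt, in `[0, 1]`.
#' @param pattern `"mixed"` (default), `"flatline"` or `"hfnoise"`.
#' @param seed RNG seed.
#' @return The corrupted `bp_waveform`, with `$artifact = list(idx, type)`.
#' @export
inject_artifacts <- function(record, fraction,
                             pattern = c("mixed", "flatline", "hfnoise"),
                             seed = NULL) {
  stopifnot(inherits(record, "bp_waveform"), fraction >= 0, fraction <= 1)
  pattern <- match.arg(pattern)
  n <- length(record$pressure)
  if (fraction == 0) {
    record$artifact <- list(idx = integer(0), type = character(0))
    return(record)
  }
  fs <- record$sampling_rate
  with_seed(seed, {
    target <- round(fraction * n)
    idx <- integer(0); type <- character(0)
    p <- record$pressure
    guard <- 0L
    while (length(idx) < target && guard < 10000L) {
      guard <- guard + 1L
      kind <- switch(pattern, mixed = sample(c("flatline", "hfnoise"), 1L),
                     flatline = "flatline", hfnoise = "hfnoise")
      len <- round(fs * if (kind == "flatline") 2 else 1)
      len <- min(len, target - length(idx) + round(0.25 * fs))
      if (len < 2L) len <- 2L
      s0 <- sample.int(max(n - len, 1L), 1L)
      span <- s0:min(s0 + len - 1L, n)
      if (kind == "flatline") p[span] <- p[span[1]]
      else p[span] <- p[span] + rnorm(length(span), 0, 25)
      idx <- union(idx, span); type <- c(type, kind)
    }
    record$pressure <- p
    record$artifact <- list(idx = sort(idx), type = type)
    record
  })
}
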