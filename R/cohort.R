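#' Simulate a complete protocol cohort
#'
#' Generates `n_subjects` independent synthetic subjects following the
#' three-activity laboratory protocol: per-session true beat series, sampled
#' pressure waveforms with R-peaks, brachial cuff triplets taken during each
#' pre-activity rest, per-15-s-segment PPG-style feature streams, and direct
#' device-side BP estimates under the configured error model. A configurable
#' subset of subjects (default 11 of 38) additionally performs a day-2
#' handgrip session.
#'
#' @param n_subjects number of subjects (>= 1; default 38).
#' @param protocol day-1 protocol, a [bp_protocol()] (default
#'   [default_protocol()]).
#' @param error_model a [device_error_model()].
#' @param seed master RNG seed; the whole cohort is bit-reproducible from it.
#' @param sampling_rate waveform sampling rate, Hz (default 250; see the
#'   methods vignette).
#' @param n_day2 number of subjects with a day-2 handgrip session; default
#'   `round(n_subjects * 11 / 38)`.
#' @param feature_map linear PPG feature map, see [default_feature_map()].
#' @param feature_noise_sd per-feature noise SD override (`NULL` = map
#'   defaults).
#' @param brachial_noise_sd cuff reading noise SD, mmHg.
#' @param noise_sd,hr_noise_sd subject beat-level noise SDs (mmHg /
#'   beats-per-min); set both to 0 (with a zero error model, zero feature
#'   and brachial noise) for a fully deterministic cohort.
#' @return A `bp_cohort`: list with `subjects` (each holding `params`,
#'   `day2`, and `sessions`, where every session carries the waveform, truth
#'   beats/segments, brachial triplet, feature stream and direct device
#'   estimates) plus the generating configuration.
#' @export
simulate_cohort <- function(n_subjects = 38L, protocol = default_protocol(),
                            error_model = device_error_model(), seed = 1L,
                            sampling_rate = 250, n_day2 = NULL,
                            feature_map = default_feature_map(),
                            feature_noise_sd = NULL, brachial_noise_sd = 2,
                            noise_sd = 3, hr_noise_sd = 2) {
  stopifnot(n_subjects >= 1L, inherits(protocol, "bp_protocol"),
            inherits(error_model, "bp_error_model"))
  n_day2 <- n_day2 %||% round(n_subjects * 11 / 38)
  n_day2 <- min(n_day2, n_subjects)
  ids <- sprintf("s%02d", seq_len(n_subjects))
  seeds <- derive_seeds(seed, n_subjects + 1L)
  day2_ids <- with_seed(seeds[n_subjects + 1L],
                        sort(sample(ids, n_day2)))
  subjects <- vector("list", n_subjects)
  names(subjects) <- ids
  for (i in seq_len(n_subjects)) {
    params <- draw_subject_params(ids[i], seeds[i], noise_sd = noise_sd,
                                  hr_noise_sd = hr_noise_sd)
    sub_seeds <- derive_seeds(params$seed, 4L)
    sessions <- simulate_subject_day(params, protocol, day = 1L,
                                     seed = sub_seeds[1],
                                     error_model = error_model,
                                     sampling_rate = sampling_rate,
                                     feature_map = feature_map,
                                     feature_noise_sd = feature_noise_sd,
                                     brachial_noise_sd = brachial_noise_sd,
                                     re_seed = sub_seeds[3])
    if (ids[i] %in% day2_ids) {
      sessions <- c(sessions,
                    simulate_subject_day(params, day2_protocol(), day = 2L,
                                         seed = sub_seeds[2],
                                         error_model = error_model,
                                         sampling_rate = sampling_rate,
                                         feature_map = feature_map,
                                         feature_noise_sd = feature_noise_sd,
                                         brachial_noise_sd = brachial_noise_sd,
                                         re_seed = sub_seeds[3]))
    }
    subjects[[i]] <- list(params = params, day2 = ids[i] %in% day2_ids,
                          sessions = sessions)
  }
  structure(list(subjects = subjects, protocol = protocol,
                 error_model = error_model, seed = seed,
                 sampling_rate = sampling_rate, feature_map = feature_map,
                 day2_ids = day2_ids),
            class = "bp_cohort")
}

# One simulated day for one subject: trajectory -> waveform -> truth segments
# -> brachial triplet -> device-corrupted state -> feature stream. The
# device's subject-level random effect is drawn from `re_seed`, shared across
# days (it is a property of device placement on that subject's arm, not of
# the day).
simulate_subject_day <- function(params, protocol, day, seed, error_model,
                                 sampling_rate, feature_map, feature_noise_sd,
                                 brachial_noise_sd, re_seed) {
  traj <- simulate_bp_trajectory(params, protocol, day = day, seed = seed)
  ses_seeds <- derive_seeds(seed + 1L, 3L * length(traj$sessions))
  re <- with_seed(re_seed, rnorm(3, 0, error_model$subject_sd))
  names(re) <- c("sbp", "dbp", "map")
  pause_between_sessions <- 450   # 5-10 min between activities; midpoint
  t_offset <- 0
  out <- vector("list", length(traj$sessions))
  for (j in seq_along(traj$sessions)) {
    ses <- traj$sessions[[j]]
    wf <- simulate_waveform(ses$beats, sampling_rate = sampling_rate,
                            activity = ses$activity, subject = params$id,
                            day = day)
    truth_beats <- wf$beats
    truth_segments <- aggregate_segments(truth_beats,
                                         session_duration = ses$duration)
    brachial <- simulate_brachial_readings(truth_beats,
                                           rest_window = c(0, ses$rest),
                                           noise_sd = brachial_noise_sd,
                                           seed = ses_seeds[3L * j - 2L])
    dev <- device_state(truth_segments, error_model, re = re, day = day,
                        t_day_offset = t_offset, seed = ses_seeds[3L * j - 1L])
    features <- simulate_ppg_features(dev, feature_map = feature_map,
                                      noise_sd = feature_noise_sd,
                                      seed = ses_seeds[3L * j])
    out[[j]] <- list(activity = ses$activity, day = day,
                     duration = ses$duration, rest = ses$rest,
                     t_day_offset = t_offset,
                     waveform = wf$record, truth_beats = truth_beats,
                     truth_segments = truth_segments, brachial = brachial,
                     device_state = dev, features = features)
    t_offset <- t_offset + ses$duration + pause_between_sessions
  }
  out
}

# The BP/HR state as sensed by the device: truth segments plus the error
# model (bias + subject random effect + drift + day-2 offset + segment
# noise); HR sensed with independent noise.
device_state <- function(truth_segments, error_model, re, day, t_day_offset,
                         seed = NULL) {
  em <- error_model
  n <- nrow(truth_segments)
  with_seed(seed, {
    t_h <- (t_day_offset + truth_segments$window_start) / 3600
    out <- truth_segments[, c("window_start", "sbp", "dbp", "map", "hr")]
    for (p in c("sbp", "dbp", "map")) {
      out[[p]] <- out[[p]] + em$bias[[p]] + re[[p]] +
        em$drift_per_hour[[p]] * t_h +
        (day == 2L) * em$day2_offset[[p]] +
        rnorm(n, 0, em$segment_sd[[p]])
    }
    out$hr <- out$hr + rnorm(n, 0, em$hr_noise_sd)
    out
  })
}

#' @export
print.bp_cohort <- function(x, ...) {
  n <- length(x$subjects)
  cat(sprintf("<bp_cohort> %d subject(s), %d with a day-2 session, seed %s\n",
              n, length(x$day2_ids), format(x$seed)))
  cat(sprintf("  sampling rate %g Hz, %d day-1 session(s) per subject\n",
              x$sampling_rate, length(x$protocol$sessions)))
  invisible(x)
}
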