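#' Per-subject simulation parameters
#'
#' Baselines and per-activity response amplitudes for one simulated subject.
#' All pressures in mmHg, heart rate in beats/min.
#'
#' @param id subject identifier (character).
#' @param sbp_base,dbp_base baseline systolic/diastolic pressure, mmHg
#'   (supine rest). Must satisfy `dbp_base < sbp_base`.
#' @param hr_base baseline heart rate, beats/min.
#' @param amplitudes named list with one entry per activity
#'   (`handgrip`, `mental_stress`, `cold_pressor`), each a numeric vector
#'   `c(sbp =, dbp =, hr =)` of non-negative peak responses.
#' @param noise_sd beat-level SBP noise SD, mmHg (AR(1), see vignette).
#' @param dbp_noise_frac DBP noise SD as a fraction of `noise_sd`.
#' @param hr_noise_sd beat-level HR noise SD, beats/min.
#' @param seed per-subject RNG seed (integer).
#' @return A `bp_subject_params` object.
#' @export
subject_params <- function(id, sbp_base = 119.3, dbp_base = 72.6, hr_base = 65,
                           amplitudes = NULL, noise_sd = 3,
                           dbp_noise_frac = 0.6, hr_noise_sd = 2, seed = 1L) {
  if (!(dbp_base < sbp_base))
    stop_cf("baseline DBP (%.1f) must be below baseline SBP (%.1f)",
            dbp_base, sbp_base)
  stopifnot(noise_sd >= 0, hr_noise_sd >= 0, hr_base > 0)
  if (is.null(amplitudes))
    amplitudes <- lapply(RESPONSE_TABLE, function(r) r[, "median"])
  for (a in names(amplitudes)) {
    v <- amplitudes[[a]]
    if (!all(c("sbp", "dbp", "hr") %in% names(v)))
      stop_cf("amplitudes[['%s']] must name sbp, dbp and hr", a)
    if (any(v < 0)) stop_cf("response amplitudes must be >= 0")
  }
  structure(list(id = as.character(id), sbp_base = sbp_base,
                 dbp_base = dbp_base, hr_base = hr_base,
                 amplitudes = amplitudes, noise_sd = noise_sd,
                 dbp_noise_frac = dbp_noise_frac, hr_noise_sd = hr_noise_sd,
                 seed = as.integer(seed)),
            class = "bp_subject_params")
}

# Cohort response-amplitude distributions (mmHg / bpm), calibrated so that the
# cohort medians of within-subject segment-level change reproduce the study
# conditions (handgrip ~25.5 / mental stress ~22.6 / cold pressor ~35.1 mmHg
# SBP, with matching DBP and HR summaries). `median` is the draw centre; `iqr`
# the draw IQR; draws are truncated at zero. Centres sit a few mmHg below the
# target change medians because beat noise widens the observed max-min range.
RESPONSE_TABLE <- list(
  handgrip = rbind(sbp = c(median = 16.2, iqr = 22.6),
                   dbp = c(median = 12.7, iqr = 11.6),
                   hr  = c(median = 13.5, iqr = 8.5)),
  mental_stress = rbind(sbp = c(median = 16.0, iqr = 15.1),
                        dbp = c(median = 9.3,  iqr = 9.0),
                        hr  = c(median = 18.0, iqr = 13.6)),
  cold_pressor = rbind(sbp = c(median = 29.8, iqr = 19.0),
                       dbp = c(median = 20.0, iqr = 12.2),
                       hr  = c(median = 12.8, iqr = 8.1))
)

# Draw heterogeneous subject parameters for a cohort. Baselines follow the
# cohort summary (SBP 119.3 (9.4), DBP 72.6 (7.1) mmHg); HR baseline N(65, 8).
draw_subject_params <- function(id, seed, noise_sd = 3, hr_noise_sd = 2,
                                dbp_noise_frac = 0.6) {
  with_seed(seed, {
    sbp0 <- rnorm(1, 119.3, 9.4)
    dbp0 <- min(rnorm(1, 72.6, 7.1), sbp0 - 25)
    hr0  <- max(rnorm(1, 65, 8), 45)
    amps <- lapply(RESPONSE_TABLE, function(tbl) {
      v <- pmax(0, rnorm(nrow(tbl), tbl[, "median"], tbl[, "iqr"] / 1.349))
      stats::setNames(v, rownames(tbl))
    })
    subject_params(id = id, sbp_base = sbp0, dbp_base = dbp0, hr_base = hr0,
                   amplitudes = amps, noise_sd = noise_sd,
                   dbp_noise_frac = dbp_noise_frac,
                   hr_noise_sd = hr_noise_sd, seed = derive_seeds(seed, 1L))
  })
}

#' Device error model
#'
#' Structural error applied to the simulated device's blood-pressure sensing
#' before PPG-style features are formed: a fixed bias, a per-subject random
#' effect, independent per-segment white noise, a slow linear drift, and an
#' extra day-2 offset exercising the Stability statistic. With every field
#' zero the simulated device reproduces the truth exactly.
#'
#' @param bias named vector `c(sbp=, dbp=, map=)`, fixed bias in mmHg.
#' @param subject_sd per-subject random-effect SD, mmHg (same names).
#' @param segment_sd per-15-s-segment white-noise SD, mmHg.
#' @param drift_per_hour linear drift, mmHg per hour of session time.
#' @param day2_offset additional additive offset on day-2 sessions, mmHg.
#' @param hr_noise_sd device-side HR sensing noise SD, beats/min.
#' @return A `bp_error_model` object.
#' @export
device_error_model <- function(
    bias       = c(sbp = 0.3, dbp = 0.04, map = 0.8),
    subject_sd = c(sbp = 6,   dbp = 4.5,  map = 5.5),
    segment_sd = c(sbp = 6,   dbp = 4.8,  map = 5.7),
    drift_per_hour = c(sbp = 0, dbp = 0, map = 0),
    day2_offset = c(sbp = 2, dbp = 2, map = 2),
    hr_noise_sd = 1) {
  par3 <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) x <- c(sbp = x, dbp = x, map = x)
    if (!all(c("sbp", "dbp", "map") %in% names(x)))
      stop_cf("`%s` must name sbp, dbp and map", what)
    x[c("sbp", "dbp", "map")]
  }
  bias <- par3(bias, "bias"); subject_sd <- par3(subject_sd, "subject_sd")
  segment_sd <- par3(segment_sd, "segment_sd")
  drift_per_hour <- par3(drift_per_hour, "drift_per_hour")
  day2_offset <- par3(day2_offset, "day2_offset")
  if (any(subject_sd < 0) || any(segment_sd < 0) || hr_noise_sd < 0)
    stop_cf("error-model SDs must be >= 0")
  structure(list(bias = bias, subject_sd = subject_sd, segment_sd = segment_sd,
                 drift_per_hour = drift_per_hour, day2_offset = day2_offset,
                 hr_noise_sd = hr_noise_sd),
            class = "bp_error_model")
}

#' Error model with every component zero (device reproduces truth exactly)
#' @return A `bp_error_model` whose simulated device equals the truth.
#' @export
zero_error_model <- function() {
  device_error_model(bias = 0, subject_sd = 0, segment_sd = 0,
                     drift_per_hour = 0, day2_offset = 0, hr_noise_sd = 0)
}
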