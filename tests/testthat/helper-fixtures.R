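# Shared fixtures and independent oracles, built in code at test time.

# Short two-activity protocol: full 4-min rests (so brachial triplets and the
# default calibration anchor stay valid) but brief activity blocks.
tiny_protocol <- function() {
  bp_protocol(list(
    protocol_session("handgrip", 60, reps = 1L, pause = 0, rest = 240,
                     recovery = 30),
    protocol_session("cold_pressor", 60, reps = 1L, pause = 0, rest = 240,
                     recovery = 30)
  ))
}

# Fully deterministic cohort: no beat/HR noise, no brachial or feature noise,
# zero device error. Every stochastic element left is the across-subject
# parameter draw, controlled by `seed`.
deterministic_cohort <- function(n = 6L, seed = 7L, protocol = tiny_protocol(),
                                 sampling_rate = 125, n_day2 = 1L) {
  simulate_cohort(n_subjects = n, protocol = protocol,
                  error_model = zero_error_model(), seed = seed,
                  sampling_rate = sampling_rate, n_day2 = n_day2,
                  feature_noise_sd = 0, brachial_noise_sd = 0,
                  noise_sd = 0, hr_noise_sd = 0)
}

# Memoized full-size default cohort (38 subjects), shared across test files.
full_cohort_cache <- new.env(parent = emptyenv())
full_cohort_cached <- function(seed) {
  key <- as.character(seed)
  if (is.null(full_cohort_cache[[key]]))
    full_cohort_cache[[key]] <- simulate_cohort(n_subjects = 38L, seed = seed)
  full_cohort_cache[[key]]
}

# Memoized pipeline run on the full default cohort.
full_result_cached <- function(seed) {
  key <- paste0("res", seed)
  if (is.null(full_cohort_cache[[key]]))
    full_cohort_cache[[key]] <- run_pipeline(full_cohort_cached(seed),
                                             run_config(seed = seed))
  full_cohort_cache[[key]]
}

# Constant-BP single-session beat table (rest-only analogue).
flat_beats <- function(n = 20L, sbp = 120, dbp = 80, rr = 1) {
  start <- (seq_len(n) - 1) * rr
  data.frame(start = start, end = start + rr, sbp = sbp, dbp = dbp,
             map = dbp + (sbp - dbp) / 3, hr = 60 / rr)
}

# --- independent oracles -------------------------------------------------

# Trapezoidal time-weighted mean of uniformly spaced samples.
trapz_mean_oracle <- function(x, dt) {
  area <- sum((x[-1] + x[-length(x)]) / 2) * dt
  area / (dt * (length(x) - 1))
}

# Two-pass mean/SD (n-1).
mean_sd_oracle <- function(d) {
  m <- sum(d) / length(d)
  list(mean = m, sd = sqrt(sum((d - m)^2) / (length(d) - 1)))
}

# Linear-interpolation percentile via full sort (R type-7 definition computed
# from first principles).
percentile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# One-way random-effects ICC via stats::aov sums of squares.
icc_aov_oracle <- function(values, subjects) {
  fit <- stats::aov(values ~ factor(subjects))
  ss <- summary(fit)[[1]]
  msb <- ss$`Mean Sq`[1]; msw <- ss$`Mean Sq`[2]
  n_i <- table(subjects); N <- length(values); a <- length(n_i)
  n0 <- (N - sum(n_i^2) / N) / (a - 1)
  vb <- (msb - msw) / n0
  vb / (vb + msw)
}
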