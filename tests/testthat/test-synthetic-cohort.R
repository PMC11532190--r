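test_that("zero-noise, zero-stimulus trajectory is exactly the baseline", {
  amps0 <- lapply(list(handgrip = 1, mental_stress = 1, cold_pressor = 1),
                  function(x) c(sbp = 0, dbp = 0, hr = 0))
  p <- subject_params("s1", sbp_base = 120, dbp_base = 80, hr_base = 60,
                      amplitudes = amps0, noise_sd = 0, hr_noise_sd = 0)
  tr <- simulate_bp_trajectory(p, tiny_protocol())
  for (ses in tr$sessions) {
    expect_true(all(ses$beats$sbp == 120))
    expect_true(all(ses$beats$dbp == 80))
    expect_equal(ses$beats$hr, rep(60, nrow(ses$beats)), tolerance = 1e-12)
  }
})

test_that("trajectory is bit-reproducible under a fixed seed", {
  p <- subject_params("s1", seed = 11L)
  a <- simulate_bp_trajectory(p, tiny_protocol())
  b <- simulate_bp_trajectory(p, tiny_protocol())
  expect_identical(a, b)
})

test_that("every simulated beat satisfies DBP < MAP < SBP", {
  p <- subject_params("s1", seed = 3L)
  tr <- simulate_bp_trajectory(p, tiny_protocol())
  wf <- simulate_waveform(tr$sessions[[1]]$beats, 125)
  b <- wf$beats
  expect_true(all(b$dbp < b$map & b$map < b$sbp))
})

test_that("emitted waveform extrema equal the true SBP/DBP by construction", {
  beats <- data.frame(start = 0, end = 1, sbp = 120, dbp = 80)
  for (fs in c(100, 250, 1000)) {
    wf <- simulate_waveform(beats, fs)
    expect_equal(max(wf$record$pressure), 120)
    expect_equal(min(wf$record$pressure), 80)
  }
  expect_error(simulate_waveform(beats, 50), "100 Hz")
  expect_error(simulate_waveform(data.frame(start = 0, end = 0.005,
                                            sbp = 120, dbp = 80), 100),
               "2 samples")
})

test_that("waveform time-weighted mean matches the trapezoid oracle and is
           sampling-rate stable", {
  beats <- flat_beats(n = 3L, sbp = 130, dbp = 75, rr = 0.8)[, 1:4]
  wf1 <- simulate_waveform(beats, 1000)
  wf2 <- simulate_waveform(beats, 500)
  # oracle on the emitted samples of the middle cycle
  r <- wf1$record
  t <- (seq_along(r$pressure) - 1) / r$sampling_rate
  sel <- t >= beats$start[2] & t < beats$end[2]
  expect_equal(wf1$beats$map[2],
               trapz_mean_oracle(r$pressure[sel], 1 / r$sampling_rate),
               tolerance = 1e-9)
  expect_lt(max(abs(wf1$beats$map - wf2$beats$map)), 0.5)
  expect_equal(max(wf1$record$pressure), max(wf2$record$pressure))
})

test_that("brachial readings reproduce a constant truth and are spaced 1 min", {
  b <- flat_beats(n = 260L, sbp = 120, dbp = 80, rr = 1)
  tri <- simulate_brachial_readings(b, c(0, 240), noise_sd = 0)
  expect_equal(tri$sbp, rep(120, 3))
  expect_equal(tri$dbp, rep(80, 3))
  expect_equal(diff(tri$time), c(60, 60))
  expect_error(simulate_brachial_readings(b, c(0, 120)), "3 minutes")
  n1 <- simulate_brachial_readings(b, c(0, 240), noise_sd = 2, seed = 5L)
  n2 <- simulate_brachial_readings(b, c(0, 240), noise_sd = 2, seed = 5L)
  expect_identical(n1, n2)
})

test_that("PPG feature stream: identity-like map recovers segment-mean SBP", {
  segs <- data.frame(window_start = c(0, 15), sbp = c(118, 131),
                     dbp = c(76, 82), map = c(90, 98), hr = c(62, 70))
  fm <- list(intercept = c(f_sbp = 0),
             M = matrix(c(1, 0, 0, 0), 1, 4,
                        dimnames = list("f_sbp", c("sbp", "dbp", "map", "hr"))),
             noise_sd = c(f_sbp = 0))
  fx <- simulate_ppg_features(segs, fm, noise_sd = 0)
  expect_equal(fx$f_sbp, segs$sbp)
  expect_error(simulate_ppg_features(segs, fm, noise_sd = c(1, 2)),
               "does not match")
  a <- simulate_ppg_features(segs, seed = 9L)
  b <- simulate_ppg_features(segs, seed = 9L)
  expect_identical(a, b)
})

test_that("cohort structure: subject and day-2 counts, single-subject cohorts", {
  co <- deterministic_cohort(n = 5L, n_day2 = 2L)
  expect_length(co$subjects, 5L)
  expect_identical(sum(vapply(co$subjects, `[[`, TRUE, "day2")), 2L)
  d2 <- co$subjects[[co$day2_ids[1]]]$sessions
  expect_true(any(vapply(d2, `[[`, 0L, "day") == 2L))
  co1 <- deterministic_cohort(n = 1L, n_day2 = 0L)
  res <- run_pipeline(co1, run_config(seed = 1L, device_source = "direct",
                                      accuracy_n = 5L, k = 1L))
  expect_s3_class(res$report, "bp_criteria_report")
})

test_that("cohort generation is reproducible from its seed", {
  a <- deterministic_cohort(n = 2L, seed = 13L)
  b <- deterministic_cohort(n = 2L, seed = 13L)
  expect_identical(a$subjects, b$subjects)
})

test_that("artifact injection: identity at fraction 0, ground truth recorded,
           coverage grows with the fraction", {
  co <- deterministic_cohort(n = 1L)
  wf <- co$subjects[[1]]$sessions[[1]]$waveform
  r0 <- inject_artifacts(wf, 0)
  expect_identical(r0$pressure, wf$pressure)
  expect_length(r0$artifact$idx, 0L)
  fr <- vapply(c(0.1, 0.3, 0.6), function(f) {
    r <- inject_artifacts(wf, f, seed = 21L)
    expect_true(all(r$artifact$idx >= 1L &
                      r$artifact$idx <= length(wf$pressure)))
    length(r$artifact$idx) / length(wf$pressure)
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_true(all(fr >= c(0.1, 0.3, 0.6) - 0.02))
})

test_that("within-subject change grows with the configured response amplitude", {
  mk <- function(a) {
    amps <- list(handgrip = c(sbp = a, dbp = a / 2, hr = 5),
                 mental_stress = c(sbp = a, dbp = a / 2, hr = 5),
                 cold_pressor = c(sbp = a, dbp = a / 2, hr = 5))
    p <- subject_params("s", amplitudes = amps, noise_sd = 0,
                        hr_noise_sd = 0)
    tr <- simulate_bp_trajectory(p, tiny_protocol())
    segs <- aggregate_segments(tr$sessions[[1]]$beats,
                               tr$sessions[[1]]$duration)
    max(segs$sbp) - min(segs$sbp)
  }
  ch <- vapply(c(5, 15, 30), mk, numeric(1))
  expect_true(all(diff(ch) > 0))
})

test_that("cohort handgrip within-subject SBP change matches the protocol's
           cohort summary", {
  co <- full_cohort_cached(seed = 2024L)
  ch <- vapply(co$subjects, function(s) {
    ts <- s$sessions[[1]]$truth_segments     # day-1 handgrip session
    max(ts$sbp) - min(ts$sbp)
  }, numeric(1))
  # Monte-Carlo band: the sample median of 38 draws whose across-subject IQR
  # is 22.6 mmHg has SE ~ 1.253 * (22.6/1.349) / sqrt(38) ~ 3.4 mmHg; allow
  # two SEs around the configured 25.5 mmHg target.
  expect_lt(abs(median(ch) - 25.5), 7)
})
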