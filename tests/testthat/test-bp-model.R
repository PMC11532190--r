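test_that("pulse features: symmetric triangle has width at half amplitude T/2;
           a constant pulse is flagged", {
  fs <- 1000
  T_ <- 1
  n <- fs * T_ + 1
  tri <- c(seq(0, 1, length.out = (n + 1) / 2),
           seq(1, 0, length.out = (n + 1) / 2)[-1])
  f <- pulse_features(tri, fs)
  expect_equal(unname(f["width50"]), T_ / 2, tolerance = 1e-3)
  expect_equal(unname(f["pulse_amp"]), 1)
  expect_equal(unname(f["rise_time"]), T_ / 2, tolerance = 1e-3)
  expect_equal(unname(f["decay_time"]), T_ / 2, tolerance = 1e-3)

  expect_true(all(is.na(pulse_features(rep(5, 100), fs))))
})

test_that("waveform feature extraction agrees with a direct sample-scan
           oracle on the generator template", {
  beats <- flat_beats(n = 40L, sbp = 125, dbp = 78, rr = 0.75)[, 1:4]
  wf <- simulate_waveform(beats, 500)$record
  fx <- extract_features(wf, session_duration = 30)
  expect_equal(nrow(fx), 2L)
  expect_false(any(fx$missing))
  # oracle: scan the first cycle's emitted samples directly
  t <- (seq_along(wf$pressure) - 1) / wf$sampling_rate
  s <- wf$pressure[t >= beats$start[1] & t < beats$end[1]]
  expect_equal(unname(fx$pulse_amp[1]), max(s) - min(s), tolerance = 1e-9)
  expect_equal(unname(fx$max_slope[1]), max(diff(s)) * wf$sampling_rate,
               tolerance = 1e-9)
  expect_equal(unname(fx$rise_time[1]),
               (which.max(s) - 1) / wf$sampling_rate, tolerance = 1e-9)
  expect_equal(fx$hr_mean, c(80, 80))

  # a feature stream passes through with non-finite rows flagged
  st <- data.frame(window_start = c(0, 15), a = c(1, NA), b = c(2, 3))
  out <- extract_features(st)
  expect_equal(out$missing, c(FALSE, TRUE))
})

test_that("subject-wise folds are disjoint, balanced and seeded", {
  ids <- sprintf("s%02d", 1:38)
  sp <- subject_kfold_split(ids, k = 3L, seed = 5L)
  expect_equal(sort(table(sp$fold), decreasing = TRUE),
               sort(table(c(rep(1, 13), rep(2, 13), rep(3, 12))),
                    decreasing = TRUE), ignore_attr = TRUE)
  expect_equal(anyDuplicated(sp$subject), 0L)
  expect_identical(sp, subject_kfold_split(ids, k = 3L, seed = 5L))
  expect_false(identical(sp$fold, subject_kfold_split(ids, 3L, 6L)$fold))

  sp3 <- subject_kfold_split(c("a", "b", "c"), k = 3L, seed = 1L)
  expect_equal(sort(sp3$fold), 1:3)
  expect_error(subject_kfold_split(c("a", "b"), k = 3L), "at least k")
  expect_error(subject_kfold_split(c("a", "a", "b"), k = 2L), "unique")
})

test_that("noiseless linear features are recovered to < 0.5 mmHg held-out", {
  set.seed(11)
  n_sub <- 9L
  ids <- sprintf("s%d", seq_len(n_sub))
  rows <- do.call(rbind, lapply(ids, function(id) {
    sbp <- rnorm(40, 120, 12); dbp <- sbp - rnorm(40, 45, 5)
    map <- dbp + (sbp - dbp) / 3; hr <- rnorm(40, 70, 8)
    data.frame(subject = id, sbp = sbp, dbp = dbp, map = map, hr = hr)
  }))
  fm <- default_feature_map()
  X <- sweep(as.matrix(rows[, c("sbp", "dbp", "map", "hr")]) %*% t(fm$M),
             2L, fm$intercept, `+`)
  split <- subject_kfold_split(ids, 3L, seed = 2L)
  ens <- train_ensemble(X, rows[, c("sbp", "dbp", "map")], rows$subject,
                        split)
  pred <- predict(ens, X, subjects = rows$subject, mode = "strict")
  for (p in c("sbp", "dbp", "map")) {
    rmse <- sqrt(mean((pred[[p]] - rows[[p]])^2))
    expect_lt(rmse, 0.5)
  }
})

test_that("ensemble mechanics: identical folds collapse to one model, member
           averaging, permutation invariance, missing features", {
  fake_member <- function(const) list(beta = c(x = 0), intercept = const)
  ens <- structure(list(models = list(sbp = lapply(c(100, 110, 120),
                                                   fake_member)),
                        split = subject_kfold_split(c("a", "b", "c"), 3L, 1L),
                        lambda = 0, feature_names = "x", k = 3L),
                   class = "bp_ensemble")
  X <- matrix(c(1, NA), 2, 1, dimnames = list(NULL, "x"))
  out <- predict(ens, X, mode = "paper")
  expect_equal(out$sbp, c(110, NA))

  ens_perm <- ens
  ens_perm$models$sbp <- ens$models$sbp[c(3, 1, 2)]
  expect_equal(predict(ens_perm, X, mode = "paper")$sbp, out$sbp)

  # three members trained on identical data give an ensemble == each member
  set.seed(3)
  Xr <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- 2 * Xr[, 1] - Xr[, 2] + 100
  subs <- rep(c("s1", "s2", "s3"), each = 10L)
  sp <- subject_kfold_split(c("s1", "s2", "s3"), 3L, 1L)
  # duplicate every subject's rows into all folds by using equal data
  ens2 <- train_ensemble(rbind(Xr, Xr, Xr), data.frame(sbp = rep(y, 3L)),
                         rep(c("s1", "s2", "s3"), each = 30L)[1:90], sp,
                         lambda = 1e-8)
  p1 <- predict(ens2, Xr, mode = "paper")$sbp
  expect_equal(p1, y, tolerance = 1e-4)
})

test_that("held-out predictions cannot memorize subject-specific noise", {
  set.seed(21)
  n_sub <- 6L
  ids <- sprintf("s%d", seq_len(n_sub))
  X <- matrix(rnorm(n_sub * 30 * 5), n_sub * 30, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- rnorm(n_sub * 30, 120, 10)          # pure noise target
  subs <- rep(ids, each = 30L)
  sp <- subject_kfold_split(ids, 3L, seed = 4L)
  ens <- train_ensemble(X, data.frame(sbp = y), subs, sp, lambda = 1e-8)
  held <- predict(ens, X, subjects = subs, mode = "strict")$sbp
  rmse_held <- sqrt(mean((held - y)^2))
  # null model: held-out error is close to the target SD, not near zero
  expect_gt(rmse_held, 0.8 * sd(y))
  expect_lt(abs(rmse_held - sd(y)) / sd(y), 0.35)
})

test_that("permuted feature-target pairing gives held-out RMSE near the
           target SD", {
  set.seed(31)
  ids <- sprintf("s%d", 1:6)
  subs <- rep(ids, each = 25L)
  sbp <- rnorm(150, 120, 10)
  X <- cbind(f1 = sbp * 0.01 + rnorm(150, 0, 1e-4))   # perfectly informative
  sp <- subject_kfold_split(ids, 3L, seed = 2L)
  good <- predict(train_ensemble(X, data.frame(sbp = sbp), subs, sp),
                  X, subjects = subs, mode = "strict")$sbp
  expect_lt(sqrt(mean((good - sbp)^2)), 0.5)
  perm <- sample(150)
  bad <- predict(train_ensemble(X[perm, , drop = FALSE],
                                data.frame(sbp = sbp), subs, sp),
                 X[perm, , drop = FALSE], subjects = subs,
                 mode = "strict")$sbp
  expect_gt(sqrt(mean((bad - sbp)^2)), 0.7 * sd(sbp))
})
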