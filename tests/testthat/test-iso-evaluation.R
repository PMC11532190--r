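pairs_df <- function(subject, ref, dev, day = 1L, activity = "handgrip") {
  data.frame(subject = subject, day = day, activity = activity,
             ref = ref, dev = dev)
}

test_that("accuracy statistic: closed forms and pass bounds", {
  a <- accuracy_statistic(pairs_df(c("a", "a"), c(100, 100), c(102, 98)))
  expect_equal(a$mean_diff, 0)
  expect_equal(a$sd_diff, sqrt(8))
  expect_equal(a$n, 2L)

  b <- accuracy_statistic(pairs_df(rep("a", 5), rep(100, 5), rep(103, 5)))
  expect_equal(b$mean_diff, 3)
  expect_equal(b$sd_diff, 0)
  expect_true(b$pass)

  expect_error(accuracy_statistic(pairs_df("a", 100, 101)), "at least 2")
  # |mean| = 6.0 exactly passes (inclusive bound)
  expect_true(agreement_result(6, 10, 10)$pass)
  expect_false(agreement_result(6.01, 10, 10)$pass)
  expect_false(agreement_result(0, 10.01, 10)$pass)
})

test_that("pair selection: exact totals (38x22 = 836, 11x44 = 484),
           identity, reproducibility, named failure", {
  mk <- function(n_sub, n_per) {
    pairs_df(rep(sprintf("s%02d", 1:n_sub), each = n_per),
             rnorm(n_sub * n_per, 120, 10), rnorm(n_sub * n_per, 120, 10))
  }
  set.seed(1)
  p38 <- mk(38, 60)
  sel <- select_pairs(p38, 22L, seed = 2L)
  expect_equal(nrow(sel), 836L)
  expect_equal(unname(table(sel$subject)), rep(22L, 38L), ignore_attr = TRUE)

  p11 <- mk(11, 50)
  expect_equal(nrow(select_pairs(p11, 44L, seed = 2L)), 484L)

  exact <- mk(3, 10)
  expect_equal(select_pairs(exact, 10L, seed = 1L), exact)
  expect_identical(select_pairs(p38, 22L, seed = 9L),
                   select_pairs(p38, 22L, seed = 9L))
  short <- mk(2, 5)
  expect_error(select_pairs(short, 6L), "s01")
})

test_that("stability statistic pools day-1 and day-2 pairs of day-2 subjects
           and tracks injected drift", {
  set.seed(7)
  subs <- sprintf("s%d", 1:11)
  d1 <- pairs_df(rep(subs, each = 40L), rnorm(440, 120, 8),
                 rnorm(440, 120, 8), day = 1L)
  d1$dev <- d1$ref + rnorm(440, 0, 2)
  d2 <- pairs_df(rep(subs, each = 40L), rnorm(440, 120, 8),
                 rnorm(440, 120, 8), day = 2L)
  d2$dev <- d2$ref + rnorm(440, 0, 2)

  st <- stability_statistic(d1, d2, 44L, seed = 3L)
  expect_equal(st$n, 484L)
  acc <- accuracy_statistic(rbind(d1, d2))
  expect_lt(abs(st$mean_diff - acc$mean_diff), 0.5)

  # +d drift on day 2 shifts the pooled mean by d x (day-2 pair fraction)
  drift <- 6
  d2d <- d2; d2d$dev <- d2d$dev + drift
  st_d <- stability_statistic(d1, d2d, 44L, seed = 3L)
  sel <- rbind(d1, d2d)
  # oracle from the actual selected pair counts under the same seed
  pool <- rbind(d1, d2d)
  sel2 <- select_pairs(pool, 44L, seed = 3L)
  frac2 <- mean(sel2$day == 2L)
  expect_equal(st_d$mean_diff - st$mean_diff, drift * frac2,
               tolerance = 1e-9)
  expect_error(stability_statistic(d1, d1[0, ], 44L), "no day-2")
})

test_that("change pairs: error-rate arithmetic, thresholds and scale
           invariance", {
  seg <- data.frame(subject = "a", activity = "handgrip",
                    window_start = c(0, 15), ref = c(100, 120),
                    dev = c(100, 115))
  cp <- change_pairs(seg, threshold = 15)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$d_ref, 20)
  expect_equal(cp$error_rate, 25)          # |15 - 20| / 20

  seg$dev <- c(100, 120)
  expect_equal(change_pairs(seg, 15)$error_rate, 0)

  seg$ref <- c(100, 112)                   # 12 mmHg: below the SBP threshold
  expect_equal(nrow(change_pairs(seg, CHANGE_THRESHOLDS[["sbp"]])), 0L)
  expect_equal(nrow(change_pairs(seg, CHANGE_THRESHOLDS[["dbp"]])), 1L)

  # scale invariance of the error rate
  set.seed(2)
  s1 <- data.frame(subject = "a", activity = "x",
                   window_start = (0:9) * 15,
                   ref = rnorm(10, 120, 20), dev = rnorm(10, 120, 20))
  s2 <- s1; s2$ref <- s2$ref * 3; s2$dev <- s2$dev * 3
  c1 <- change_pairs(s1, 15, cap = Inf)
  c2 <- change_pairs(s2, 45, cap = Inf)
  expect_equal(c1$error_rate, c2$error_rate, tolerance = 1e-12)

  # per-subject cap with seeded subsample
  big <- data.frame(subject = "a", activity = "x",
                    window_start = (0:39) * 15,
                    ref = seq(100, 100 + 39 * 16, by = 16), dev = 100)
  capped <- change_pairs(big, 15, cap = 50L, seed = 5L)
  expect_equal(nrow(capped), 50L)
  expect_identical(capped, change_pairs(big, 15, cap = 50L, seed = 5L))
})

test_that("change percentiles use linear interpolation and satisfy
           p50 <= p85", {
  r <- change_percentiles(c(10, 20, 30, 40))
  expect_equal(r$p50, 25)
  expect_equal(r$p85, percentile_oracle(c(10, 20, 30, 40), 0.85))

  r7 <- change_percentiles(rep(7, 5))
  expect_equal(c(r7$p50, r7$p85), c(7, 7))
  expect_true(r7$pass_p50 && r7$pass_p85)

  set.seed(9)
  for (i in 1:20) {
    x <- runif(sample(2:50, 1), 0, 100)
    rr <- change_percentiles(x)
    expect_lte(rr$p50, rr$p85)
    expect_equal(rr$p50, percentile_oracle(x, 0.5), tolerance = 1e-12)
    expect_equal(rr$p85, percentile_oracle(x, 0.85), tolerance = 1e-12)
  }
  expect_error(change_percentiles(numeric(0)), "no change pairs")
})

test_that("Bland-Altman: formula, degenerate case, clamping affects only the
           plotted values", {
  z <- bland_altman(data.frame(ref = c(100, 110), dev = c(100, 110)))
  expect_equal(c(z$bias, z$loa_lower, z$loa_upper), c(0, 0, 0))

  set.seed(12)
  d <- rnorm(200, 2, 5)
  ba <- bland_altman(data.frame(ref = rep(100, 200), dev = 100 + d))
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d))

  out <- bland_altman(data.frame(ref = c(100, 100, 100),
                                 dev = c(135, 100, 100)))
  expect_equal(max(out$data$diff), 35)           # statistics use +35
  expect_equal(max(out$data$diff_plotted), 30)   # plotted at +30
  expect_equal(out$bias, mean(c(35, 0, 0)))
})

test_that("within-subject change equals the max-minus-min oracle per subject
           and activity", {
  seg <- data.frame(subject = rep(c("a", "b"), each = 4L),
                    activity = rep(c("x", "x", "y", "y"), 2L),
                    ref = c(110, 150, 120, 130, 100, 100, 90, 95))
  w <- within_subject_change(seg)
  expect_equal(w$change[w$subject == "a" & w$activity == "all"], 40)
  expect_equal(w$change[w$subject == "a" & w$activity == "y"], 10)
  expect_equal(w$change[w$subject == "b" & w$activity == "x"], 0)

  set.seed(5)
  seg2 <- data.frame(subject = sample(letters[1:4], 120, TRUE),
                     activity = sample(c("x", "y"), 120, TRUE),
                     ref = rnorm(120, 120, 15))
  w2 <- within_subject_change(seg2)
  for (s in letters[1:4]) {
    v <- seg2$ref[seg2$subject == s]
    expect_equal(w2$change[w2$subject == s & w2$activity == "all"],
                 max(v) - min(v))
  }
})

test_that("ICC: limiting cases and the 4x3 ANOVA oracle", {
  set.seed(6)
  # no between-subject component: estimate close to zero
  s <- rep(sprintf("s%d", 1:20), each = 10L)
  v <- rnorm(200)
  expect_lt(abs(icc(v, s)$estimate), 0.2)

  # between-subject variance dominates
  v2 <- rep(c(0, 50, 100, 150), each = 3L) + rnorm(12, 0, 0.1)
  s2 <- rep(sprintf("s%d", 1:4), each = 3L)
  expect_gt(icc(v2, s2)$estimate, 0.99)

  v3 <- c(5.1, 4.9, 5.3, 7.2, 7.4, 6.9, 3.1, 3.3, 2.8, 6.0, 5.8, 6.1)
  s3 <- rep(c("a", "b", "c", "d"), each = 3L)
  expect_equal(icc(v3, s3)$estimate, icc_aov_oracle(v3, s3),
               tolerance = 1e-12)
  expect_lte(icc(v3, s3)$estimate, 1)
  expect_error(icc(c(1, 2), c("a", "b")), "2 subjects")
})

test_that("criteria report reproduces the reference verdict pattern from
           printed statistics", {
  # published-style statistics: Accuracy/Stability pass for all parameters,
  # p50 fails everywhere, p85 fails only for SBP
  rep_ <- criteria_report(list(
    sbp = list(accuracy = agreement_result(0.3, 8.7, 836),
               stability = agreement_result(1.9, 9.2, 484),
               change = change_result(39, 56, 3549)),
    dbp = list(accuracy = agreement_result(0.04, 6.6, 836),
               stability = agreement_result(2.9, 8.1, 484),
               change = change_result(32, 48, 3142)),
    map = list(accuracy = agreement_result(0.8, 7.9, 836),
               stability = agreement_result(2.5, 9.5, 484),
               change = change_result(33, 47, 3510))))
  tab <- rep_$table
  expect_true(all(tab$accuracy_pass))
  expect_true(all(tab$stability_pass))
  expect_false(any(tab$change_p50_pass))
  expect_equal(tab$change_p85_pass[tab$parameter == "sbp"], FALSE)
  expect_equal(tab$change_p85_pass[tab$parameter == "dbp"], TRUE)
  expect_equal(tab$change_p85_pass[tab$parameter == "map"], TRUE)
})
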