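ISO_AGREEMENT_BOUNDS <- c(mean = 6, sd = 10)
ISO_CHANGE_BOUNDS <- c(p50 = 25, p85 = 50)

#' Change-analysis minimum reference change per parameter (mmHg)
#' @export
CHANGE_THRESHOLDS <- c(sbp = 15, dbp = 10, map = 12)

#' Agreement result from explicit statistics
#'
#' Builds an Accuracy/Stability-style agreement result directly from a mean
#' difference and SD (e.g. values printed in a report), with the pass flag
#' evaluated against the bounds `|mean| <= 6` and `SD <= 10` mmHg
#' (inclusive).
#'
#' @param mean_diff mean of (device - reference) differences, mmHg.
#' @param sd_diff sample SD of the differences, mmHg.
#' @param n number of pairs.
#' @param bounds named vector `c(mean =, sd =)`.
#' @return A `bp_agreement` object.
#' @export
agreement_result <- function(mean_diff, sd_diff, n,
                             bounds = ISO_AGREEMENT_BOUNDS) {
  structure(list(n = as.integer(n), mean_diff = mean_diff, sd_diff = sd_diff,
                 bounds = bounds,
                 pass = is.finite(mean_diff) && is.finite(sd_diff) &&
                   abs(mean_diff) <= bounds[["mean"]] &&
                   sd_diff <= bounds[["sd"]]),
            class = "bp_agreement")
}

#' Accuracy statistic: pooled mean (SD) of paired differences
#'
#' Mean and sample SD (n-1 denominator) of `device - reference` pooled
#' across all selected pairs, with the pass flag against the agreement
#' bounds.
#'
#' @param pairs data.frame with columns `ref` and `dev` (one BP parameter);
#'   rows with a missing member are dropped.
#' @param bounds agreement bounds, `c(mean = 6, sd = 10)` mmHg.
#' @return A `bp_agreement` object.
#' @export
accuracy_statistic <- function(pairs, bounds = ISO_AGREEMENT_BOUNDS) {
  d <- pair_differences(pairs)
  if (length(d) < 2L) stop_cf("need at least 2 pairs, got %d", length(d))
  agreement_result(mean(d), stats::sd(d), length(d), bounds)
}

pair_differences <- function(pairs) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("ref", "dev") %in% names(pairs)))
    d <- pairs$dev - pairs$ref
  } else d <- as.numeric(pairs)
  d[is.finite(d)]
}

#' @export
print.bp_agreement <- function(x, ...) {
  cat(sprintf("<bp_agreement> n = %d: mean %.2f (SD %.2f) mmHg vs <=%.1f (%.1f): %s\n",
              x$n, x$mean_diff, x$sd_diff, x$bounds[["mean"]],
              x$bounds[["sd"]], if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Randomly select a fixed number of pairs per subject
#'
#' Uniform sampling without replacement of exactly `n_per_subject` valid
#' pairs per retained subject (22 per subject in the Accuracy analysis, 44
#' in the Stability analysis), so the total is
#' `n_per_subject * n_subjects`.
#'
#' @param pairs data.frame with `subject`, `ref`, `dev` columns.
#' @param n_per_subject pairs to draw per subject.
#' @param seed RNG seed.
#' @return the selected rows of `pairs`.
#' @export
select_pairs <- function(pairs, n_per_subject, seed = 1L) {
  stopifnot(is.data.frame(pairs), all(c("subject", "ref", "dev") %in% names(pairs)))
  valid <- pairs[is.finite(pairs$ref) & is.finite(pairs$dev), , drop = FALSE]
  counts <- table(valid$subject)
  short <- names(counts)[counts < n_per_subject]
  if (length(short))
    stop_cf("subject(s) with fewer than %d valid pairs: %s", n_per_subject,
            paste(short, collapse = ", "))
  with_seed(seed, {
    take <- unlist(lapply(split(seq_len(nrow(valid)), valid$subject),
                          function(ix) if (length(ix) == n_per_subject) ix
                          else sample(ix, n_per_subject)),
                   use.names = FALSE)
    out <- valid[sort(take), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Stability statistic over day-1 plus day-2 pairs
#'
#' Restricted to subjects with a day-2 session; `n_per_subject` pairs
#' (default 44) are drawn per subject from the union of that subject's day-1
#' and day-2 pairs — with the original day-1 one-point calibration still
#' applied — and the pooled mean (SD) is computed as for Accuracy.
#'
#' @param day1_pairs,day2_pairs data.frames with `subject`, `ref`, `dev`.
#' @param n_per_subject pairs per subject (default 44).
#' @param seed RNG seed.
#' @param bounds agreement bounds.
#' @return A `bp_agreement` object.
#' @export
stability_statistic <- function(day1_pairs, day2_pairs, n_per_subject = 44L,
                                seed = 1L, bounds = ISO_AGREEMENT_BOUNDS) {
  if (is.null(day2_pairs) || nrow(day2_pairs) == 0L)
    stop_cf("no day-2 subjects: the Stability statistic is undefined")
  keep <- unique(day2_pairs$subject)
  pool <- rbind(day1_pairs[day1_pairs$subject %in% keep, , drop = FALSE],
                day2_pairs)
  sel <- select_pairs(pool, n_per_subject, seed = seed)
  accuracy_statistic(sel, bounds)
}

#' Within-activity change pairs and their error rates
#'
#' Enumerates all ordered (start < end) segment-window pairs within one
#' activity session, retains those whose reference change meets the
#' parameter's minimum (`|d_ref| >= threshold`; 15/10/12 mmHg for
#' SBP/DBP/MAP), computes the device change over the same windows and the
#' error rate `|d_dev - d_ref| / |d_ref| * 100`. When a subject accumulates
#' more than `cap` candidate pairs across activities, a seeded subsample of
#' size `cap` is kept.
#'
#' @param segments data.frame with `subject`, `activity`, `window_start`,
#'   `ref`, `dev` for one BP parameter.
#' @param threshold minimum reference change, mmHg.
#' @param cap per-subject cap on retained pairs (`Inf` to disable).
#' @param seed RNG seed for the cap subsample.
#' @return data.frame: `subject`, `activity`, `start_window`, `end_window`,
#'   `d_ref`, `d_dev`, `error_rate` (%). May have zero rows.
#' @export
change_pairs <- function(segments, threshold, cap = 200L, seed = 1L) {
  stopifnot(is.data.frame(segments), threshold > 0,
            all(c("subject", "activity", "window_start", "ref", "dev") %in%
                  names(segments)))
  ok <- is.finite(segments$ref) & is.finite(segments$dev)
  segments <- segments[ok, , drop = FALSE]
  groups <- split(segments, list(segments$subject, segments$activity),
                  drop = TRUE)
  res <- lapply(groups, function(g) {
    g <- g[order(g$window_start), , drop = FALSE]
    n <- nrow(g)
    if (n < 2L) return(NULL)
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    dref <- g$ref[ij[, 2L]] - g$ref[ij[, 1L]]
    keep <- abs(dref) >= threshold
    if (!any(keep)) return(NULL)
    ij <- ij[keep, , drop = FALSE]; dref <- dref[keep]
    ddev <- g$dev[ij[, 2L]] - g$dev[ij[, 1L]]
    data.frame(subject = g$subject[ij[, 1L]], activity = g$activity[1L],
               start_window = g$window_start[ij[, 1L]],
               end_window = g$window_start[ij[, 2L]],
               d_ref = dref, d_dev = ddev,
               error_rate = abs(ddev - dref) / abs(dref) * 100)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(subject = character(0), activity = character(0),
                      start_window = numeric(0), end_window = numeric(0),
                      d_ref = numeric(0), d_dev = numeric(0),
                      error_rate = numeric(0)))
  rownames(out) <- NULL
  if (is.finite(cap)) {
    out <- with_seed(seed, {
      kept <- unlist(lapply(split(seq_len(nrow(out)), out$subject),
                            function(ix) if (length(ix) <= cap) ix
                            else sort(sample(ix, cap))),
                     use.names = FALSE)
      out[sort(kept), , drop = FALSE]
    })
    rownames(out) <- NULL
  }
  out
}

#' Change criterion: percentiles of the error-rate distribution
#'
#' 50th and 85th percentiles (linear interpolation between order statistics)
#' of the change error rates, with pass flags against 25% and 50%.
#'
#' @param x a [change_pairs()] result or a numeric vector of error rates (%).
#' @param bounds `c(p50 = 25, p85 = 50)`.
#' @return A `bp_change_result`.
#' @export
change_percentiles <- function(x, bounds = ISO_CHANGE_BOUNDS) {
  rates <- if (is.data.frame(x)) x$error_rate else as.numeric(x)
  rates <- rates[is.finite(rates)]
  if (!length(rates)) stop_cf("no change pairs: percentiles undefined")
  q <- stats::quantile(rates, c(0.5, 0.85), names = FALSE, type = 7)
  change_result(q[1], q[2], length(rates), bounds)
}

#' Change result from explicit percentiles
#' @param p50,p85 50th/85th percentile of error rate, %.
#' @param n number of change pairs.
#' @param bounds `c(p50 = 25, p85 = 50)`.
#' @return A `bp_change_result` with per-percentile pass flags.
#' @export
change_result <- function(p50, p85, n, bounds = ISO_CHANGE_BOUNDS) {
  structure(list(n = as.integer(n), p50 = p50, p85 = p85, bounds = bounds,
                 pass_p50 = is.finite(p50) && p50 <= bounds[["p50"]],
                 pass_p85 = is.finite(p85) && p85 <= bounds[["p85"]]),
            class = "bp_change_result")
}

#' @export
print.bp_change_result <- function(x, ...) {
  cat(sprintf("<bp_change_result> n = %d: p50 %.1f%% (<=%.0f: %s), p85 %.1f%% (<=%.0f: %s)\n",
              x$n, x$p50, x$bounds[["p50"]],
              if (x$pass_p50) "PASS" else "FAIL",
              x$p85, x$bounds[["p85"]],
              if (x$pass_p85) "PASS" else "FAIL"))
  invisible(x)
}

#' Bland-Altman agreement
#'
#' Bias (mean difference) and 95% limits of agreement
#' `bias +/- 1.96 * SD`. For plotting, differences beyond the clamp bound
#' (default +/- 30 mmHg) are drawn at the bound; the statistics always use
#' the unclamped values.
#'
#' @param pairs data.frame with `ref` and `dev` (one parameter).
#' @param clamp plotting clamp bound, mmHg.
#' @return A `bp_bland_altman`: `bias`, `loa_lower`, `loa_upper`, `sd`, `n`,
#'   `clamp`, and `data` (means, differences, clamped differences).
#' @export
bland_altman <- function(pairs, clamp = 30) {
  stopifnot(is.data.frame(pairs), all(c("ref", "dev") %in% names(pairs)))
  ok <- is.finite(pairs$ref) & is.finite(pairs$dev)
  if (sum(ok) < 2L) stop_cf("need at least 2 pairs")
  d <- pairs$dev[ok] - pairs$ref[ok]
  m <- (pairs$dev[ok] + pairs$ref[ok]) / 2
  bias <- mean(d); s <- stats::sd(d)
  structure(list(bias = bias, sd = s,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 n = sum(ok), clamp = clamp,
                 data = data.frame(mean = m, diff = d,
                                   diff_plotted = pmin(pmax(d, -clamp), clamp))),
            class = "bp_bland_altman")
}

#' @export
print.bp_bland_altman <- function(x, ...) {
  cat(sprintf("<bp_bland_altman> n = %d: bias %.2f mmHg, 95%% LoA [%.2f, %.2f]\n",
              x$n, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Plot a Bland-Altman result
#'
#' Differences beyond the clamp bound are drawn at the bound (the printed
#' statistics are unaffected).
#'
#' @param x a `bp_bland_altman`.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bp_bland_altman <- function(x, main = "Bland-Altman", ...) {
  graphics::plot(x$data$mean, x$data$diff_plotted,
                 xlab = "Mean of reference and device (mmHg)",
                 ylab = "Device - reference (mmHg)",
                 ylim = c(-x$clamp, x$clamp) * 1.05, main = main,
                 pch = 20, col = "grey40", ...)
  graphics::abline(h = x$bias, col = "red")
  graphics::abline(h = c(x$loa_lower, x$loa_upper), col = "blue", lty = 2)
  invisible(x)
}

#' Within-subject reference change
#'
#' Highest minus lowest reference segment value per subject, over the whole
#' day-1 test period and within each activity separately.
#'
#' @param segments data.frame with `subject`, `activity` and a reference
#'   value column.
#' @param value_col name of the value column (default `"ref"`).
#' @return data.frame: `subject`, `activity` (`"all"` plus each activity),
#'   `change` (mmHg; `NA` when the subject has no non-missing segment
#'   there).
#' @export
within_subject_change <- function(segments, value_col = "ref") {
  stopifnot(is.data.frame(segments),
            all(c("subject", "activity", value_col) %in% names(segments)))
  v <- segments[[value_col]]
  rng <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) NA_real_ else max(x) - min(x)
  }
  subs <- unique(segments$subject)
  acts <- unique(segments$activity)
  rows <- list()
  for (s in subs) {
    sel <- segments$subject == s
    rows[[length(rows) + 1L]] <-
      data.frame(subject = s, activity = "all", change = rng(v[sel]))
    for (a in acts) {
      rows[[length(rows) + 1L]] <-
        data.frame(subject = s, activity = a,
                   change = rng(v[sel & segments$activity == a]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way random-effects intraclass correlation
#'
#' ICC(1,1) on per-pair differences grouped by subject, from one-way ANOVA
#' variance components: `sigma2_b / (sigma2_b + sigma2_w)` with
#' `sigma2_b = (MSB - MSW) / n0` and the unbalanced-design average group
#' size `n0`. Negative estimates are reported as-is with a note.
#'
#' @param values numeric vector of per-pair differences.
#' @param subjects grouping vector (same length).
#' @return A `bp_icc`: `estimate`, `var_between`, `var_within`,
#'   `n_subjects`, `mean_repeats`, `note`.
#' @export
icc <- function(values, subjects) {
  ok <- is.finite(values)
  values <- values[ok]; subjects <- as.character(subjects[ok])
  n_i <- table(subjects)
  a <- length(n_i)
  if (a < 2L || sum(n_i >= 2L) < 2L)
    stop_cf("ICC needs at least 2 subjects with at least 2 repeats each")
  N <- length(values)
  if (N - a < 1L) stop_cf("no within-subject degrees of freedom")
  gmean <- mean(values)
  means <- tapply(values, subjects, mean)
  ssb <- sum(n_i * (means - gmean)^2)
  ssw <- sum((values - means[subjects])^2)
  msb <- ssb / (a - 1L)
  msw <- ssw / (N - a)
  n0 <- (N - sum(n_i^2) / N) / (a - 1L)
  vb <- (msb - msw) / n0
  est <- vb / (vb + msw)
  structure(list(estimate = est, var_between = vb, var_within = msw,
                 n_subjects = a, mean_repeats = N / a,
                 note = if (est < 0) "negative estimate reported as-is" else ""),
            class = "bp_icc")
}

#' @export
print.bp_icc <- function(x, ...) {
  cat(sprintf("<bp_icc> %.3f (between %.2f, within %.2f; %d subjects, %.1f repeats)%s\n",
              x$estimate, x$var_between, x$var_within, x$n_subjects,
              x$mean_repeats,
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Criteria report: Accuracy / Stability / Change pass-fail summary
#'
#' Collects the agreement and change statistics per BP parameter into one
#' structured report with each statistic, its bound, and the pass/fail
#' verdicts (`<=` inclusive throughout).
#'
#' @param results named list (names = parameters, e.g. `sbp`, `dbp`, `map`);
#'   each element a list with `accuracy` (`bp_agreement`), `change`
#'   (`bp_change_result`) and optionally `stability` (`bp_agreement` or
#'   `NULL` when no day-2 data exist).
#' @return A `bp_criteria_report` whose `$table` holds one row per
#'   parameter.
#' @export
criteria_report <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L, !is.null(names(results)))
  rows <- lapply(names(results), function(p) {
    r <- results[[p]]
    if (is.null(r$accuracy))
      stop_cf("parameter '%s' needs an accuracy result", p)
    if (is.null(r$change))
      r$change <- list(p50 = NA_real_, p85 = NA_real_, n = NA_integer_,
                       pass_p50 = NA, pass_p85 = NA)
    st <- r$stability
    data.frame(parameter = p,
               accuracy_mean = r$accuracy$mean_diff,
               accuracy_sd = r$accuracy$sd_diff,
               accuracy_n = r$accuracy$n,
               accuracy_pass = r$accuracy$pass,
               stability_mean = if (is.null(st)) NA_real_ else st$mean_diff,
               stability_sd = if (is.null(st)) NA_real_ else st$sd_diff,
               stability_n = if (is.null(st)) NA_integer_ else st$n,
               stability_pass = if (is.null(st)) NA else st$pass,
               change_p50 = r$change$p50,
               change_p85 = r$change$p85,
               change_n = r$change$n,
               change_p50_pass = r$change$pass_p50,
               change_p85_pass = r$change$pass_p85)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 bounds = list(agreement = ISO_AGREEMENT_BOUNDS,
                               change = ISO_CHANGE_BOUNDS)),
            class = "bp_criteria_report")
}

#' @export
print.bp_criteria_report <- function(x, ...) {
  b <- x$bounds
  cat(sprintf("Agreement bounds: |mean| <= %.1f mmHg, SD <= %.1f mmHg; change bounds: p50 <= %.0f%%, p85 <= %.0f%%\n\n",
              b$agreement[["mean"]], b$agreement[["sd"]],
              b$change[["p50"]], b$change[["p85"]]))
  pf <- function(p) if (is.na(p)) "  - " else if (p) "pass" else "FAIL"
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf("%-4s accuracy %6.2f (%5.2f) [%s]  stability %6.2f (%5.2f) [%s]  change p50 %5.1f%% [%s] p85 %5.1f%% [%s]\n",
                toupper(r$parameter), r$accuracy_mean, r$accuracy_sd,
                pf(r$accuracy_pass), r$stability_mean, r$stability_sd,
                pf(r$stability_pass), r$change_p50, pf(r$change_p50_pass),
                r$change_p85, pf(r$change_p85_pass)))
  }
  invisible(x)
}
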