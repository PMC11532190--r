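#' Pipeline run configuration
#'
#' A fully serializable bundle of every tunable the evaluation pipeline uses;
#' a run is reproducible from a cohort plus this configuration alone.
#'
#' @param seed master seed for every stochastic pipeline step (pair
#'   selection, fold split, change-pair capping).
#' @param mode `"strict"` (held-out fold predictions, default) or `"paper"`
#'   (final averaged ensemble predicts for everyone).
#' @param device_source `"model"` (regression on PPG features, default) or
#'   `"direct"` (the simulator's direct device BP estimates).
#' @param accuracy_n pairs per subject for the Accuracy analysis (22).
#' @param stability_n pairs per subject for the Stability analysis (44).
#' @param change_thresholds minimum reference change per parameter, mmHg.
#' @param change_cap per-subject cap on change pairs.
#' @param anchor_window one-point device calibration window within the first
#'   session's initial rest, seconds (default the rest's last minute).
#' @param lambda ridge penalty for the regression ensemble.
#' @param k number of cross-validation folds.
#' @param filter artifact-filter settings passed to [filter_artifacts()].
#' @return A `bp_run_config` list.
#' @export
run_config <- function(seed = 1L, mode = c("strict", "paper"),
                       device_source = c("model", "direct"),
                       accuracy_n = 22L, stability_n = 44L,
                       change_thresholds = CHANGE_THRESHOLDS,
                       change_cap = 200L, anchor_window = c(180, 240),
                       lambda = 1e-3, k = 3L,
                       filter = list(flat_run = 0.5, flat_eps = 1e-3,
                                     range = c(20, 300), hf_cutoff = 20,
                                     hf_ratio = 0.3)) {
  structure(list(seed = seed, mode = match.arg(mode),
                 device_source = match.arg(device_source),
                 accuracy_n = as.integer(accuracy_n),
                 stability_n = as.integer(stability_n),
                 change_thresholds = change_thresholds,
                 change_cap = change_cap, anchor_window = anchor_window,
                 lambda = lambda, k = as.integer(k), filter = filter),
            class = "bp_run_config")
}

#' Run the full evaluation pipeline on a cohort
#'
#' Executes process (artifact filtering, beat extraction, 15-s segment
#' aggregation, subject exclusion), calibrate (per-activity brachial
#' recalibration of the reference; one-time offset calibration of the
#' device), train/predict (subject-wise k-fold ridge ensemble on the PPG
#' features, unless `device_source = "direct"`), and evaluate (Accuracy,
#' Stability, Change, Bland-Altman, within-subject change, ICC, criteria
#' report).
#'
#' @param cohort a `bp_cohort` from [simulate_cohort()] (or [cohort_read()]).
#' @param config a [run_config()].
#' @return A `bp_pipeline_result`: `report` (criteria report), `results`
#'   (per-parameter statistics and audit tables), `pairs` (all valid
#'   time-matched segment pairs), `within_subject_change`, `exclusions`,
#'   `calibration` (per-subject/session offsets) and `log`.
#' @export
run_pipeline <- function(cohort, config = run_config()) {
  stopifnot(inherits(cohort, "bp_cohort"), inherits(config, "bp_run_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  params3 <- c("sbp", "dbp", "map")

  ## ---- stage: process + reference calibration --------------------------
  proc <- list(); excl <- list(); cal_log <- list()
  masked_total <- 0L; sample_total <- 0L
  for (id in names(cohort$subjects)) {
    sub <- cohort$subjects[[id]]
    sessions <- list()
    seg_missing <- 0L; seg_total <- 0L
    uncal <- FALSE
    for (j in seq_along(sub$sessions)) {
      ses <- sub$sessions[[j]]
      f <- config$filter
      mask <- filter_artifacts(ses$waveform, flat_run = f$flat_run,
                               flat_eps = f$flat_eps, range = f$range,
                               hf_cutoff = f$hf_cutoff, hf_ratio = f$hf_ratio)
      masked_total <- masked_total + sum(mask)
      sample_total <- sample_total + length(mask)
      beats <- extract_beats(ses$waveform, mask = mask)
      segs <- aggregate_segments(beats, session_duration = ses$duration)
      seg_missing <- seg_missing + sum(segs$missing)
      seg_total <- seg_total + nrow(segs)
      off <- tryCatch(
        reference_calibration_offset(beats, ses$brachial, c(0, ses$rest)),
        error = function(e) NA_real_)
      if (is.na(off)) uncal <- TRUE
      ref <- segs
      for (p in params3) ref[[p]] <- ref[[p]] + off
      sessions[[j]] <- list(activity = ses$activity, day = ses$day,
                            session_key = j, duration = ses$duration,
                            rest = ses$rest, ref_segments = ref,
                            features = ses$features,
                            device_state = ses$device_state,
                            truth_segments = ses$truth_segments)
      cal_log[[length(cal_log) + 1L]] <-
        data.frame(subject = id, session_key = j, activity = ses$activity,
                   day = ses$day, ref_offset = off,
                   brachial_sbp = brachial_calibration_value(ses$brachial))
    }
    ex <- subject_exclusion(removed = seg_missing, total = seg_total)
    if (uncal && !ex$excluded) {
      ex$excluded <- TRUE
      ex$reason <- "uncalibratable_reference"
    }
    excl[[id]] <- ex
    proc[[id]] <- list(sessions = sessions, day2 = sub$day2)
    if (ex$excluded)
      note("subject %s excluded (%s, %.0f%% of reference segments removed)",
           id, ex$reason, 100 * (ex$fraction_removed %||% NA))
  }
  retained <- names(proc)[!vapply(excl, `[[`, TRUE, "excluded")]
  note("retained %d of %d subjects; %.1f%% of samples masked",
       length(retained), length(proc), 100 * masked_total / sample_total)
  if (length(retained) < config$k)
    stop_cf("only %d subject(s) retained: fewer than k = %d folds",
            length(retained), config$k)

  seeds <- derive_seeds(config$seed, 10L)

  ## ---- stage: device estimates ----------------------------------------
  # long per-segment table: one row per subject/session/window
  seg_rows <- list()
  for (id in retained) {
    for (ses in proc[[id]]$sessions) {
      r <- ses$ref_segments
      row <- data.frame(subject = id, day = ses$day,
                        session_key = ses$session_key,
                        activity = ses$activity,
                        window_start = r$window_start,
                        ref_sbp = r$sbp, ref_dbp = r$dbp, ref_map = r$map,
                        ref_missing = r$missing)
      fx <- ses$features
      row <- cbind(row, fx[match(r$window_start, fx$window_start),
                           setdiff(names(fx), "window_start"), drop = FALSE])
      ds <- ses$device_state
      mi <- match(r$window_start, ds$window_start)
      row$direct_sbp <- ds$sbp[mi]; row$direct_dbp <- ds$dbp[mi]
      row$direct_map <- ds$map[mi]
      seg_rows[[length(seg_rows) + 1L]] <- row
    }
  }
  seg <- do.call(rbind, seg_rows)
  rownames(seg) <- NULL

  split <- subject_kfold_split(retained, k = config$k, seed = seeds[1])
  ensemble <- NULL
  if (config$device_source == "model") {
    feat_cols <- intersect(FEATURE_NAMES, names(seg))
    if (!length(feat_cols)) feat_cols <- setdiff(
      names(seg), c("subject", "day", "session_key", "activity",
                    "window_start", "ref_sbp", "ref_dbp", "ref_map",
                    "ref_missing", "direct_sbp", "direct_dbp", "direct_map",
                    "missing"))
    train_sel <- seg$day == 1L & !seg$ref_missing
    ensemble <- train_ensemble(
      seg[train_sel, feat_cols, drop = FALSE],
      data.frame(sbp = seg$ref_sbp, dbp = seg$ref_dbp,
                 map = seg$ref_map)[train_sel, ],
      subjects = seg$subject[train_sel], split = split,
      lambda = config$lambda)
    preds <- predict(ensemble, seg[, feat_cols, drop = FALSE],
                     subjects = seg$subject, mode = config$mode)
    seg$dev_sbp <- preds$sbp; seg$dev_dbp <- preds$dbp; seg$dev_map <- preds$map
    note("trained %d-fold ensembles on %d segments (%s mode)",
         config$k, sum(train_sel), config$mode)
  } else {
    seg$dev_sbp <- seg$direct_sbp; seg$dev_dbp <- seg$direct_dbp
    seg$dev_map <- seg$direct_map
    note("using direct device estimates")
  }

  ## ---- stage: one-point device calibration -----------------------------
  dev_offsets <- list()
  seg_cal <- list()
  for (id in retained) {
    rows <- seg[seg$subject == id, , drop = FALSE]
    device <- data.frame(session_key = rows$session_key,
                         window_start = rows$window_start,
                         sbp = rows$dev_sbp, dbp = rows$dev_dbp,
                         map = rows$dev_map)
    reference <- data.frame(session_key = rows$session_key,
                            window_start = rows$window_start,
                            sbp = rows$ref_sbp, dbp = rows$ref_dbp,
                            map = rows$ref_map)
    cal <- tryCatch(
      calibrate_device_once(device, reference,
                            anchor_window = config$anchor_window),
      error = function(e) NULL)
    if (is.null(cal)) {
      excl[[id]]$excluded <- TRUE
      excl[[id]]$reason <- "uncalibratable_device"
      note("subject %s excluded (device one-point calibration failed)", id)
      next
    }
    rows$dev_sbp <- cal$device$sbp; rows$dev_dbp <- cal$device$dbp
    rows$dev_map <- cal$device$map
    dev_offsets[[id]] <- cal$offset
    seg_cal[[id]] <- rows
  }
  retained <- names(seg_cal)
  seg <- do.call(rbind, seg_cal)
  rownames(seg) <- NULL

  ## ---- stage: evaluate --------------------------------------------------
  pair_rows <- list()
  for (p in params3) {
    pr <- data.frame(subject = seg$subject, day = seg$day,
                     activity = seg$activity,
                     window_start = seg$window_start, parameter = p,
                     ref = seg[[paste0("ref_", p)]],
                     dev = seg[[paste0("dev_", p)]])
    pair_rows[[p]] <- pr[is.finite(pr$ref) & is.finite(pr$dev), , drop = FALSE]
  }
  pairs <- do.call(rbind, pair_rows)
  rownames(pairs) <- NULL

  results <- list()
  for (i in seq_along(params3)) {
    p <- params3[i]
    pp <- pair_rows[[p]]
    d1 <- pp[pp$day == 1L, , drop = FALSE]
    d2 <- pp[pp$day == 2L, , drop = FALSE]
    acc_sel <- select_pairs(d1, config$accuracy_n, seed = seeds[2] + i)
    acc <- accuracy_statistic(acc_sel)
    stab <- NULL
    if (nrow(d2)) stab <- stability_statistic(d1, d2, config$stability_n,
                                              seed = seeds[3] + i)
    ch <- change_pairs(d1[, c("subject", "activity", "window_start",
                              "ref", "dev")],
                       threshold = config$change_thresholds[[p]],
                       cap = config$change_cap, seed = seeds[4] + i)
    chg <- if (nrow(ch)) change_percentiles(ch) else NULL
    ba <- bland_altman(d1)
    icc_acc <- tryCatch(icc(acc_sel$dev - acc_sel$ref, acc_sel$subject),
                        error = function(e) NULL)
    results[[p]] <- list(accuracy = acc, stability = stab,
                         change = chg, change_pairs = ch,
                         bland_altman = ba, icc = icc_acc,
                         accuracy_pairs = acc_sel)
    note("%s: accuracy n=%d mean %.2f (%.2f); change pairs %d",
         p, acc$n, acc$mean_diff, acc$sd_diff, nrow(ch))
  }
  wsc <- within_subject_change(
    data.frame(subject = pair_rows$sbp$subject[pair_rows$sbp$day == 1L],
               activity = pair_rows$sbp$activity[pair_rows$sbp$day == 1L],
               ref = pair_rows$sbp$ref[pair_rows$sbp$day == 1L]))

  report <- criteria_report(lapply(results, function(r)
    list(accuracy = r$accuracy, stability = r$stability, change = r$change)))

  structure(list(report = report, results = results, pairs = pairs,
                 within_subject_change = wsc, exclusions = excl,
                 retained = retained,
                 calibration = list(reference = do.call(rbind, cal_log),
                                    device_offsets = dev_offsets),
                 ensemble = ensemble, split = split, config = config,
                 log = log),
            class = "bp_pipeline_result")
}

#' @export
print.bp_pipeline_result <- function(x, ...) {
  cat(sprintf("<bp_pipeline_result> %d subject(s) retained, %s/%s\n\n",
              length(x$retained), x$config$mode, x$config$device_source))
  print(x$report)
  invisible(x)
}
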