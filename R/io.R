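#' Write a simulated cohort to a directory of CSV files
#'
#' One directory per subject, one per session, each holding `waveform.csv`
#' (`time_s`, `pressure_mmHg`), `r_peaks.csv` (`time_s`), `features.csv`
#' (`segment_start_s` + feature columns), `brachial.csv` (`time_s`, `sbp`,
#' `dbp`), `truth.csv` (`beat_time_s`, `beat_end_s`, `sbp`, `dbp`, `map`,
#' `hr`) and `device.csv` (`segment_start_s`, `sbp`, `dbp`, `map`, `hr`),
#' plus a YAML manifest at the root.
#'
#' @param cohort a `bp_cohort`.
#' @param dir output directory (created if needed).
#' @param waveforms write the (large) waveform CSVs? Default `TRUE`.
#' @return `dir`, invisibly.
#' @export
cohort_write <- function(cohort, dir, waveforms = TRUE) {
  stopifnot(inherits(cohort, "bp_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_subjects = length(cohort$subjects),
                   seed = cohort$seed,
                   sampling_rate = cohort$sampling_rate,
                   day2_ids = as.list(cohort$day2_ids),
                   subjects = list())
  for (id in names(cohort$subjects)) {
    sub <- cohort$subjects[[id]]
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    ses_meta <- list()
    for (j in seq_along(sub$sessions)) {
      ses <- sub$sessions[[j]]
      sesdir <- file.path(sdir, sprintf("session%02d_%s_day%d", j,
                                        ses$activity, ses$day))
      dir.create(sesdir, showWarnings = FALSE)
      wf <- ses$waveform
      if (waveforms) {
        n <- length(wf$pressure)
        write.csv(data.frame(time_s = (seq_len(n) - 1) / wf$sampling_rate,
                             pressure_mmHg = wf$pressure),
                  file.path(sesdir, "waveform.csv"), row.names = FALSE)
      }
      write.csv(data.frame(time_s = wf$rpeaks),
                file.path(sesdir, "r_peaks.csv"), row.names = FALSE)
      fx <- ses$features
      names(fx)[names(fx) == "window_start"] <- "segment_start_s"
      write.csv(fx, file.path(sesdir, "features.csv"), row.names = FALSE)
      write.csv(data.frame(time_s = ses$brachial$time, sbp = ses$brachial$sbp,
                           dbp = ses$brachial$dbp),
                file.path(sesdir, "brachial.csv"), row.names = FALSE)
      tb <- ses$truth_beats
      write.csv(data.frame(beat_time_s = tb$start, beat_end_s = tb$end,
                           sbp = tb$sbp, dbp = tb$dbp, map = tb$map,
                           hr = tb$hr),
                file.path(sesdir, "truth.csv"), row.names = FALSE)
      ds <- ses$device_state
      names(ds)[names(ds) == "window_start"] <- "segment_start_s"
      write.csv(ds, file.path(sesdir, "device.csv"), row.names = FALSE)
      ses_meta[[j]] <- list(dir = basename(sesdir), activity = ses$activity,
                            day = ses$day, duration = ses$duration,
                            rest = ses$rest,
                            sampling_rate = wf$sampling_rate)
    }
    p <- sub$params
    manifest$subjects[[id]] <-
      list(id = id, day2 = sub$day2, sessions = ses_meta,
           params = list(sbp_base = p$sbp_base, dbp_base = p$dbp_base,
                         hr_base = p$hr_base, noise_sd = p$noise_sd,
                         hr_noise_sd = p$hr_noise_sd,
                         dbp_noise_frac = p$dbp_noise_frac,
                         seed = p$seed,
                         amplitudes = lapply(p$amplitudes, as.list)))
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [cohort_write()]
#'
#' @param dir cohort directory containing `manifest.yaml`.
#' @return A `bp_cohort` (waveforms must have been written).
#' @export
cohort_read <- function(dir) {
  mf <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  subjects <- list()
  for (id in names(mf$subjects)) {
    sm <- mf$subjects[[id]]
    sessions <- list()
    for (j in seq_along(sm$sessions)) {
      meta <- sm$sessions[[j]]
      sesdir <- file.path(dir, id, meta$dir)
      wfcsv <- file.path(sesdir, "waveform.csv")
      if (!file.exists(wfcsv))
        stop_cf("no waveform.csv in %s (cohort written with waveforms = FALSE?)", sesdir)
      wfd <- read.csv(wfcsv)
      rp <- read.csv(file.path(sesdir, "r_peaks.csv"))$time_s
      wf <- bp_waveform(wfd$pressure_mmHg, meta$sampling_rate, rp,
                        activity = meta$activity, subject = id,
                        day = meta$day)
      tb <- read.csv(file.path(sesdir, "truth.csv"))
      truth_beats <- data.frame(start = tb$beat_time_s, end = tb$beat_end_s,
                                sbp = tb$sbp, dbp = tb$dbp, map = tb$map,
                                hr = tb$hr)
      fx <- read.csv(file.path(sesdir, "features.csv"))
      names(fx)[names(fx) == "segment_start_s"] <- "window_start"
      br <- read.csv(file.path(sesdir, "brachial.csv"))
      brachial <- data.frame(time = br$time_s, sbp = br$sbp, dbp = br$dbp)
      class(brachial) <- c("bp_brachial_triplet", "data.frame")
      ds <- read.csv(file.path(sesdir, "device.csv"))
      names(ds)[names(ds) == "segment_start_s"] <- "window_start"
      sessions[[j]] <- list(activity = meta$activity, day = meta$day,
                            duration = meta$duration, rest = meta$rest,
                            t_day_offset = NA_real_, waveform = wf,
                            truth_beats = truth_beats,
                            truth_segments = aggregate_segments(
                              truth_beats, session_duration = meta$duration),
                            brachial = brachial, device_state = ds,
                            features = fx)
    }
    pm <- sm$params
    params <- subject_params(id, sbp_base = pm$sbp_base,
                             dbp_base = pm$dbp_base, hr_base = pm$hr_base,
                             amplitudes = lapply(pm$amplitudes,
                                                 function(a) unlist(a)),
                             noise_sd = pm$noise_sd,
                             dbp_noise_frac = pm$dbp_noise_frac,
                             hr_noise_sd = pm$hr_noise_sd, seed = pm$seed)
    subjects[[id]] <- list(params = params, day2 = isTRUE(sm$day2),
                           sessions = sessions)
  }
  structure(list(subjects = subjects, protocol = NULL, error_model = NULL,
                 seed = mf$seed, sampling_rate = mf$sampling_rate,
                 feature_map = NULL,
                 day2_ids = unlist(mf$day2_ids) %||% character(0)),
            class = "bp_cohort")
}

#' Serialize a criteria report (or full pipeline result) to JSON
#'
#' @param x a `bp_criteria_report` or `bp_pipeline_result`.
#' @param path output file; `NULL` returns the JSON string.
#' @return the JSON string, invisibly when written to a file.
#' @export
report_json <- function(x, path = NULL) {
  if (inherits(x, "bp_pipeline_result")) x <- x$report
  stopifnot(inherits(x, "bp_criteria_report"))
  obj <- list(bounds = lapply(x$bounds, as.list),
              parameters = split(x$table, x$table$parameter))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write a pipeline result's audit trail to a directory
#'
#' Emits `report.json`, `pairs.csv`, per-parameter `change_pairs_<p>.csv`,
#' `within_subject_change.csv`, `exclusions.csv`, `calibration.json` and
#' `log.txt`, so every number in the report is traceable to a flat file.
#'
#' @param result a `bp_pipeline_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
report_write <- function(result, dir) {
  stopifnot(inherits(result, "bp_pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  report_json(result, file.path(dir, "report.json"))
  write.csv(result$pairs, file.path(dir, "pairs.csv"), row.names = FALSE)
  for (p in names(result$results)) {
    cp <- result$results[[p]]$change_pairs
    if (!is.null(cp) && nrow(cp))
      write.csv(cp, file.path(dir, sprintf("change_pairs_%s.csv", p)),
                row.names = FALSE)
  }
  write.csv(result$within_subject_change,
            file.path(dir, "within_subject_change.csv"), row.names = FALSE)
  ex <- do.call(rbind, lapply(names(result$exclusions), function(id) {
    e <- result$exclusions[[id]]
    data.frame(subject = id, excluded = e$excluded,
               fraction_removed = e$fraction_removed, reason = e$reason)
  }))
  write.csv(ex, file.path(dir, "exclusions.csv"), row.names = FALSE)
  cal <- list(reference = result$calibration$reference,
              device_offsets = lapply(result$calibration$device_offsets,
                                      as.list))
  writeLines(jsonlite::toJSON(cal, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, dataframe = "rows"),
             file.path(dir, "calibration.json"))
  writeLines(result$log, file.path(dir, "log.txt"))
  invisible(dir)
}
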