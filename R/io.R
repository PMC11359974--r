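# Trial CSVs are plain comma-separated text with a header row:
# time_s, force_n[, emg_v]; time in seconds, force in newtons, EMG in volts.
# The manifest (YAML or JSON, chosen by file extension) maps each file to its
# (subject, session, trial) identifiers.

#' Read one trial trace CSV
#'
#' Reads a `time_s, force_n[, emg_v]` CSV, checks that the time axis is
#' uniform (at most 1% jitter around the median step), and infers the
#' sampling rate from the median time step.
#'
#' @param path Path to the CSV file.
#' @param subject_id,session,trial Identifiers for the recording.
#' @return A [trial_recording()]; `emg` is absent when the CSV has no EMG
#'   column.
#' @export
read_trial_csv <- function(path, subject_id, session, trial) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  tcol <- grep("^time", names(df))
  fcol <- grep("^force", names(df))
  ecol <- grep("^emg", names(df))
  if (length(tcol) != 1L) stop("CSV must have a single time column: ", path)
  if (length(fcol) != 1L) {
    stop("missing force column in ", path, call. = FALSE)
  }
  tt <- df[[tcol]]
  if (length(tt) < 2L || is.unsorted(tt, strictly = TRUE)) {
    stop("time column must be strictly increasing: ", path, call. = FALSE)
  }
  dt <- diff(tt)
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 0.01 * step) {
    stop("non-uniform sampling (jitter exceeds 1% of the median step): ",
         path, call. = FALSE)
  }
  rate <- 1 / step
  force <- signal_trace(df[[fcol]], rate, "newton")
  emg <- if (length(ecol) == 1L) signal_trace(df[[ecol]], rate, "volt")
  trial_recording(subject_id, session, trial, force, emg)
}

#' Write one trial trace CSV
#'
#' @param trial A [trial_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  df <- data.frame(time_s = trace_times(trial$force),
                   force_n = trial$force$samples)
  if (!is.null(trial$emg)) df$emg_v <- trial$emg$samples
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a study to a directory of trial CSVs plus a manifest
#'
#' One CSV per trial (named `<subject>_s<session>_t<trial>.csv`) and a
#' manifest file mapping files to identifiers.
#'
#' @param study A [study_dataset()].
#' @param dir Output directory (created if needed).
#' @param manifest_format `"yaml"` or `"json"`.
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir, manifest_format = c("yaml", "json")) {
  manifest_format <- match.arg(manifest_format)
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(study$trials, function(tr) {
    fn <- sprintf("%s_s%d_t%d.csv", tr$subject_id, tr$session, tr$trial)
    write_trial_csv(tr, file.path(dir, fn))
    list(file = fn, subject = tr$subject_id, session = tr$session,
         trial = tr$trial)
  })
  mpath <- file.path(dir, paste0("manifest.", manifest_format))
  if (manifest_format == "yaml") {
    yaml::write_yaml(list(trials = entries), mpath)
  } else {
    jsonlite::write_json(list(trials = entries), mpath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(mpath)
}

#' Read a study from a manifest
#'
#' @param manifest_path Path to a YAML or JSON manifest whose `trials` list
#'   holds entries `file`, `subject`, `session`, `trial`; file paths are
#'   resolved relative to the manifest's directory.
#' @return A [study_dataset()].
#' @export
read_study <- function(manifest_path) {
  ext <- tolower(tools::file_ext(manifest_path))
  man <- switch(ext,
    yaml = , yml = yaml::read_yaml(manifest_path),
    json = jsonlite::read_json(manifest_path),
    stop("manifest must be .yaml/.yml or .json", call. = FALSE))
  if (is.null(man$trials) || length(man$trials) == 0L) {
    stop("manifest lists no trials", call. = FALSE)
  }
  base <- dirname(manifest_path)
  trials <- lapply(man$trials, function(e) {
    read_trial_csv(file.path(base, e$file), e$subject, e$session, e$trial)
  })
  study_dataset(trials)
}

fmt_signif <- function(x, digits) formatC(signif(x, digits), format = "fg")

format_report_rows <- function(results) {
  # Rounding mirrors the conventional reliability-table style:
  # ICC and CI to 2 dp, SEM to 2 significant figures, SEM% to the nearest
  # integer, session means/SDs to 3 significant figures.
  data.frame(
    outcome = results$outcome,
    aggregation = results$aggregation,
    n = results$n,
    test1 = paste0(fmt_signif(results$mean_session1, 3), "±",
                   fmt_signif(results$sd_session1, 3)),
    test2 = paste0(fmt_signif(results$mean_session2, 3), "±",
                   fmt_signif(results$sd_session2, 3)),
    icc_ci = sprintf("%.2f [%.2f, %.2f]", results$icc, results$ci_low,
                     results$ci_high),
    sem = fmt_signif(results$sem, 2),
    sem_pct = as.character(round(results$sem_pct)),
    classification = paste0(results$class_point, " (lower CI ",
                            results$class_lower, ")"),
    log_transformed = results$log_transformed,
    stringsAsFactors = FALSE
  )
}

#' Write a reliability report as CSV and JSON
#'
#' Serialises a reliability table (one row per outcome x aggregation) in the
#' conventional published layout: session means +/- SD, ICC with 95% CI,
#' SEM, SEM% and the qualitative classification. The CSV and JSON carry the
#' same rounded values, so a consumer parsing either sees identical numbers.
#'
#' @param results A reliability table from [reliability_table()].
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return The formatted data frame, invisibly.
#' @export
write_report <- function(results, csv_path = NULL, json_path = NULL) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("no results to report", call. = FALSE)
  }
  rows <- format_report_rows(results)
  if (!is.null(csv_path)) utils::write.csv(rows, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    recs <- lapply(seq_len(nrow(results)), function(i) {
      list(outcome = results$outcome[i],
           aggregation = results$aggregation[i],
           n = results$n[i],
           mean_session1 = signif(results$mean_session1[i], 3),
           sd_session1 = signif(results$sd_session1[i], 3),
           mean_session2 = signif(results$mean_session2[i], 3),
           sd_session2 = signif(results$sd_session2[i], 3),
           icc = round(results$icc[i], 2),
           ci_low = round(results$ci_low[i], 2),
           ci_high = round(results$ci_high[i], 2),
           sem = signif(results$sem[i], 2),
           sem_pct = round(results$sem_pct[i]),
           classification = rows$classification[i],
           log_transformed = results$log_transformed[i])
    })
    jsonlite::write_json(recs, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(rows)
}
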