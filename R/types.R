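#' Uniformly sampled signal trace
#'
#' Container for a single-channel, uniformly sampled recording: the force
#' channel of a dynamometer (newtons) or a surface EMG channel (volts).
#' A trace must hold at least one second of data so that a pre-contraction
#' baseline window can always be estimated from it.
#'
#' @param samples Numeric vector of sample values, no missing values.
#' @param rate_hz Sampling rate in Hz (nominally 1961 for the acquisition
#'   system this pipeline models).
#' @param units Either `"newton"` or `"volt"`.
#' @return An object of class `signal_trace` with fields `samples`,
#'   `rate_hz` and `units`.
#' @export
signal_trace <- function(samples, rate_hz, units = c("newton", "volt")) {
  units <- match.arg(units)
  samples <- as.numeric(samples)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("rate_hz must be a single positive number", call. = FALSE)
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be finite with no missing values", call. = FALSE)
  }
  if (length(samples) < rate_hz) {
    stop("trace must contain at least 1 s of data (length >= rate_hz)",
         call. = FALSE)
  }
  structure(list(samples = samples, rate_hz = rate_hz, units = units),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ %.6g Hz (%.3g s), units: %s\n",
              length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz, x$units))
  invisible(x)
}

#' Time axis of a trace
#'
#' Sample times in seconds from trace start; sample 1 is at t = 0.
#'
#' @param trace A [signal_trace()].
#' @return Numeric vector of times, same length as the samples.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  (seq_along(trace$samples) - 1L) / trace$rate_hz
}

#' One maximal-contraction trial
#'
#' A force trace plus an optional, time-aligned EMG trace for a single
#' maximal voluntary contraction, tagged with subject, session and trial
#' identifiers. EMG may be absent (electrode failure or missing channel);
#' such trials still contribute force outcomes.
#'
#' @param subject_id Character subject identifier.
#' @param session Session number, 1 or 2.
#' @param trial Trial number within the session, 1 to 3.
#' @param force A [signal_trace()] in newtons.
#' @param emg A [signal_trace()] in volts, or `NULL` when the EMG channel is
#'   missing. When present it must share the force trace's rate and length.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(subject_id, session, trial, force, emg = NULL) {
  stopifnot(inherits(force, "signal_trace"))
  if (force$units != "newton") stop("force trace must be in newtons")
  session <- as.integer(session)
  trial <- as.integer(trial)
  if (!session %in% c(1L, 2L)) stop("session must be 1 or 2", call. = FALSE)
  if (!trial %in% 1:3) stop("trial must be 1, 2 or 3", call. = FALSE)
  if (!is.null(emg)) {
    stopifnot(inherits(emg, "signal_trace"))
    if (emg$units != "volt") stop("emg trace must be in volts")
    if (abs(emg$rate_hz - force$rate_hz) > 1e-9 * force$rate_hz ||
        length(emg$samples) != length(force$samples)) {
      stop("force and emg traces must share rate and duration", call. = FALSE)
    }
  }
  structure(list(subject_id = as.character(subject_id), session = session,
                 trial = trial, force = force, emg = emg),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> subject %s, session %d, trial %d, emg: %s\n",
              x$subject_id, x$session, x$trial,
              if (is.null(x$emg)) "absent" else "present"))
  invisible(x)
}

#' Two-session study dataset
#'
#' A collection of [trial_recording()] objects spanning n subjects, two
#' sessions and up to three trials per session, with a manifest data frame
#' describing each trial. Every (subject, session) pair must contribute at
#' least one trial.
#'
#' @param trials List of [trial_recording()] objects.
#' @param meta Optional free-form metadata (list), e.g. generator settings.
#' @return An object of class `study_dataset` with fields `trials`,
#'   `manifest` (data frame: subject, session, trial, has_emg) and `meta`.
#' @export
study_dataset <- function(trials, meta = list()) {
  if (length(trials) == 0L) stop("study needs at least one trial")
  ok <- vapply(trials, inherits, logical(1), what = "trial_recording")
  if (!all(ok)) stop("all elements must be trial_recording objects")
  manifest <- data.frame(
    subject = vapply(trials, function(tr) tr$subject_id, character(1)),
    session = vapply(trials, function(tr) tr$session, integer(1)),
    trial = vapply(trials, function(tr) tr$trial, integer(1)),
    has_emg = vapply(trials, function(tr) !is.null(tr$emg), logical(1)),
    stringsAsFactors = FALSE
  )
  if (!all(sort(unique(manifest$session)) %in% c(1L, 2L))) {
    stop("sessions must be labelled 1 and 2", call. = FALSE)
  }
  for (s in unique(manifest$subject)) {
    for (j in unique(manifest$session)) {
      if (!any(manifest$subject == s & manifest$session == j)) {
        stop(sprintf("subject %s has no trial in session %d", s, j),
             call. = FALSE)
      }
    }
  }
  structure(list(trials = trials, manifest = manifest, meta = meta),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<study_dataset> %d subjects x %d sessions, %d trials (%d with EMG)\n",
    length(unique(m$subject)), length(unique(m$session)), nrow(m),
    sum(m$has_emg)))
  invisible(x)
}

#' Onset-detection settings
#'
#' The automated replacement for visually confirmed contraction onset: the
#' baseline mean and SD are estimated over a pre-contraction window, and
#' onset is the first sample exceeding mean + `k_sd` x SD that stays above
#' that threshold for `min_hold_s` (a debounce against noise excursions,
#' standing in for the researcher's visual check).
#'
#' @param baseline_window_s Length of the pre-contraction baseline window in
#'   seconds (default 0.5).
#' @param k_sd Threshold in baseline SD units (default 3).
#' @param min_hold_s Time the signal must remain above threshold for a
#'   crossing to count as onset, seconds (default 0.025).
#' @return An object of class `onset_spec`.
#' @export
onset_spec <- function(baseline_window_s = 0.5, k_sd = 3, min_hold_s = 0.025) {
  stopifnot(baseline_window_s > 0, k_sd > 0, min_hold_s >= 0)
  structure(list(baseline_window_s = baseline_window_s, k_sd = k_sd,
                 min_hold_s = min_hold_s), class = "onset_spec")
}
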