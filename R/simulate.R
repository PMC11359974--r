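# Synthetic maximal-contraction generator.
#
# Trace model: quiet Gaussian baseline, then from the onset instant a
# half-logistic rise 2/(1 + exp(-u/tau)) - 1 (u = time since onset) up to the
# target peak, held through a 4-5 s plateau. The half-logistic (the upper
# half of a logistic centred at onset) is zero at onset with an immediately
# steep slope peak/(2 tau) -- the trace shape of a contraction performed "as
# fast and hard as possible" -- and has closed-form landmarks used as ground
# truth: time to fraction q of peak is tau * logit((1 + q)/2).
#
# EMG model: zero-mean broadband Gaussian noise band-limited to 10-500 Hz,
# amplitude-modulated so its instantaneous SD is
# emg_noise_sd + emg_gain * force(t).

#' Trace-shape parameters for the synthetic generator
#'
#' @param baseline_noise_sd SD of additive Gaussian sensor noise, N
#'   (default 0.5).
#' @param peak_force Target plateau force in N (default 150).
#' @param rise_tau Time constant of the half-logistic rise, s (default 0.4;
#'   gives time-to-90%-peak of `rise_tau * logit(0.95)` ~ 1.2 s). `0` means
#'   an instantaneous step.
#' @param onset_time Contraction onset, s from trace start (default 1.5;
#'   must leave at least 1 s of pre-contraction baseline).
#' @param plateau_duration Contraction duration from onset, s (default 4.5;
#'   the 4-5 s range covers rise plus plateau).
#' @param emg_gain EMG amplitude per newton of force, V/N (default 0.0013:
#'   with a ~150 N contraction this yields the ~0.2 V peak RMS typical of
#'   tibialis anterior surface EMG).
#' @param emg_noise_sd Baseline EMG amplitude SD, V (default 0.005).
#' @param rate_hz Sampling rate, Hz (default 1961).
#' @param emg Logical; generate the EMG channel? (default `TRUE`).
#' @return An object of class `trace_params`.
#' @export
trace_params <- function(baseline_noise_sd = 0.5, peak_force = 150,
                         rise_tau = 0.4, onset_time = 1.5,
                         plateau_duration = 4.5, emg_gain = 0.0013,
                         emg_noise_sd = 0.005, rate_hz = 1961, emg = TRUE) {
  stopifnot(baseline_noise_sd >= 0, peak_force > 0, rise_tau >= 0,
            onset_time >= 1.0, plateau_duration > 0, emg_gain >= 0,
            emg_noise_sd >= 0, rate_hz > 0)
  structure(list(baseline_noise_sd = baseline_noise_sd,
                 peak_force = peak_force, rise_tau = rise_tau,
                 onset_time = onset_time,
                 plateau_duration = plateau_duration, emg_gain = emg_gain,
                 emg_noise_sd = emg_noise_sd, rate_hz = rate_hz, emg = emg),
            class = "trace_params")
}

# Half-logistic rise, 0 at u = 0, -> 1 as u -> Inf; tau = 0 is a step.
rise_fraction <- function(u, tau) {
  r <- numeric(length(u))
  pos <- u >= 0
  if (tau > 0) {
    r[pos] <- 2 / (1 + exp(-u[pos] / tau)) - 1
  } else {
    r[pos] <- 1
  }
  r
}

#' Time for the synthetic rise to reach a fraction of peak force
#'
#' Closed-form inverse of the half-logistic rise: `tau * logit((1 + q)/2)`.
#' Ground truth for time-to-90%-peak (`q = 0.9`) of noiseless traces.
#'
#' @param q Fraction of peak force, in (0, 1).
#' @param rise_tau Rise time constant, s.
#' @return Time since onset, s.
#' @export
rise_time_to_fraction <- function(q, rise_tau) {
  stopifnot(q > 0, q < 1)
  p <- (1 + q) / 2
  rise_tau * log(p / (1 - p))
}

#' Generate one synthetic maximal-contraction trial
#'
#' Draws from the trace model described in [trace_params()] using the
#' current RNG state (`set.seed()` beforehand for reproducibility).
#'
#' @param p A [trace_params()].
#' @param subject_id,session,trial Identifiers stamped on the recording.
#' @return A [trial_recording()]; `emg` is absent when `p$emg` is `FALSE`.
#' @export
generate_trial_trace <- function(p, subject_id = "S01", session = 1,
                                 trial = 1) {
  stopifnot(inherits(p, "trace_params"))
  n <- round((p$onset_time + p$plateau_duration) * p$rate_hz)
  t <- (seq_len(n) - 1L) / p$rate_hz
  clean <- p$peak_force * rise_fraction(t - p$onset_time, p$rise_tau)
  force <- clean
  if (p$baseline_noise_sd > 0) {
    force <- force + stats::rnorm(n, 0, p$baseline_noise_sd)
  }
  emg <- NULL
  if (p$emg) {
    w <- stats::rnorm(n)
    if (p$rate_hz > 1000) {
      bp <- signal::butter(4, c(10, 500) / (p$rate_hz / 2), type = "pass")
      w <- filtfilt_reflect(bp, w, pad_s = 0.3, rate_hz = p$rate_hz)
    }
    w <- w / stats::sd(w)
    emg_samples <- (p$emg_noise_sd + p$emg_gain * clean) * w
    emg <- signal_trace(emg_samples, p$rate_hz, "volt")
  }
  trial_recording(subject_id, session, trial,
                  signal_trace(force, p$rate_hz, "newton"), emg)
}

#' Variance-component study design
#'
#' The two-way random-effects structure that the absolute-agreement ICC
#' assumes: the target peak force of subject i, session j, trial t is
#' `mu + b_i + s_ij + w_ijt` with independent Gaussian components
#' `b_i ~ N(0, sigma_between^2)` (stable subject level),
#' `s_ij ~ N(0, sigma_session^2)` (subject-by-session interaction, drawn per
#' subject and session) and `w_ijt ~ N(0, sigma_trial^2)` (trial-to-trial
#' noise). Subjects' rise time constants vary multiplicatively (lognormal,
#' unit mean) so rapid-force outcomes carry their own between-subject
#' variance.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param mu Population mean target peak force, N.
#' @param sigma_between Between-subject SD, N.
#' @param sigma_session Subject-by-session SD, N.
#' @param sigma_trial Within-session trial SD, N.
#' @param trials_per_session Trials per session (default 3).
#' @param tau_between_cv,tau_trial_cv Coefficients of variation of the
#'   subject-level and trial-level rise-time multipliers (defaults 0.4 and
#'   0.2, matching the wide spread of time-to-90%-peak seen in hemiparetic
#'   dorsiflexors).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `study_params`.
#' @export
study_params <- function(n_subjects, mu, sigma_between, sigma_session,
                         sigma_trial, trials_per_session = 3,
                         tau_between_cv = 0.4, tau_trial_cv = 0.2,
                         seed = 1L) {
  stopifnot(n_subjects >= 2, is.finite(mu), sigma_between >= 0,
            sigma_session >= 0, sigma_trial >= 0, trials_per_session >= 1,
            tau_between_cv >= 0, tau_trial_cv >= 0)
  structure(list(n_subjects = as.integer(n_subjects), mu = mu,
                 sigma_between = sigma_between,
                 sigma_session = sigma_session, sigma_trial = sigma_trial,
                 trials_per_session = as.integer(trials_per_session),
                 tau_between_cv = tau_between_cv,
                 tau_trial_cv = tau_trial_cv, seed = as.integer(seed)),
            class = "study_params")
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a full two-session synthetic study
#'
#' Draws per-trial target peaks from the variance-component model in
#' [study_params()] (floored at 1 N so all outcomes stay positive and
#' log-transformable) and synthesises a trace for every trial. A warning is
#' issued when more than 1% of raw targets fall at or below zero, which
#' signals that a Gaussian model for strictly positive forces is
#' misspecified for the chosen parameters.
#'
#' @param sp A [study_params()].
#' @param p A [trace_params()]; its `peak_force` and `rise_tau` act as the
#'   population baseline that the variance components perturb.
#' @return A [study_dataset()] whose `meta` records the generating
#'   parameters and the per-trial target peaks.
#' @export
generate_study <- function(sp, p = trace_params()) {
  stopifnot(inherits(sp, "study_params"), inherits(p, "trace_params"))
  with_seed(sp$seed, {
    trials <- list()
    targets <- data.frame()
    n_nonpos <- 0L
    for (i in seq_len(sp$n_subjects)) {
      sid <- sprintf("S%02d", i)
      b <- stats::rnorm(1, 0, sp$sigma_between)
      tau_i <- p$rise_tau * rlnorm_cv(1, sp$tau_between_cv)
      for (j in 1:2) {
        s_ij <- stats::rnorm(1, 0, sp$sigma_session)
        for (tt in seq_len(sp$trials_per_session)) {
          w <- stats::rnorm(1, 0, sp$sigma_trial)
          target <- sp$mu + b + s_ij + w
          if (target <= 0) n_nonpos <- n_nonpos + 1L
          target <- max(target, 1)
          tau_ijt <- tau_i * rlnorm_cv(1, sp$tau_trial_cv)
          pt <- p
          pt$peak_force <- target
          pt$rise_tau <- tau_ijt
          trials[[length(trials) + 1L]] <-
            generate_trial_trace(pt, sid, j, tt)
          targets <- rbind(targets, data.frame(
            subject = sid, session = j, trial = tt, target_peak_n = target,
            rise_tau_s = tau_ijt, stringsAsFactors = FALSE))
        }
      }
    }
    n_total <- sp$n_subjects * 2L * sp$trials_per_session
    if (n_nonpos > 0.01 * n_total) {
      warning(sprintf(
        "%d of %d target peaks <= 0 before flooring; ", n_nonpos, n_total),
        "Gaussian force model is misspecified for these parameters")
    }
    study_dataset(trials, meta = list(study_params = unclass(sp),
                                      trace_params = unclass(p),
                                      targets = targets))
  })
}

#' Simulate an aggregated outcome matrix directly from the variance model
#'
#' Draws session-level aggregated outcomes from the [study_params()]
#' variance-component model without synthesising traces: subject i gets
#' level `mu + b_i`; session j adds `s_ij`; each of m trials adds `w_ijt`;
#' the m trials are then aggregated by mean or max/min. This is the
#' outcome-scale view of [generate_study()] used for large-n reliability
#' simulations (parameter recovery, CI coverage), where per-sample trace
#' synthesis is unnecessary.
#'
#' Uses the current RNG state; seed it with `set.seed()`.
#'
#' @param sp A [study_params()] (`tau_*` fields are ignored here).
#' @param aggregation `"mean3"` (mean of the m trials), `"best3"` (max) or
#'   `"best3min"` (min; the "best" direction for time-based outcomes).
#' @return An `n_subjects x 2` numeric matrix, one row per subject, columns
#'   session 1 and 2.
#' @export
simulate_outcome_matrix <- function(sp,
                                    aggregation = c("mean3", "best3",
                                                    "best3min")) {
  stopifnot(inherits(sp, "study_params"))
  aggregation <- match.arg(aggregation)
  n <- sp$n_subjects
  m <- sp$trials_per_session
  b <- stats::rnorm(n, 0, sp$sigma_between)
  out <- matrix(NA_real_, n, 2)
  for (j in 1:2) {
    s <- stats::rnorm(n, 0, sp$sigma_session)
    w <- matrix(stats::rnorm(n * m, 0, sp$sigma_trial), n, m)
    vals <- sp$mu + b + s + w
    out[, j] <- switch(aggregation,
      mean3 = rowMeans(vals),
      best3 = apply(vals, 1, max),
      best3min = apply(vals, 1, min))
  }
  colnames(out) <- c("session1", "session2")
  out
}

#' True ICC(2,1) implied by study parameters
#'
#' For mean-of-m aggregation the absolute-agreement ICC has the closed form
#' `sigma_b^2 / (sigma_b^2 + sigma_s^2 + sigma_t^2 / m)`. Best-of-m has no
#' clean closed form (the max of correlated normals); the mean-of-m value is
#' returned as an approximation and flagged via the `"approximate"`
#' attribute. Simulation-based truth should be preferred for best-of-m.
#'
#' @param sp A [study_params()].
#' @param aggregation `"mean3"` or `"best3"`.
#' @return The true ICC in `[0, 1]`; attribute `approximate` is `TRUE` for
#'   best-of-m.
#' @export
true_icc <- function(sp, aggregation = c("mean3", "best3")) {
  stopifnot(inherits(sp, "study_params"))
  aggregation <- match.arg(aggregation)
  vb <- sp$sigma_between^2
  vs <- sp$sigma_session^2
  vt <- sp$sigma_trial^2 / sp$trials_per_session
  if (vb + vs + vt == 0) stop("all variance components are zero")
  icc <- vb / (vb + vs + vt)
  attr(icc, "approximate") <- aggregation == "best3"
  icc
}
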