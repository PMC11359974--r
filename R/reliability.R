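# Trial aggregation and the absolute-agreement reliability layer:
# two-way random-effects ANOVA -> ICC(2,1) with McGraw-Wong 95% CI,
# SEM = sqrt(MS_error), SEM% = 100 * SEM / grand mean, and the conventional
# qualitative bands (excellent >= 0.90, good 0.75-0.89, moderate 0.50-0.74,
# poor < 0.50) applied to both the point estimate and the lower CI bound.

# outcome columns that reliability is computed for, and the direction of
# "best": larger is better except for time-to-90%-peak (faster is better)
.outcome_cols <- c(mvc_n = "max", rfd200_n_per_s = "max",
                   t90_s = "min", peak_emg_rms_v = "max")

#' Aggregate up to three trial values
#'
#' `mean3` is the arithmetic mean of the available trials; `best3` is the
#' maximum for force, RFD and EMG outcomes and the minimum for
#' time-to-90%-peak (the fastest trial is the best one). Ties take the first
#' occurrence. Fewer than three trials are aggregated over what is
#' available.
#'
#' @param values Numeric vector of 1-3 per-trial values.
#' @param method `"mean3"` or `"best3"`.
#' @param direction `"max"` or `"min"`: which end is "best".
#' @return The aggregated scalar.
#' @export
aggregate_trials <- function(values, method = c("mean3", "best3"),
                             direction = c("max", "min")) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no trial values to aggregate",
                                 call. = FALSE)
  switch(method,
         mean3 = mean(values),
         best3 = if (direction == "max") max(values) else min(values))
}

#' Aggregate per-trial outcomes to subject-session level
#'
#' Collapses the per-trial outcome table from [extract_study_outcomes()] to
#' one row per (subject, session) for a given aggregation method.
#' Subject-sessions with fewer than three trials are aggregated over the
#' available trials and flagged in the `n_trials` column.
#'
#' @param outcomes Per-trial outcome data frame.
#' @param method `"mean3"` or `"best3"`.
#' @return Data frame: subject, session, n_trials, and one column per
#'   outcome.
#' @export
aggregate_study_outcomes <- function(outcomes, method = c("mean3", "best3")) {
  method <- match.arg(method)
  keys <- unique(outcomes[c("subject", "session")])
  keys <- keys[order(keys$subject, keys$session), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- outcomes[outcomes$subject == keys$subject[i] &
                      outcomes$session == keys$session[i], , drop = FALSE]
    row <- data.frame(subject = keys$subject[i], session = keys$session[i],
                      n_trials = nrow(sub), stringsAsFactors = FALSE)
    for (oc in names(.outcome_cols)) {
      v <- sub[[oc]]
      row[[oc]] <- if (all(is.na(v))) NA_real_ else
        aggregate_trials(v, method, .outcome_cols[[oc]])
    }
    row
  })
  do.call(rbind, rows)
}

#' Build the n x 2 outcome matrix for one outcome
#'
#' Pivots aggregated subject-session values into the n-subjects x 2-sessions
#' matrix that the reliability analysis operates on. Subjects missing either
#' session's value (e.g. missing EMG) are dropped listwise; dropped subjects
#' are recorded in the `"dropped"` attribute and reported via `message()`.
#'
#' @param aggregated Output of [aggregate_study_outcomes()].
#' @param outcome Name of the outcome column.
#' @return Numeric matrix with rownames = subject ids and a `"dropped"`
#'   attribute.
#' @export
outcome_matrix <- function(aggregated, outcome) {
  stopifnot(outcome %in% names(aggregated))
  subjects <- unique(aggregated$subject)
  m <- matrix(NA_real_, length(subjects), 2,
              dimnames = list(subjects, c("session1", "session2")))
  for (j in 1:2) {
    sub <- aggregated[aggregated$session == j, , drop = FALSE]
    m[sub$subject, j] <- sub[[outcome]]
  }
  complete <- stats::complete.cases(m)
  dropped <- subjects[!complete]
  if (length(dropped) > 0) {
    message(sprintf("%s: dropping %d subject(s) with a missing session: %s",
                    outcome, length(dropped),
                    paste(dropped, collapse = ", ")))
  }
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 complete subjects", call. = FALSE)
  attr(m, "dropped") <- dropped
  m
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over `stats::shapiro.test` (Royston's approximation),
#' the screening test applied per session column before deciding on a log
#' transform.
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::sd(values) == 0) stop("constant input", call. = FALSE)
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Log-transform an outcome matrix when either session is non-normal
#'
#' Tests each session column with Shapiro-Wilk; if either p-value falls
#' below `alpha`, applies the natural log to all cells (requires strictly
#' positive values) and sets the flag.
#'
#' @param m n x 2 numeric matrix.
#' @param alpha Significance level for the normality screen (default 0.05).
#' @return List: `matrix` (possibly transformed), `log_transformed` flag,
#'   `shapiro_p` (per-session p-values).
#' @export
maybe_log_transform <- function(m, alpha = 0.05) {
  p <- vapply(1:2, function(j) shapiro_wilk(m[, j])$p, numeric(1))
  transform <- alpha > 0 && any(p < alpha)
  if (transform) {
    if (any(m <= 0)) {
      stop("log transform triggered with non-positive values",
           call. = FALSE)
    }
    m <- log(m)
  }
  list(matrix = m, log_transformed = transform, shapiro_p = p)
}

#' Two-way one-observation-per-cell ANOVA decomposition
#'
#' Mean squares for subjects (rows), sessions (columns) and residual from
#' the standard two-way decomposition with one observation per cell -- the
#' random-effects ANOVA underlying ICC(2,1). The sums of squares satisfy
#' SS_total = SS_rows + SS_cols + SS_error.
#'
#' @param m n x k numeric matrix (k = 2 sessions), complete.
#' @return List of class `anova_decomp`: `ms_rows`, `ms_cols`, `ms_error`,
#'   `n`, `k`, `grand_mean`.
#' @export
two_way_anova <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("matrix must be complete", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  gm <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - gm)^2)
  ss_cols <- n * sum((colMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  structure(list(ms_rows = ss_rows / (n - 1), ms_cols = ss_cols / (k - 1),
                 ms_error = max(ss_err, 0) / ((n - 1) * (k - 1)),
                 n = n, k = k, grand_mean = gm),
            class = "anova_decomp")
}

#' ICC(2,1): single-measure, absolute-agreement intraclass correlation
#'
#' Point estimate from the two-way random-effects mean squares,
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the 95%
#' confidence interval by the McGraw-Wong F-based procedure for
#' single-measure absolute agreement (Satterthwaite degrees of freedom for
#' the bounds). When the residual and session mean squares are exactly zero
#' (perfect agreement) the interval degenerates to the point estimate.
#'
#' @param a An `anova_decomp` from [two_way_anova()].
#' @param conf Confidence level (default 0.95).
#' @return List: `icc`, `ci_low`, `ci_high`.
#' @export
icc21 <- function(a, conf = 0.95) {
  stopifnot(inherits(a, "anova_decomp"))
  n <- a$n
  k <- a$k
  msr <- a$ms_rows
  msc <- a$ms_cols
  mse <- a$ms_error
  if (msr == 0 && msc == 0 && mse == 0) {
    stop("degenerate: no variance", call. = FALSE)
  }
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0) {
    # undefined point of the formula (diverges under perturbation); report
    # the admissible floor for k = 2 with an uninformative interval
    return(list(icc = -1, ci_low = -1, ci_high = 1))
  }
  icc <- (msr - mse) / denom
  if (mse == 0 && msc == 0) {
    return(list(icc = icc, ci_low = icc, ci_high = icc))
  }
  alpha <- 1 - conf
  aa <- (k * icc) / (n * (1 - icc))
  bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (aa * msc + bb * mse)^2 /
    ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high)
}

#' Standard error of measurement and its percentage
#'
#' Default formula: SEM = sqrt(MS_error) of the two-way ANOVA, the
#' within-subject error SD consistent with the absolute-agreement model.
#' The classical alternative `sd * sqrt(1 - ICC)` (pooled SD of both
#' sessions) is available via `formula = "sd1micc"`. SEM% is
#' 100 * SEM / grand mean of all cells, on the analysis scale (for
#' log-transformed outcomes both are reported on the log scale).
#'
#' @param a An `anova_decomp`.
#' @param m The analysed matrix (for the grand mean and pooled SD).
#' @param formula `"mse"` (default) or `"sd1micc"`.
#' @param icc Point ICC, required for `"sd1micc"`.
#' @return List: `sem`, `sem_pct`.
#' @export
sem_and_pct <- function(a, m, formula = c("mse", "sd1micc"), icc = NULL) {
  formula <- match.arg(formula)
  sem <- switch(formula,
    mse = sqrt(a$ms_error),
    sd1micc = {
      if (is.null(icc)) stop("icc required for sd1micc formula")
      stats::sd(as.vector(m)) * sqrt(1 - icc)
    })
  gm <- mean(m)
  if (gm == 0) stop("grand mean is zero; SEM% undefined", call. = FALSE)
  list(sem = sem, sem_pct = 100 * sem / gm)
}

#' Qualitative reliability classification
#'
#' Conventional bands: excellent (>= 0.90), good (0.75-0.89), moderate
#' (0.50-0.74), poor (< 0.50), applied to the ICC point estimate and to the
#' lower 95% CI bound.
#'
#' @param icc,ci_low Values in `[-1, 1]`.
#' @return List: `class_point`, `class_lower` (each one of "excellent",
#'   "good", "moderate", "poor").
#' @export
classify_icc <- function(icc, ci_low) {
  band <- function(x) {
    if (x >= 0.90) "excellent"
    else if (x >= 0.75) "good"
    else if (x >= 0.50) "moderate"
    else "poor"
  }
  list(class_point = band(icc), class_lower = band(ci_low))
}

#' Reliability of one outcome matrix
#'
#' Runs the full reliability chain on an n x 2 matrix: optional normality
#' screen and log transform, two-way ANOVA, ICC(2,1) with 95% CI, SEM and
#' SEM%, classification. Session means and SDs are reported on the raw
#' scale for readability even when the agreement statistics are computed on
#' the log scale (flagged).
#'
#' @param m n x 2 numeric matrix (session columns).
#' @param outcome Outcome label for the result row.
#' @param aggregation Aggregation label (`"mean3"`/`"best3"`).
#' @param alpha Normality-screen level; `0` disables the log transform.
#' @param log_transform Allow the transform at all? (default `TRUE`).
#' @param sem_formula `"mse"` or `"sd1micc"`.
#' @return One-row data frame (a reliability-table row).
#' @export
reliability_row <- function(m, outcome = "outcome",
                            aggregation = c("mean3", "best3"),
                            alpha = 0.05, log_transform = TRUE,
                            sem_formula = "mse") {
  aggregation <- match.arg(aggregation)
  m <- as.matrix(m)
  raw <- m
  flag <- FALSE
  if (log_transform && alpha > 0) {
    lt <- maybe_log_transform(m, alpha)
    m <- lt$matrix
    flag <- lt$log_transformed
  }
  a <- two_way_anova(m)
  ic <- icc21(a)
  sp <- sem_and_pct(a, m, sem_formula, icc = ic$icc)
  cl <- classify_icc(ic$icc, ic$ci_low)
  data.frame(outcome = outcome, aggregation = aggregation, n = a$n,
             mean_session1 = mean(raw[, 1]), sd_session1 = stats::sd(raw[, 1]),
             mean_session2 = mean(raw[, 2]), sd_session2 = stats::sd(raw[, 2]),
             icc = ic$icc, ci_low = ic$ci_low, ci_high = ic$ci_high,
             sem = sp$sem, sem_pct = sp$sem_pct, log_transformed = flag,
             class_point = cl$class_point, class_lower = cl$class_lower,
             stringsAsFactors = FALSE)
}

#' Full reliability table for a study's extracted outcomes
#'
#' For each outcome (MVC, RFD200ms, time-to-90%-peak, peak EMG RMS when
#' present) and each aggregation (mean of three, best of three): builds the
#' n x 2 matrix (dropping incomplete subjects listwise), screens normality,
#' optionally log-transforms, and computes ICC(2,1), 95% CI, SEM, SEM% and
#' the classification. Eight rows result when all four outcomes are present.
#'
#' @param outcomes Per-trial outcome data frame from
#'   [extract_study_outcomes()].
#' @param aggregations Character vector of aggregation methods.
#' @param alpha Normality-screen level (default 0.05).
#' @param log_transform Allow log transforms (default `TRUE`).
#' @param sem_formula `"mse"` or `"sd1micc"`.
#' @return Data frame with one row per outcome x aggregation; attribute
#'   `"dropped"` lists dropped subjects per outcome.
#' @export
reliability_table <- function(outcomes,
                              aggregations = c("mean3", "best3"),
                              alpha = 0.05, log_transform = TRUE,
                              sem_formula = "mse") {
  rows <- list()
  dropped <- list()
  for (agg in aggregations) {
    agg_df <- aggregate_study_outcomes(outcomes, agg)
    for (oc in names(.outcome_cols)) {
      if (all(is.na(agg_df[[oc]]))) next
      mm <- outcome_matrix(agg_df, oc)
      dropped[[paste(oc, agg, sep = ".")]] <- attr(mm, "dropped")
      rows[[length(rows) + 1L]] <-
        reliability_row(mm, oc, agg, alpha, log_transform, sem_formula)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "dropped") <- dropped
  out
}
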