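# Shared fixtures and independent oracles used across the suite.

# Noiseless step trial: flat baseline `baseline` for `onset_s` seconds, then
# an instantaneous step to baseline + peak, held to the end.
make_step_trial <- function(peak = 100, baseline = 0, onset_s = 1.0,
                            total_s = 3.0, rate = 1961) {
  n <- round(total_s * rate)
  t <- (seq_len(n) - 1L) / rate
  x <- baseline + ifelse(t >= onset_s, peak, 0)
  signal_trace(x, rate, "newton")
}

# Linear ramp: baseline until onset, then slope r N/s up to a plateau.
make_ramp_trace <- function(slope = 500, onset_s = 1.0, ramp_s = 1.0,
                            total_s = 4.0, rate = 1961, baseline = 0) {
  n <- round(total_s * rate)
  t <- (seq_len(n) - 1L) / rate
  u <- pmin(pmax(t - onset_s, 0), ramp_s)
  signal_trace(baseline + slope * u, rate, "newton")
}

# Exhaustive sample-by-sample scan applying the onset rule directly,
# independent of detect_onset's rle-based implementation.
onset_scan_oracle <- function(trace, spec) {
  x <- trace$samples
  rate <- trace$rate_hz
  nb <- round(spec$baseline_window_s * rate)
  m <- mean(x[1:nb])
  s <- sd(x[1:nb])
  thr <- m + spec$k_sd * s
  hold_n <- max(1L, round(spec$min_hold_s * rate))
  for (i in (nb + 1L):length(x)) {
    if (x[i] > thr) {
      j <- min(i + hold_n - 1L, length(x))
      if (all(x[i:j] > thr)) return((i - 1L) / rate)
    }
  }
  NA_real_
}

# Naive double-loop two-way ANOVA sums of squares.
anova_naive <- function(m) {
  n <- nrow(m); k <- ncol(m); gm <- mean(m)
  ssr <- 0; ssc <- 0; sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ri <- mean(m[i, ]); cj <- mean(m[, j])
    sse <- sse + (m[i, j] - ri - cj + gm)^2
  }
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - gm)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - gm)^2
  list(ms_rows = ssr / (n - 1), ms_cols = ssc / (k - 1),
       ms_error = sse / ((n - 1) * (k - 1)))
}

# Independent reference for single-measure absolute-agreement ICC + 95% CI:
# Python pingouin (ICC(A,1) row, rounding disabled). Takes a list of n x 2
# matrices, returns a data frame icc/ci_low/ci_high, one row per matrix.
pingouin_icc_reference <- function(matrices) {
  tmp_in <- tempfile(fileext = ".csv")
  tmp_out <- tempfile(fileext = ".csv")
  long <- do.call(rbind, lapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    data.frame(set = i, subject = rep(seq_len(nrow(m)), 2),
               session = rep(1:2, each = nrow(m)), value = as.vector(m))
  }))
  utils::write.csv(long, tmp_in, row.names = FALSE)
  script <- c(
    "import sys, pandas as pd, pingouin as pg",
    "pg.options['round'] = None",
    "pg.options['round.column.CI95'] = None",
    "df = pd.read_csv(sys.argv[1])",
    "rows = []",
    "for s, g in df.groupby('set'):",
    "    r = pg.intraclass_corr(g, targets='subject', raters='session',",
    "                           ratings='value')",
    "    r = r[r['Type'].isin(['ICC2', 'ICC(A,1)'])]",
    "    ci = r['CI95'].iloc[0]",
    "    rows.append((s, float(r['ICC'].iloc[0]), float(ci[0]),",
    "                 float(ci[1])))",
    "out = pd.DataFrame(rows, columns=['set','icc','ci_low','ci_high'])",
    "out.to_csv(sys.argv[2], index=False)")
  tmp_py <- tempfile(fileext = ".py")
  writeLines(script, tmp_py)
  status <- system2("python", c(tmp_py, tmp_in, tmp_out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("pingouin reference run failed")
  utils::read.csv(tmp_out)
}

# Straight-line reimplementation of the whole per-trial extraction chain,
# written independently of the package functions (explicit loops, no shared
# helpers beyond the filter design).
extract_oracle <- function(trial, baseline_window_s = 0.5, k_sd = 3,
                           min_hold_s = 0.025, rms_window_s = 0.05) {
  rate <- trial$force$rate_hz
  pad <- round(0.5 * rate)
  ff <- function(filt, x) {
    n <- length(x)
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    y <- rev(signal::filter(filt, rev(signal::filter(filt, xp))))
    y[(pad + 1):(pad + n)]
  }
  bf <- signal::butter(4, 15 / (rate / 2), type = "low")
  f <- ff(bf, trial$force$samples)
  nb <- round(baseline_window_s * rate)
  bm <- mean(f[1:nb]); bs <- sd(f[1:nb])
  thr <- bm + k_sd * bs
  hold <- max(1L, round(min_hold_s * rate))
  onset_i <- NA
  for (i in (nb + 1L):length(f)) {
    if (f[i] > thr && all(f[i:min(i + hold - 1L, length(f))] > thr)) {
      onset_i <- i; break
    }
  }
  onset_s <- (onset_i - 1L) / rate
  peak_i <- which.max(f)
  mvc <- f[peak_i] - bm
  i200 <- round((onset_s + 0.2) * rate) + 1L
  rfd <- (f[i200] - bm) / 0.2
  t90 <- NA
  for (i in onset_i:length(f)) {
    if (f[i] - bm >= 0.9 * mvc) { t90 <- (i - onset_i) / rate; break }
  }
  peak_emg <- NA_real_
  if (!is.null(trial$emg)) {
    bp <- signal::butter(4, c(10, 500) / (rate / 2), type = "pass")
    e <- ff(bp, trial$emg$samples)
    wn <- round(rms_window_s * rate); h <- wn %/% 2L
    n <- length(e)
    env <- vapply(seq_len(n), function(i) {
      w <- e[max(1, i - h):min(n, i + h)]
      sqrt(mean(w^2))
    }, numeric(1))
    lo <- max(1L, round(((peak_i - 1L) / rate - 1) * rate) + 1L)
    hi <- min(n, round(((peak_i - 1L) / rate + 1) * rate) + 1L)
    peak_emg <- max(env[lo:hi])
  }
  list(onset_s = onset_s, mvc_n = mvc, rfd200_n_per_s = rfd, t90_s = t90,
       peak_emg_rms_v = peak_emg)
}
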