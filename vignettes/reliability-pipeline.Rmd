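---
title: "Measuring between-session reliability of isometric dynamometry outcomes"
author: "dynoreli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring between-session reliability of isometric dynamometry outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Rehabilitation trials that target the ankle dorsiflexors lean on a small set
of dynamometry outcomes: the maximal voluntary contraction force (MVC), the
rate of force development over the first 200 ms of the effort (RFD200ms),
the time taken to reach 90% of peak force, and the peak amplitude of the
tibialis anterior surface EMG. Before any of these can be used to judge an
intervention, one has to know how repeatable they are when nothing has
changed — the between-session (test–retest) reliability. dynoreli implements
the full chain from raw force/EMG trial traces to the reliability table, and
pairs it with a synthetic-data generator whose true reliability is known, so
every stage of the chain can be validated without access to participant
data.

## Trace conditioning and outcome extraction

Each trial is a force trace and (optionally) a time-aligned EMG trace,
nominally sampled at 1961 Hz. The conditioning chain is:

1. **Force low-pass.** 4th-order Butterworth, 15 Hz cutoff, applied
   forward–backward so the net filter has zero phase and force landmarks do
   not shift in time. `signal::butter` supplies the design; the
   forward–backward application pads the trace by odd reflection about its
   end points before each pass, because starting the passes from zero state
   would otherwise leave large transients at the ends (with the default
   0.5 s padding the DC error is below 2e-6).
2. **Onset detection.** The baseline mean *m* and SD *s* are estimated over
   the first 0.5 s of the filtered trace; onset is the first sample after
   the baseline window exceeding *m* + 3*s* that stays above that threshold
   for at least 25 ms. The hold is a debounce: the original laboratory
   procedure confirmed every automatic onset visually, and an automated
   pipeline needs a mechanical substitute. Window, threshold multiplier and
   hold are all configurable (`onset_spec()`).
3. **MVC.** Trace maximum minus baseline mean. By default the filtered
   trace is used for the peak as well, keeping a single conditioning path;
   a 15 Hz low-pass changes the peak of a 4–5 s plateau negligibly. The
   `mvc_raw` switch restores peak-picking on the raw trace.
4. **RFD200ms.** Baseline-corrected force at onset + 200 ms divided by
   0.2 s, read at the nearest sample (at 1961 Hz the timing quantisation is
   0.51 ms). Correcting the 200 ms reading for the resting offset keeps the
   quantity a true rate; the `rfd_baseline_correct` switch disables it.
5. **Time to 90% peak.** First time after onset at which the corrected
   force reaches 0.9 × MVC.
6. **EMG.** Zero-phase 4th-order Butterworth band-pass 10–500 Hz (the upper
   edge is 0.51 of Nyquist at 1961 Hz), then a centred 50 ms moving-RMS
   envelope, then the envelope maximum within ±1 s of the force peak. The
   50 ms RMS window is a conventional choice for surface EMG; it is
   configurable because nothing in the chain depends on it structurally.

### Numerical choices

Times are seconds from trace start with sample 1 at *t* = 0. No
interpolation is used anywhere: at ~2 kHz, sub-sample timing is far below
the biological trial-to-trial variability these outcomes carry. Envelope
edges truncate the RMS window to the available samples. Ties in best-of
aggregation take the first occurrence.

## The synthetic study generator

The generator exists so the pipeline can be tested against known truth. A
trial trace is a quiet Gaussian baseline (SD 0.5 N) followed, from the
onset instant (default 1.5 s), by a half-logistic rise to the target peak:

$$F(t) = P\left(\frac{2}{1 + e^{-(t - t_0)/\tau}} - 1\right), \quad t \ge t_0,$$

held through a 4.5 s contraction. The half-logistic — the upper half of a
logistic centred at onset — was chosen over a full sigmoid because it is
zero at onset with an immediately steep slope $P/2\tau$, which is the shape
of an effort performed "as fast and hard as possible", and because it makes
the generator's onset parameter recoverable by the 3-SD rule: a full
logistic centred at onset would put half the peak force at the onset
instant and a slow sub-threshold tail before it. Its landmarks have closed
forms used as test oracles; time to the fraction *q* of peak is
$\tau\,\mathrm{logit}((1+q)/2)$, so the default $\tau = 0.4$ s gives a time
to 90% of ~1.18 s, inside the 1.0–1.6 s range typical of hemiparetic
dorsiflexors. EMG is zero-mean broadband Gaussian noise band-limited to
10–500 Hz and amplitude-modulated so its instantaneous SD is
`emg_noise_sd + emg_gain * force(t)`; the default gain of 1.3 mV/N yields
the ~0.2 V peak RMS typical of tibialis anterior recordings at ~150 N.

Study structure follows the two-way random-effects model that ICC(2,1)
assumes: the target peak of subject *i*, session *j*, trial *t* is
$\mu + b_i + s_{ij} + w_{ijt}$ with independent Gaussian components of SD
$\sigma_b$ (between subjects), $\sigma_s$ (subject-by-session interaction,
drawn per subject and session rather than once per session — either way
absolute agreement penalises it, and the interaction form keeps subjects
exchangeable) and $\sigma_w$ (trial-to-trial). Targets are floored at 1 N
so outcomes stay positive and log-transformable; if more than 1% of draws
fall at or below zero the generator warns that a Gaussian model for a
strictly positive force is misspecified at those settings. Rise-time
constants vary per subject (lognormal, CV 0.4) and per trial (CV 0.2) so
the rapid-force outcomes carry their own between-subject variance; the CVs
were set once to produce the wide spread of time-to-90% values seen in
hemiparetic cohorts.

The demonstration conditions (`demo_config()`) are 13 subjects, 2 sessions,
3 trials, $\mu = 142$ N, $\sigma_b = 64.7$ N, $\sigma_s = 5$ N,
$\sigma_w = 17.3$ N. The between-subject SD and the aggregated error SD
(~10 N for the mean of three trials) are derived from the published session
summaries of this population, giving a true mean-of-three ICC of ~0.97.

For large simulation studies (thousands of subjects), synthesising traces
is pointless; `simulate_outcome_matrix()` draws the aggregated
subject-session outcomes directly from the same variance-component model.

### What the generator does and does not emulate

It reproduces the sampling rate, trace shape, variance structure, missing
EMG channels and session labelling of a two-session MVC study. It does not
model antagonist co-contraction, fatigue across trials, amplifier
saturation, force-transducer drift, or non-Gaussian subject distributions.
Passing tests therefore demonstrate that the *pipeline* is correct under
the stated model, not that any particular clinical dataset satisfies that
model.

## The reliability layer

Per outcome and aggregation (`mean3`, `best3` — maximum for force, RFD and
EMG, minimum for time-based outcomes), the n × 2 subject-by-session matrix
is built, dropping subjects with a missing session listwise (and logging
them). Each session column is screened with Shapiro–Wilk
(`stats::shapiro.test`); if either p-value falls below 0.05 all cells are
natural-log transformed and the row is flagged. ICC and CI are then
computed on the analysis scale while session means and SDs are reported on
the raw scale for readability.

The two-way, one-observation-per-cell ANOVA gives mean squares MSR
(subjects), MSC (sessions) and MSE, and the single-measure
absolute-agreement ICC is

$$\mathrm{ICC}(2,1) = \frac{MSR - MSE}{MSR + (k-1)MSE + \tfrac{k}{n}(MSC - MSE)},$$

with the 95% CI from the McGraw–Wong F-based procedure (Satterthwaite
degrees of freedom). SEM defaults to $\sqrt{MSE}$ — the within-subject
error SD of the same ANOVA, which is the internally consistent companion to
an absolute-agreement ICC; the classical alternative
$SD\sqrt{1-\mathrm{ICC}}$ is available (`sem_formula = "sd1micc"`).
SEM% is 100 × SEM / grand mean, on the analysis scale. Classification uses
the conventional bands — excellent (≥ 0.90), good (0.75–0.89), moderate
(0.50–0.74), poor (< 0.50) — applied to both the point estimate and the
lower CI bound.

```{r, eval = FALSE}
library(dynoreli)
res <- run_pipeline(demo_config())
res$report_rows
```

## Design decisions that were genuinely open

- **Degenerate ICC inputs.** When all values are identical there is no
  variance to apportion and `icc21()` errors. When the formula's
  denominator is exactly zero with variance present (e.g. a 2 × 2
  pure-disagreement matrix) the estimate diverges under perturbation; the
  implementation reports −1, the floor of the admissible range for two
  sessions, with an uninformative CI.
- **Perfect agreement** (MSE = MSC = 0) collapses the CI to the point
  estimate, so a perfect-agreement row renders as "1.00 [1.00, 1.00]".
- **Best-of-three truth.** The maximum of correlated Gaussian trials has no
  clean closed-form ICC, so `true_icc()` returns the mean-of-three value
  flagged as an approximation; simulation is the reference for best-of
  aggregation.
- **Log-scale SEM%.** For log-transformed outcomes SEM and SEM% stay on the
  analysis scale with the flag set. When the log-scale grand mean is near
  zero, SEM% is arbitrarily large and signed — it should not be interpreted
  as a percentage of anything physical; published tables showing triple-digit
  SEM% for log-transformed time outcomes are this artefact.

## Known limitations

- The 3-SD onset rule misfires early on roughly 4–5% of default-parameter
  synthetic trials: a 15 Hz low-pass leaves baseline noise correlated over
  ~66 ms, so the SD estimated from a 0.5 s window is occasionally far too
  small and the 25 ms debounce cannot compensate. This is the same failure
  mode that makes visual onset confirmation standard practice; raising
  `min_hold_s` or `k_sd` trades misses for false alarms.
- The ANOVA ICC point estimator is attenuated at small n: at n = 13 the
  mean estimate is low by ≈ 0.032 at a true ICC of 0.5, ≈ 0.025 at 0.8 and
  ≈ 0.009 at 0.95 (measured by simulation). CI coverage stays at ~96%. Any
  reliability study this size should read the CI, not the point estimate.
- Simulation problem sizes used by the test-suite and reproduction scripts
  (2000-subject outcome-level studies, 500–1000 replicate recovery and
  coverage runs, 13-subject trace-level studies) were chosen to estimate
  each quantity to well within its decision tolerance.
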