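Package: dynoreli
Title: Between-Session Reliability of Isometric Dynamometry Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for quantifying the test-retest (between-session)
    reliability of isometric ankle-dorsiflexor outcomes measured by rigid
    dynamometry with surface electromyography (EMG). Conditions per-trial
    force and EMG traces (zero-phase Butterworth filtering, 3-SD baseline
    onset detection), extracts maximal voluntary contraction (MVC) force,
    rate of force development over the first 200 ms (RFD200ms), time to 90%
    of peak force, and peak EMG root-mean-square amplitude, aggregates
    trials (mean or best of three), and computes an absolute-agreement
    reliability layer: ICC(2,1) with 95% confidence intervals from a
    two-way random-effects ANOVA, standard error of measurement (SEM and
    SEM%), and qualitative classification. Includes a synthetic-data
    generator with a variance-component model and known true reliability,
    so every stage can be validated without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
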