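#!/usr/bin/env Rscript
# Between-session reliability of the extracted outcomes: aggregate trials
# (mean of three, best of three), screen normality per session
# (Shapiro-Wilk, natural-log transform on failure), then ICC(2,1) absolute
# agreement with McGraw-Wong 95% CI, SEM = sqrt(MS_error), SEM% and the
# excellent/good/moderate/poor classification. Produces the
# published-table-style report under results/.

library(dynoreli)

if (!file.exists("results/outcomes.csv")) {
  stop("run analysis/02_extract_outcomes.R first")
}
outcomes <- read.csv("results/outcomes.csv")

tab <- reliability_table(outcomes)
rows <- write_report(tab, "results/report.csv", "results/report.json")

cat("reliability of all outcomes between session 1 and session 2:\n\n")
print(rows[, c("outcome", "aggregation", "test1", "test2", "icc_ci",
               "sem", "sem_pct", "classification")], row.names = FALSE)
cat("\nreport written to results/report.csv and results/report.json\n")

dropped <- attr(tab, "dropped")
n_drop <- sum(lengths(dropped))
cat(sprintf("subjects dropped from any outcome: %d\n", n_drop))
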