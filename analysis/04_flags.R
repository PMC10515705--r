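#!/usr/bin/env Rscript
# Apply the published protective thresholds (mTAD <= 25 mm, TAD < 25 mm,
# ABA > -10 deg, Cleveland safe zones {5, 6, 8, 9}) per case and summarise
# how often each rule passes, and how the combined rule relates to cut-out.

library(mtad)

metrics <- read.csv("results/eval_metrics.csv", stringsAsFactors = FALSE)
outcomes <- read.csv("results/eval_outcomes.csv", stringsAsFactors = FALSE)
fl <- run_flags(metrics)
write.csv(fl, "results/flags.csv", row.names = FALSE)

n <- nrow(fl)
cat("rule pass rates over", n, "cases:\n")
print(round(100 * attr(fl, "summary") / n, 1))

d <- merge(fl, outcomes, by = "case_id")
tab <- table(all_pass = d$all_pass, cutout = d$cutout)
cat("\ncut-out rate by combined-rule status:\n")
print(round(100 * prop.table(tab, 1), 1))
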