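#!/usr/bin/env Rscript
# Simulate the study conditions: a study-sized cohort (n = 109) and a large
# evaluation cohort (n = 5000), both from the default logistic risk model on
# the latent modified TAD.  Writes image-unit landmark and outcome tables in
# the exchange schema used by the measurement step.

library(mtad)

dir.create("results", showWarnings = FALSE)
seed <- 20230920

for (spec in list(list(tag = "study", n = 109), list(tag = "eval", n = 5000))) {
  co <- generate_cohort(cohort_config(n_cases = spec$n, seed = seed),
                        compute_metrics = FALSE)
  write.csv(co$landmarks, sprintf("results/%s_landmarks.csv", spec$tag),
            row.names = FALSE)
  write.csv(co$outcomes, sprintf("results/%s_outcomes.csv", spec$tag),
            row.names = FALSE)
  write.csv(co$truth, sprintf("results/%s_truth.csv", spec$tag),
            row.names = FALSE)
  cat(sprintf("%s cohort: n = %d, cut-out rate %.1f%%\n",
              spec$tag, spec$n, 100 * mean(co$outcomes$cutout)))
}
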