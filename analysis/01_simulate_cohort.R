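#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort — 150 subjects across diagnosis
# groups, two trial sets each (three sway stances + two drift hands at
# 50 Hz), with clinical scales driven by a latent disability scalar.

source("analysis/00_config.R")

cohort <- generate_cohort(cfg$n_subjects, cfg$diagnosis_mix, cfg$n_trials,
                          cfg$seed, params = cfg$generator)
subjects <- add_subpanel_scores(cohort$subjects)

write.csv(subjects, file.path(results_dir, "cohort.csv"), row.names = FALSE)
# a small worked example of the raw record format (first subject only)
first_id <- subjects$subject_id[1]
write_trials_csv(Filter(function(tr) tr$subject_id == first_id, cohort$trials),
                 file.path(results_dir, "example_trials.csv"))

cat("Simulated", nrow(subjects), "subjects,", length(cohort$trials),
    "raw trials (", cohort$n_trials, "trial sets each )\n")
cat("\nDiagnosis mix:\n")
print(table(subjects$diagnosis))
cat("\nLatent disability by diagnosis (mean):\n")
print(round(tapply(subjects$latent_disability, subjects$diagnosis, mean), 2))
cat("\nClinical-scale correlations with latent disability:\n")
for (sc in c("edss", "combiwise", "neurex_total"))
  cat(sprintf("  %-12s r = %.2f\n", sc,
              cor(subjects[[sc]], subjects$latent_disability)))
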