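#!/usr/bin/env Rscript
# Stage 4: association analyses. Pearson/BH correlation screens of the
# reliable biomarkers against clinical and imaging outcomes (training
# cohort), the healthy-volunteer age prediction interval for the
# eyes-closed net sway amplitude, and pairwise Wilcoxon tests on the
# age-adjusted residuals. Run after 01-03.

source("analysis/00_config.R")

subjects <- read.csv(file.path(results_dir, "cohort.csv"))
features <- read.csv(file.path(results_dir, "features.csv"),
                     check.names = FALSE)
reliability <- read.csv(file.path(results_dir, "reliability.csv"))

split <- split_cohort(subjects, cfg$train_fraction, cfg$seed)
feat_train <- features[features$subject_id %in% split$train, ]
retained <- reliability$feature[reliability$retained]
fences <- lapply(setNames(retained, retained), function(f)
  outlier_fences(feat_train[[f]], cfg$iqr_mult))
subj_feats <- swaymetrics:::aggregate_subject_features(features, fences)
meta <- subjects[match(subj_feats$subject_id, subjects$subject_id), ]
is_train <- subj_feats$subject_id %in% split$train

nm <- biomarker_names()
for (block in c("sway", "drift")) {
  keep <- intersect(nm[[block]], retained)
  outs <- cfg[[paste0(block, "_outcomes")]]
  scr <- correlation_screen(subj_feats[is_train, keep, drop = FALSE],
                            meta[is_train, outs, drop = FALSE], cfg$alpha)
  write.csv(scr, file.path(results_dir, paste0("screen_", block, ".csv")),
            row.names = FALSE)
  cat(sprintf("%s screen: %d reliable biomarkers x %d outcomes, %d BH-significant\n",
              block, length(keep), length(outs), sum(scr$significant)))
  best <- scr[which.max(abs(scr$pearson_r)), ]
  cat(sprintf("  strongest: %s ~ %s, r = %.2f (adj. p = %.2g)\n",
              best$feature, best$outcome, best$pearson_r, best$p_adjusted))
}

# age prediction interval on the eyes-closed net sway amplitude
df <- data.frame(age = meta$age, value = subj_feats[[cfg$age_feature]],
                 diagnosis = meta$diagnosis)
hv <- df[df$diagnosis == "HV", ]
if (sum(!is.na(hv$value)) >= 10) {
  pi_res <- hv_age_prediction_interval(hv, df, cfg$pi_level)
  cat(sprintf("\n%s ~ age in HV: slope %.4f /yr, R^2 = %.2f\n",
              cfg$age_feature, pi_res$slope, pi_res$r_squared))
  cat("Fraction above the HV 95% prediction band, by diagnosis:\n")
  print(round(pi_res$abnormal_fraction_by_diagnosis, 2))
  flags <- data.frame(subject_id = subj_feats$subject_id,
                      diagnosis = df$diagnosis, abnormal = pi_res$flags)
  write.csv(flags, file.path(results_dir, "abnormality_flags.csv"),
            row.names = FALSE)
  resid <- df$value - predict(pi_res$fit, newdata = data.frame(age = df$age))
  grps <- split(resid, df$diagnosis)
  grps <- grps[vapply(grps, function(g) sum(!is.na(g)) >= 3, TRUE)]
  gt <- pairwise_group_tests(grps)
  write.csv(gt, file.path(results_dir, "group_tests.csv"), row.names = FALSE)
  cat("\nPairwise Wilcoxon on age residuals (BH-significant pairs):\n")
  print(gt[gt$stars != "", c("group1", "group2", "p_adjusted", "stars")],
        row.names = FALSE)
}
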