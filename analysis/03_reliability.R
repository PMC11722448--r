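#!/usr/bin/env Rscript
# Stage 3: test-retest reliability. ICC(2,1) over the first two trials of
# each TRAINING subject, retention at ICC > 0.5, and Tukey fences for
# outlier masking. Run after 01/02.

source("analysis/00_config.R")

subjects <- read.csv(file.path(results_dir, "cohort.csv"))
features <- read.csv(file.path(results_dir, "features.csv"),
                     check.names = FALSE)

split <- split_cohort(subjects, cfg$train_fraction, cfg$seed)
feat_train <- features[features$subject_id %in% split$train, ]
reliability <- filter_reliable(feat_train, cfg$icc_threshold)
write.csv(reliability, file.path(results_dir, "reliability.csv"),
          row.names = FALSE)

nm <- biomarker_names()
cat("Training cohort:", length(split$train), "subjects; validation:",
    length(split$validation), "\n")
cat(sprintf("Retained at ICC > %.1f: %d of 60 sway, %d of 16 drift\n",
            cfg$icc_threshold,
            sum(reliability$retained & reliability$feature %in% nm$sway),
            sum(reliability$retained & reliability$feature %in% nm$drift)))
cat("\nMost reliable biomarkers:\n")
top <- reliability[order(-reliability$icc), ][1:8, c("feature", "icc")]
top$icc <- round(top$icc, 3)
print(top, row.names = FALSE)
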