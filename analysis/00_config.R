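# Shared configuration for the analysis scripts. Sourced by 01-05; every
# stage derives all randomness from this one seed.

library(swaymetrics)

cfg <- default_pipeline_config(seed = 2026)
cfg$n_subjects <- 150

results_dir <- "results"
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
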