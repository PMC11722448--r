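# End-to-end orchestration: generate (or accept) a cohort -> calibrate ->
# extract biomarkers -> split -> reliability -> outlier masking ->
# correlation screens -> age analysis -> prediction models -> artifacts.
#
# Every training-side computation (reliability, fences, screens, gates,
# model fits) sees training subjects only; validation subjects are touched
# exclusively at evaluation time. The split is an explicit input drawn
# once from the seed, so re-running on a cohort with the validation
# subjects deleted reproduces the training-side artifacts identically.

#' Default pipeline configuration
#'
#' All thresholds of the analysis in one list: cohort size and mix,
#' spectral bands, ICC retention threshold (0.5), Tukey-fence multiplier
#' (1.5), BH alpha (0.05), training fraction (0.8), relevant-outcome sets
#' per test, and the model grid. The list round-trips through JSON.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @return Named config list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    n_subjects = 100,
    diagnosis_mix = c(HV = 0.25, NIND = 0.15, OIND = 0.05, RRMS = 0.3,
                      SPMS = 0.1, PPMS = 0.1, CIS = 0.04, RIS = 0.01),
    n_trials = 2,
    sway_band = c(0.15, 10),
    drift_band = c(0.15, 15),
    icc_threshold = 0.5,
    iqr_mult = 1.5,
    alpha = 0.05,
    train_fraction = 0.8,
    global_outcomes = c("edss", "combiwise", "neurex_total"),
    sway_outcomes = c("neurex_postural_sway", "edss", "combiwise",
                      "neurex_total", "mri_infratentorial"),
    drift_outcomes = c("neurex_pronator_drift", "edss", "combiwise",
                       "neurex_total", "mri_infratentorial"),
    age_feature = "RMS_Net_EC-FT",
    pi_level = 0.95,
    nfolds = 5,
    enet_alphas = c(0.1, 0.5, 0.9),
    lambda_rule = "lambda.1se",
    generator = default_cohort_params()
  )
}

# Subject-level feature matrix: mask outliers using the supplied per-
# feature fences, then average each feature over a subject's trials.
aggregate_subject_features <- function(features, fences) {
  fcols <- setdiff(names(features), c("subject_id", "trial_index"))
  masked <- features
  for (f in names(fences)) {
    out <- flag_outliers(masked[[f]], fences = fences[[f]])
    masked[[f]][out] <- NA
  }
  agg <- stats::aggregate(masked[fcols], by = list(subject_id = masked$subject_id),
                          FUN = function(v) mean(v, na.rm = TRUE))
  agg[fcols] <- lapply(agg[fcols], function(v) ifelse(is.nan(v), NA, v))
  agg
}

gate_block <- function(block_features, reliability, subj_feats, outcomes_df,
                       relevant, alpha) {
  retained <- intersect(block_features,
                        reliability$feature[reliability$retained])
  if (length(retained) == 0)
    return(list(screen = NULL, gated = character(0)))
  screen <- correlation_screen(subj_feats[, retained, drop = FALSE],
                               outcomes_df, alpha = alpha)
  gated <- select_model_features(reliability, screen, relevant, alpha)
  list(screen = screen, gated = intersect(gated, retained))
}

run_models <- function(feats, outcome_name, train_mat, val_mat,
                       y_train, y_val, config) {
  if (length(feats) < 2 || stats::sd(y_train) == 0) return(NULL)
  m <- fit_and_select(train_mat[, feats, drop = FALSE], y_train,
                      seed = config$seed, nfolds = config$nfolds,
                      enet_alphas = config$enet_alphas,
                      lambda_rule = config$lambda_rule)
  if (length(y_val) >= 3 && stats::sd(y_val) > 0)
    m <- evaluate_model(m, train_mat[, feats, drop = FALSE], y_train,
                        val_mat[, feats, drop = FALSE], y_val)
  m$outcome <- outcome_name
  m
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: generate (or accept) cohort ->
#' calibrate + extract biomarkers -> 80/20 subject split -> test-retest
#' reliability on training -> Tukey-fence masking (training fences) ->
#' subject-level aggregation -> per-test correlation screens (training) ->
#' healthy-volunteer age prediction-interval analysis -> per-outcome model
#' tournaments evaluated on validation. Deterministic for a fixed config.
#'
#' @param config List from [default_pipeline_config()].
#' @param cohort Optional pre-generated cohort (from [generate_cohort()]);
#'   generated from the config otherwise.
#' @param split Optional list(train, validation) of subject ids; drawn via
#'   [split_cohort()] otherwise.
#' @param output_dir Optional directory; artifacts are written there as
#'   CSV/JSON with a manifest.
#' @return List of artifacts: `subjects`, `features`, `split`,
#'   `reliability`, `fences`, `screens`, `gated`, `subject_features`,
#'   `age_analysis`, `models`, `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         cohort = NULL, split = NULL, output_dir = NULL) {
  if (is.null(cohort))
    cohort <- generate_cohort(config$n_subjects, config$diagnosis_mix,
                              config$n_trials, config$seed,
                              params = config$generator)
  subjects <- add_subpanel_scores(cohort$subjects)

  features <- extract_cohort_features(cohort, sway_band = config$sway_band,
                                      drift_band = config$drift_band)
  if (is.null(split))
    split <- split_cohort(subjects, config$train_fraction, config$seed)

  names_all <- biomarker_names()
  feat_train <- features[features$subject_id %in% split$train, ]

  # reliability + fences on TRAINING trials only
  reliability <- filter_reliable(feat_train, config$icc_threshold)
  retained <- reliability$feature[reliability$retained]
  fences <- lapply(stats::setNames(retained, retained), function(f)
    outlier_fences(feat_train[[f]], config$iqr_mult))

  subj_feats_all <- aggregate_subject_features(features, fences)
  subj_train <- subj_feats_all[subj_feats_all$subject_id %in% split$train, ]
  subj_val <- subj_feats_all[subj_feats_all$subject_id %in% split$validation, ]
  meta_train <- subjects[match(subj_train$subject_id, subjects$subject_id), ]
  meta_val <- subjects[match(subj_val$subject_id, subjects$subject_id), ]

  sway_gate <- gate_block(names_all$sway, reliability, subj_train,
                          meta_train[, config$sway_outcomes, drop = FALSE],
                          config$sway_outcomes, config$alpha)
  drift_gate <- gate_block(names_all$drift, reliability, subj_train,
                           meta_train[, config$drift_outcomes, drop = FALSE],
                           config$drift_outcomes, config$alpha)

  # age analysis on the full cohort (descriptive, not model-fitting)
  age_analysis <- NULL
  if (config$age_feature %in% names(subj_feats_all)) {
    meta_all <- subjects[match(subj_feats_all$subject_id,
                               subjects$subject_id), ]
    df <- data.frame(age = meta_all$age,
                     value = subj_feats_all[[config$age_feature]],
                     diagnosis = meta_all$diagnosis)
    hv <- df[df$diagnosis == "HV", ]
    if (sum(!is.na(hv$value)) >= 10) {
      age_analysis <- hv_age_prediction_interval(hv, df, config$pi_level)
      resid_df <- df
      resid_df$residual <- df$value -
        stats::predict(age_analysis$fit, newdata = data.frame(age = df$age))
      grps <- split(resid_df$residual, resid_df$diagnosis)
      grps <- grps[vapply(grps, function(g) sum(!is.na(g)) >= 3, TRUE)]
      if (length(grps) >= 2)
        age_analysis$group_tests <- pairwise_group_tests(grps)
    }
  }

  tr_mat <- as.matrix(subj_train[, setdiff(names(subj_train), "subject_id")])
  rownames(tr_mat) <- subj_train$subject_id
  va_mat <- as.matrix(subj_val[, setdiff(names(subj_val), "subject_id")])
  rownames(va_mat) <- subj_val$subject_id
  # models require complete predictor rows; impute residual NAs with
  # training medians (outlier masking leaves holes)
  for (j in colnames(tr_mat)) {
    med <- stats::median(tr_mat[, j], na.rm = TRUE)
    tr_mat[is.na(tr_mat[, j]), j] <- med
    if (ncol(va_mat) > 0) va_mat[is.na(va_mat[, j]), j] <- med
  }

  models <- list()
  sway_target <- "neurex_postural_sway"
  models$sway <- run_models(sway_gate$gated, sway_target, tr_mat, va_mat,
                            meta_train[[sway_target]], meta_val[[sway_target]],
                            config)
  drift_target <- "neurex_pronator_drift"
  models$drift <- run_models(drift_gate$gated, drift_target, tr_mat, va_mat,
                             meta_train[[drift_target]],
                             meta_val[[drift_target]], config)
  models$combined <- lapply(
    stats::setNames(config$global_outcomes, config$global_outcomes),
    function(oc) {
      if (length(union(sway_gate$gated, drift_gate$gated)) < 2) return(NULL)
      combined_test_models(sway_gate$gated, drift_gate$gated,
                           tr_mat, meta_train[[oc]], va_mat, meta_val[[oc]],
                           seed = config$seed, nfolds = config$nfolds,
                           enet_alphas = config$enet_alphas,
                           lambda_rule = config$lambda_rule)
    })

  artifacts <- list(
    subjects = subjects, features = features, split = split,
    reliability = reliability, fences = fences,
    screens = list(sway = sway_gate$screen, drift = drift_gate$screen),
    gated = list(sway = sway_gate$gated, drift = drift_gate$gated),
    subject_features = subj_feats_all,
    age_analysis = age_analysis, models = models,
    manifest = list(seed = config$seed,
                    n_subjects = nrow(subjects),
                    n_trials = cohort$n_trials,
                    package_version = as.character(utils::packageVersion("swaymetrics")),
                    config = config[setdiff(names(config), "generator")])
  )
  if (!is.null(output_dir)) write_artifacts(artifacts, output_dir)
  artifacts
}

# Serialize the tabular artifacts plus a manifest with file hashes.
write_artifacts <- function(artifacts, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    p <- file.path(output_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(
    w(artifacts$subjects, "cohort.csv"),
    w(artifacts$features, "features.csv"),
    w(artifacts$reliability, "reliability.csv"))
  if (!is.null(artifacts$screens$sway))
    paths <- c(paths, w(artifacts$screens$sway, "screen_sway.csv"))
  if (!is.null(artifacts$screens$drift))
    paths <- c(paths, w(artifacts$screens$drift, "screen_drift.csv"))

  model_summary <- function(m) {
    if (is.null(m)) return(NULL)
    list(outcome = m$outcome, strategy = m$strategy,
         hyperparameters = m$hyperparameters[c("alpha", "lambda")],
         cv_r2 = m$cv_r2,
         coefficients = as.list(m$coefficients[m$coefficients != 0]),
         metrics = if (!is.null(m$metrics)) as.list(m$metrics) else NULL,
         best_single = if (!is.null(m$best_single))
           list(feature = m$best_single$feature,
                metrics = as.list(m$best_single$metrics)) else NULL)
  }
  report <- list(
    sway = model_summary(artifacts$models$sway),
    drift = model_summary(artifacts$models$drift),
    combined = lapply(artifacts$models$combined, function(cm)
      if (is.null(cm)) NULL else list(
        combined = model_summary(cm$combined),
        sway_only = model_summary(cm$sway_only),
        drift_only = model_summary(cm$drift_only),
        comparison = cm$comparison)))
  jsonlite::write_json(report, file.path(output_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  manifest <- artifacts$manifest
  manifest$files <- as.list(tools::md5sum(paths))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' Hashes of the training-side artifacts of a pipeline run
#'
#' Digest of everything computed from training subjects only (reliability
#' table, outlier fences, screens, gates, model coefficients and
#' hyperparameters). Two runs that agree here were trained identically,
#' whatever happened on the validation side.
#'
#' @param artifacts Output of [run_pipeline()].
#' @return Named character vector of md5 hashes.
#' @export
training_side_hashes <- function(artifacts) {
  dig <- function(x) {
    f <- tempfile()
    on.exit(unlink(f), add = TRUE)
    saveRDS(x, f, version = 2, compress = FALSE)
    unname(tools::md5sum(f))
  }
  strip_model <- function(m) {
    if (is.null(m)) return(NULL)
    m[c("strategy", "hyperparameters", "cv_r2", "coefficients",
        "intercept", "selected_features")]
  }
  c(reliability = dig(artifacts$reliability),
    fences = dig(artifacts$fences),
    screens = dig(artifacts$screens),
    gated = dig(artifacts$gated),
    sway_model = dig(strip_model(artifacts$models$sway)),
    drift_model = dig(strip_model(artifacts$models$drift)),
    combined_models = dig(lapply(artifacts$models$combined, function(cm)
      if (is.null(cm)) NULL else lapply(cm[c("combined", "sway_only",
                                             "drift_only")], strip_model))))
}
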