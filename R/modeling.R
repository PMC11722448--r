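# Disability-prediction modeling: subject-level 80/20 split, reliability +
# correlation feature gating, a six-candidate tournament (ridge / lasso /
# elastic net, each on raw features and on PCA scores) selected by
# cross-validated R^2, and validation by Pearson r, R^2 and Lin's
# concordance correlation coefficient against the best single predictor.

#' Stratified subject-level train/validation split
#'
#' Disjoint, exhaustive split of subjects, stratified by diagnosis where
#' group sizes permit; deterministic under the seed.
#'
#' @param subjects Cohort data.frame with `subject_id` and `diagnosis`.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `validation`.
#' @export
split_cohort <- function(subjects, train_fraction = 0.8, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly inside (0, 1)")
  if (nrow(subjects) < 5) stop("need >= 5 subjects to split")
  set.seed(as.integer(seed %% 2147483647))
  train <- character(0)
  for (g in split(subjects$subject_id, subjects$diagnosis)) {
    n_tr <- round(length(g) * train_fraction)
    n_tr <- min(max(n_tr, 0L), length(g))
    train <- c(train, sample(g, n_tr))
  }
  list(train = sort(train),
       validation = sort(setdiff(subjects$subject_id, train)))
}

#' Gate features on reliability and outcome correlation
#'
#' A biomarker enters the models only if (i) its test-retest ICC exceeds
#' the reliability threshold and (ii) it has at least one BH-significant
#' correlation with a relevant clinical/imaging outcome. Both tables must
#' be computed on training data only.
#'
#' @param reliability A `reliability_report` from [filter_reliable()].
#' @param correlations A screen from [correlation_screen()].
#' @param relevant_outcomes Outcome names eligible to open the gate.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Character vector of gated feature names.
#' @export
select_model_features <- function(reliability, correlations,
                                  relevant_outcomes, alpha = 0.05) {
  if (length(relevant_outcomes) == 0) stop("relevant_outcomes is empty")
  reliable <- reliability$feature[reliability$retained]
  sig <- correlations[!is.na(correlations$p_adjusted) &
                        correlations$p_adjusted < alpha &
                        correlations$outcome %in% relevant_outcomes, ]
  intersect(reliable, unique(sig$feature))
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (n-denominator) moments. Penalizes both decorrelation and
#' location/scale miscalibration, so |CCC| <= |Pearson r|.
#'
#' @param y_true,y_pred Equal-length numeric vectors (n >= 2).
#' @return CCC in `[-1, 1]`.
#' @export
ccc <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("ccc: length mismatch")
  n <- length(y_true)
  if (n < 2) stop("ccc: need >= 2 observations")
  mx <- mean(y_true); my <- mean(y_pred)
  vx <- mean((y_true - mx)^2); vy <- mean((y_pred - my)^2)
  if (vx == 0 && vy == 0 && mx == my)
    stop("ccc: zero variance in both inputs")
  sxy <- mean((y_true - mx) * (y_pred - my))
  2 * sxy / (vx + vy + (mx - my)^2)
}

# Candidate strategies of the tournament.
MODEL_STRATEGIES <- expand.grid(
  penalty = c("ridge", "lasso", "elastic_net"),
  space = c("raw", "pca"), stringsAsFactors = FALSE)

# One cv.glmnet candidate; returns the cross-validated R^2 at the chosen
# lambda and a predictor closure refit on the full training data.
fit_candidate <- function(X, y, penalty, space, foldid, enet_alphas,
                          pca_var = 0.95, lambda_rule = "lambda.1se") {
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- scale(X, center = center, scale = scale_)

  rotation <- NULL
  if (space == "pca") {
    pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    ncomp <- max(2, min(which(cum >= pca_var)))
    ncomp <- min(ncomp, ncol(Xs))
    rotation <- pc$rotation[, seq_len(ncomp), drop = FALSE]
    Xs <- Xs %*% rotation
  }

  cv_one <- function(alpha) glmnet::cv.glmnet(
    Xs, y, alpha = alpha, foldid = foldid, standardize = FALSE)
  if (penalty == "ridge") {
    cvs <- list(`0` = cv_one(0))
  } else if (penalty == "lasso") {
    cvs <- list(`1` = cv_one(1))
  } else {
    cvs <- lapply(stats::setNames(enet_alphas, enet_alphas), cv_one)
  }
  best <- which.min(vapply(cvs, function(cv)
    cv$cvm[cv$index[sub("lambda\\.", "", lambda_rule), 1]], 0))
  cv <- cvs[[best]]
  alpha <- as.numeric(names(cvs)[best])
  lambda <- cv[[lambda_rule]]
  cv_mse <- cv$cvm[cv$index[sub("lambda\\.", "", lambda_rule), 1]]
  cv_r2 <- 1 - cv_mse / mean((y - mean(y))^2)

  beta <- as.numeric(stats::coef(cv, s = lambda))
  nz <- which(beta[-1] != 0)
  space_names <- colnames(Xs)
  predictor <- function(Xnew) {
    Z <- scale(as.matrix(Xnew), center = center, scale = scale_)
    if (!is.null(rotation)) Z <- Z %*% rotation
    as.numeric(stats::predict(cv, newx = Z, s = lambda))
  }
  list(penalty = penalty, space = space, alpha = alpha, lambda = lambda,
       cv_r2 = cv_r2, coefficients = stats::setNames(beta[-1], space_names),
       intercept = beta[1],
       selected = if (!is.null(space_names)) space_names[nz] else nz,
       predict = predictor)
}

#' Fit the six-candidate tournament and select the winner
#'
#' Fits ridge, lasso and elastic-net regressions on the raw standardized
#' features and on PCA scores (components retained to 95% explained
#' variance), each with 5-fold cross-validated regularization strength
#' (shared folds), and selects the candidate with the highest
#' cross-validated R^2. The winner is refit on the complete training
#' cohort. Standardization and PCA statistics come from training only.
#'
#' @param X_train Numeric matrix/data.frame (subjects x features, >= 2
#'   features, >= 10 subjects).
#' @param y_train Outcome vector.
#' @param seed Seed for the shared CV folds.
#' @param nfolds Folds for hyperparameter cross-validation.
#' @param enet_alphas Mixing grid for elastic net.
#' @param lambda_rule `"lambda.1se"` (default, conservative) or
#'   `"lambda.min"`.
#' @return List of class `model_result`: winner description, per-candidate
#'   CV R^2 table, coefficients, and a `predict(Xnew)` closure.
#' @export
fit_and_select <- function(X_train, y_train, seed = 1, nfolds = 5,
                           enet_alphas = c(0.1, 0.5, 0.9),
                           lambda_rule = "lambda.1se") {
  X_train <- as.matrix(X_train)
  if (ncol(X_train) < 2) stop("need >= 2 features")
  if (nrow(X_train) < 10) stop("need >= 10 training subjects")
  if (stats::sd(y_train) == 0) stop("degenerate outcome: zero variance")
  set.seed(as.integer(seed %% 2147483647))
  foldid <- sample(rep(seq_len(nfolds), length.out = nrow(X_train)))

  candidates <- lapply(seq_len(nrow(MODEL_STRATEGIES)), function(i)
    fit_candidate(X_train, y_train,
                  MODEL_STRATEGIES$penalty[i], MODEL_STRATEGIES$space[i],
                  foldid, enet_alphas, lambda_rule = lambda_rule))
  cv_table <- data.frame(
    penalty = MODEL_STRATEGIES$penalty, space = MODEL_STRATEGIES$space,
    cv_r2 = vapply(candidates, `[[`, 0, "cv_r2"))
  winner <- candidates[[which.max(cv_table$cv_r2)]]

  structure(list(
    strategy = paste(winner$penalty, winner$space, sep = "_"),
    penalty = winner$penalty, space = winner$space,
    hyperparameters = list(alpha = winner$alpha, lambda = winner$lambda,
                           lambda_rule = lambda_rule, nfolds = nfolds),
    cv_r2 = winner$cv_r2, cv_table = cv_table,
    coefficients = winner$coefficients, intercept = winner$intercept,
    selected_features = winner$selected,
    n_train = nrow(X_train),
    predict = winner$predict
  ), class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s (alpha=%.2g, lambda=%.3g), CV R^2 = %.3f\n",
              x$strategy, x$hyperparameters$alpha, x$hyperparameters$lambda,
              x$cv_r2))
  if (!is.null(x$metrics))
    cat(sprintf("  validation: r=%.3f R^2=%.3f CCC=%.3f\n",
                x$metrics["pearson_r"], x$metrics["r_squared"],
                x$metrics["ccc"]))
  invisible(x)
}

# Validation metrics for a vector of predictions.
prediction_metrics <- function(y, yhat) {
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r <- if (stats::sd(yhat) == 0) 0 else stats::cor(y, yhat)
  c(pearson_r = r, r_squared = 1 - ss_res / ss_tot,
    ccc = if (stats::sd(yhat) == 0) 0 else ccc(y, yhat))
}

#' Evaluate a fitted model on the independent validation cohort
#'
#' Computes Pearson r, R^2 (`1 - SS_res/SS_tot` on validation) and Lin's
#' CCC for the winning model and, side by side, for a univariate
#' regression on the best single predictor (the training feature with the
#' highest univariate in-sample R^2, fit on training).
#'
#' @param model A `model_result` from [fit_and_select()].
#' @param X_train,y_train Training data (to choose and fit the single
#'   predictor).
#' @param X_val,y_val Validation data, disjoint from training.
#' @return The model with `metrics`, `best_single` (name, coefficients,
#'   metrics) and `predictions` filled in.
#' @export
evaluate_model <- function(model, X_train, y_train, X_val, y_val) {
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  if (!is.null(rownames(X_train)) && !is.null(rownames(X_val)) &&
      length(intersect(rownames(X_train), rownames(X_val))) > 0)
    stop("validation subjects overlap the training cohort")
  yhat <- model$predict(X_val)
  model$metrics <- prediction_metrics(y_val, yhat)
  model$predictions <- data.frame(y = y_val, y_hat = yhat)

  r2_uni <- apply(X_train, 2, function(x)
    if (stats::sd(x) == 0) -Inf else summary(stats::lm(y_train ~ x))$r.squared)
  best <- names(which.max(r2_uni))
  fit <- stats::lm(y_train ~ X_train[, best])
  yhat_s <- stats::coef(fit)[1] + stats::coef(fit)[2] * X_val[, best]
  model$best_single <- list(
    feature = best,
    train_r_squared = max(r2_uni),
    coefficients = stats::setNames(stats::coef(fit),
                                   c("(Intercept)", best)),
    metrics = prediction_metrics(y_val, yhat_s))
  model
}

#' Tournament over combined sway + drift feature blocks
#'
#' Gates each test's block independently, then runs the full six-candidate
#' tournament on the union block for each global outcome, reporting
#' whether the combined model beats each single-test model on validation
#' R^2.
#'
#' @param sway_gated,drift_gated Gated feature-name vectors per block.
#' @param X_train,y_train,X_val,y_val Data; `X_*` must contain all gated
#'   columns.
#' @param seed Seed for CV folds.
#' @param ... Passed to [fit_and_select()].
#' @return List with `combined`, `sway_only`, `drift_only` evaluated
#'   models and a `comparison` data.frame of validation R^2.
#' @export
combined_test_models <- function(sway_gated, drift_gated,
                                 X_train, y_train, X_val, y_val,
                                 seed = 1, ...) {
  union_feats <- union(sway_gated, drift_gated)
  if (length(union_feats) == 0) stop("empty union after gating")
  X_val <- as.matrix(X_val)
  run <- function(feats) {
    if (length(feats) < 2) return(NULL)
    m <- fit_and_select(X_train[, feats, drop = FALSE], y_train,
                        seed = seed, ...)
    if (nrow(X_val) >= 3 && stats::sd(y_val) > 0)
      m <- evaluate_model(m, X_train[, feats, drop = FALSE], y_train,
                          X_val[, feats, drop = FALSE], y_val)
    m
  }
  res <- list(combined = run(union_feats), sway_only = run(sway_gated),
              drift_only = run(drift_gated))
  r2 <- vapply(res, function(m)
    if (is.null(m) || is.null(m$metrics)) NA_real_
    else unname(m$metrics["r_squared"]), 0)
  res$comparison <- data.frame(model = names(r2), validation_r2 = r2,
                               row.names = NULL)
  res
}
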