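# Test-retest reliability: ICC(2,1) over the first two trials, the 0.5
# retention cutoff, and 1.5 x IQR (Tukey fence) outlier masking.

#' Single-measure absolute-agreement intraclass correlation, ICC(2,1)
#'
#' Two-way ANOVA decomposition with subjects and trials ("raters") as
#' crossed factors:
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#' where MSR, MSC, MSE are the subject, trial and residual mean squares,
#' n the number of subjects and k the number of trials. High values mean
#' the between-subject variance dominates the test-retest variance.
#'
#' @param data Numeric matrix, subjects x trials; rows with any missing
#'   cell are dropped.
#' @return ICC value in `[-1, 1]`, or `NA` (with attribute
#'   `reason = "zero variance"`) when the data carry no variance.
#' @export
icc_2_1 <- function(data) {
  data <- as.matrix(data)
  data <- data[stats::complete.cases(data), , drop = FALSE]
  n <- nrow(data)
  k <- ncol(data)
  if (n < 2) stop("icc_2_1: need >= 2 complete subjects")
  if (k < 2) stop("icc_2_1: need >= 2 trial columns")
  grand <- mean(data)
  if (sum((data - grand)^2) < 1e-300)
    return(structure(NA_real_, reason = "zero variance"))
  row_m <- rowMeans(data)
  col_m <- colMeans(data)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- data - outer(row_m, rep(1, k)) -
    outer(rep(1, n), col_m) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Filter biomarkers by test-retest reliability
#'
#' Computes ICC(2,1) per feature from the first two trials of each subject
#' and retains features whose ICC exceeds the threshold.
#'
#' @param features Feature data.frame with `subject_id`, `trial_index`
#'   and one column per biomarker (as from [extract_cohort_features()]).
#' @param threshold Retention cutoff on ICC (default 0.5).
#' @return data.frame of class `reliability_report`: `feature`, `icc`,
#'   `retained` (icc > threshold), `n_subjects_used`.
#' @export
filter_reliable <- function(features, threshold = 0.5) {
  fcols <- setdiff(names(features), c("subject_id", "trial_index"))
  if (length(fcols) == 0) stop("filter_reliable: empty feature matrix")
  t1 <- features[features$trial_index == 1, ]
  t2 <- features[features$trial_index == 2, ]
  common <- intersect(t1$subject_id, t2$subject_id)
  t1 <- t1[match(common, t1$subject_id), ]
  t2 <- t2[match(common, t2$subject_id), ]
  out <- do.call(rbind, lapply(fcols, function(f) {
    mat <- cbind(t1[[f]], t2[[f]])
    ok <- stats::complete.cases(mat)
    icc <- if (sum(ok) >= 2) icc_2_1(mat[ok, , drop = FALSE]) else NA_real_
    data.frame(feature = f, icc = as.numeric(icc),
               retained = isTRUE(icc > threshold),
               n_subjects_used = sum(ok))
  }))
  rownames(out) <- NULL
  class(out) <- c("reliability_report", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Tukey-fence outlier mask
#'
#' Flags values outside `[Q1 - mult*IQR, Q3 + mult*IQR]` with quartiles by
#' linear interpolation (type-7). Flagged values are masked as missing
#' downstream; the subject is retained.
#'
#' @param values Numeric vector, >= 4 non-missing values.
#' @param mult Fence multiplier (default 1.5).
#' @param fences Optional precomputed `c(lower, upper)` fences (e.g. from
#'   the training cohort) applied instead of recomputing.
#' @return Logical mask, `TRUE` = outlier; `NA` values stay `NA`-masked
#'   (`FALSE` in the mask).
#' @export
flag_outliers <- function(values, mult = 1.5, fences = NULL) {
  if (is.null(fences)) {
    if (sum(!is.na(values)) < 4) stop("flag_outliers: need >= 4 values")
    q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7,
                         names = FALSE)
    iqr <- q[2] - q[1]
    fences <- c(q[1] - mult * iqr, q[2] + mult * iqr)
  }
  out <- values < fences[1] | values > fences[2]
  out[is.na(out)] <- FALSE
  attr(out, "fences") <- fences
  out
}

#' Tukey fences of a training vector
#' @inheritParams flag_outliers
#' @return `c(lower, upper)`.
#' @export
outlier_fences <- function(values, mult = 1.5) {
  attr(flag_outliers(values, mult), "fences")
}
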