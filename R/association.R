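# Association analyses: Pearson correlation screening with
# Benjamini-Hochberg control, the healthy-volunteer age prediction-interval
# abnormality analysis, and pairwise Wilcoxon group testing.

#' Pearson correlation screen with BH adjustment
#'
#' Correlates every feature column against every outcome column with
#' pairwise-complete deletion (outlier-masked cells enter as `NA`), then
#' adjusts the two-sided p-values by the Benjamini-Hochberg false discovery
#' rate across the whole screen (one family per call).
#'
#' @param features data.frame/matrix of features (rows = subjects).
#' @param outcomes data.frame/matrix of outcomes, same row order.
#' @param alpha Significance level on adjusted p (default 0.05).
#' @return data.frame: `feature, outcome, pearson_r, p_value, p_adjusted,
#'   n, significant`. Constant pairs yield `NA` r with `degenerate = TRUE`.
#' @export
correlation_screen <- function(features, outcomes, alpha = 0.05) {
  features <- as.data.frame(features)
  outcomes <- as.data.frame(outcomes)
  rows <- list()
  for (f in names(features)) for (o in names(outcomes)) {
    x <- features[[f]]; y <- outcomes[[o]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    degenerate <- n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0
    if (degenerate) {
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, outcome = o, pearson_r = NA_real_,
        p_value = NA_real_, n = n, degenerate = TRUE)
    } else {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, outcome = o, pearson_r = unname(ct$estimate),
        p_value = ct$p.value, n = n, degenerate = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out[, c("feature", "outcome", "pearson_r", "p_value", "p_adjusted",
          "n", "significant", "degenerate")]
}

#' Healthy-volunteer age prediction interval and abnormality flags
#'
#' Fits ordinary least squares of a biomarker on age over the healthy
#' volunteers, forms the two-sided 95% prediction interval for a new
#' observation, and flags every subject whose biomarker value exceeds the
#' upper bound at their age (one-sided abnormality: disability elevates
#' sway). Reports flagged fractions per diagnosis group.
#'
#' @param hv data.frame of healthy volunteers with columns `age` and
#'   `value`.
#' @param all_subjects data.frame with `age`, `value`, `diagnosis` for
#'   everyone to be flagged.
#' @param level Prediction-interval coverage (default 0.95).
#' @return List of class `age_model_result`: `fit` (the lm), `slope`,
#'   `intercept`, `r_squared`, `flags` (per-subject logical),
#'   `abnormal_fraction_by_diagnosis`, and `interval(age)` returning the
#'   band.
#' @export
hv_age_prediction_interval <- function(hv, all_subjects, level = 0.95) {
  hv <- hv[!is.na(hv$age) & !is.na(hv$value), ]
  if (nrow(hv) < 10) stop("need >= 10 healthy volunteers")
  if (stats::sd(hv$age) == 0) stop("zero age variance in HV")
  fit <- stats::lm(value ~ age, data = hv)

  band <- function(age) {
    p <- stats::predict(fit, newdata = data.frame(age = age),
                        interval = "prediction", level = level)
    data.frame(age = age, fit = p[, "fit"], lower = p[, "lwr"],
               upper = p[, "upr"])
  }
  b <- band(all_subjects$age)
  # strict exceedance with a numerical guard, so an exact-line fit (zero
  # residual variance) flags nobody
  eps <- 1e-9 * pmax(1, abs(b$upper))
  flags <- !is.na(all_subjects$value) & all_subjects$value > b$upper + eps
  frac <- tapply(flags, all_subjects$diagnosis, mean)

  structure(list(
    fit = fit,
    slope = unname(stats::coef(fit)["age"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = summary(fit)$r.squared,
    level = level,
    flags = flags,
    abnormal_fraction_by_diagnosis = frac,
    interval = band
  ), class = "age_model_result")
}

#' Pairwise Wilcoxon rank-sum tests across diagnosis groups
#'
#' Two-sided Wilcoxon rank-sum test for every pair of groups, with BH
#' adjustment over all pairs and significance stars at 0.05 / 0.01.
#'
#' @param groups Named list: diagnosis -> numeric vector of biomarker
#'   values. Each group needs >= 3 non-missing values.
#' @return data.frame: `group1, group2, statistic, p_value, p_adjusted,
#'   stars`.
#' @export
pairwise_group_tests <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sizes <- vapply(groups, length, 0L)
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(sizes < 3))
    stop("groups below minimum size (3): ",
         paste(names(groups)[sizes < 3], collapse = ", "))
  pairs <- utils::combn(names(groups), 2)
  rows <- apply(pairs, 2, function(p) {
    wt <- stats::wilcox.test(groups[[p[1]]], groups[[p[2]]],
                             alternative = "two.sided", exact = FALSE)
    data.frame(group1 = p[1], group2 = p[2],
               statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$stars <- ifelse(out$p_adjusted <= 0.01, "**",
                      ifelse(out$p_adjusted <= 0.05, "*", ""))
  out
}
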