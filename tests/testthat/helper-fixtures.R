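# Shared fixtures: minimal subject rows and small cohorts built in code.

make_subject <- function(subject_id = "T001", age = 40, latent = 0,
                         cerebellar = 0, dominant_hand = "right",
                         sway_factor = 1, tilt_deg = 5, tilt_az = 1) {
  data.frame(subject_id = subject_id, age = age,
             dominant_hand = dominant_hand,
             latent_disability = latent, latent_cerebellar = cerebellar,
             sway_subject_factor = sway_factor,
             tilt_angle_deg = tilt_deg, tilt_azimuth = tilt_az,
             stringsAsFactors = FALSE)
}

# Calibrated series straight from a pair of horizontal components.
make_calibrated <- function(ml, ap, dt = 0.02, test = "EO-FA",
                            subject_id = "T001", trial_index = 1L) {
  structure(list(subject_id = subject_id, test = test,
                 trial_index = trial_index, dt = dt, ml = ml, ap = ap,
                 net = sqrt(ml^2 + ap^2), n_samples = length(ml)),
            class = "calibrated_series")
}

# One complete calibrated trial set (3 stances) from a tiny HV cohort.
complete_sway_set <- function(seed = 7) {
  subj <- make_subject()
  trials <- lapply(SWAY_STANCES_ <- c("EO-FA", "EO-FT", "EC-FT"),
                   function(s) calibrate_trial(
                     simulate_sway_trial(subj, s, 1, seed)))
  names(trials) <- SWAY_STANCES_
  trials
}

complete_drift_pair <- function(seed = 7, cerebellar = 1) {
  subj <- make_subject(cerebellar = cerebellar, latent = 1)
  list(left = calibrate_trial(simulate_drift_trial(subj, "drift_left", 1, seed)),
       right = calibrate_trial(simulate_drift_trial(subj, "drift_right", 1, seed + 1)))
}

# Independent brute-force BH step-up (oracle for p.adjust).
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Independent ANOVA-table ICC(2,1) oracle via aov().
icc_oracle <- function(mat) {
  df <- data.frame(y = as.vector(mat),
                   subj = factor(as.vector(row(mat))),
                   rater = factor(as.vector(col(mat))))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(mat); k <- ncol(mat)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Trial-level feature table with a prescribed true ICC per feature:
# value = subject effect (sd sqrt(icc)) + trial noise (sd sqrt(1-icc)).
features_with_icc <- function(n_subjects, iccs) {
  ids <- sprintf("S%03d", seq_len(n_subjects))
  out <- data.frame(subject_id = rep(ids, 2),
                    trial_index = rep(1:2, each = n_subjects))
  for (f in names(iccs)) {
    b <- stats::rnorm(n_subjects, 0, sqrt(iccs[[f]]))
    out[[f]] <- rep(b, 2) + stats::rnorm(2 * n_subjects, 0, sqrt(1 - iccs[[f]]))
  }
  out
}
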