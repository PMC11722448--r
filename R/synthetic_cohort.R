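# Synthetic cohort and trial generator.
#
# Emulates a mixed neurology clinic cohort (healthy volunteers plus
# inflammatory / non-inflammatory neurological disease groups) together with
# the raw smartphone accelerometer records of the balance test battery:
# three quiet-standing stances (EO-FA, EO-FT, EC-FT) and two pronator-drift
# hands, sampled at 50 Hz for ~9.5 s. A per-subject latent disability scalar
# drives both the clinical scales and the sway amplitude, so every
# downstream stage (calibration, feature extraction, reliability, screening,
# modeling) sees the statistical structure it assumes.

#' Default parameters of the synthetic cohort generator
#'
#' Returns the full parameter list controlling cohort demographics, clinical
#' scale generation, and the accelerometer signal model. All downstream
#' generator functions accept this list so single knobs can be overridden.
#'
#' Signal-model parameters (accelerations in m/s^2):
#' * `base_sway_sd`: horizontal sway acceleration SD of a young healthy
#'   subject in the easiest stance (EO-FA).
#' * `stance_factors`: multiplicative stance difficulty, ordered
#'   EO-FA < EO-FT < EC-FT (harder stances sway more).
#' * `age_slope`: fractional amplitude increase per year past `age_ref`.
#' * `disability_gain`: sway SD scales with exp(gain * latent disability).
#' * `subject_sd_log` / `trial_sd_log`: between-subject and between-day
#'   (within-subject, across-trial) SD of the log amplitude factor; their
#'   ratio sets the achievable test-retest ICC of amplitude biomarkers.
#' * `tremor_gain`: pronator-drift tremor (4-8 Hz) amplitude per unit of the
#'   cerebellar latent component.
#' * `clinical_cor_target`: Pearson correlation each clinical scale should
#'   achieve with latent disability; noise SDs are derived from it.
#'
#' @return Named list of generator parameters.
#' @export
default_cohort_params <- function() {
  list(
    sampling_hz        = 50,
    trial_seconds      = 9.5,
    base_sway_sd       = 0.03,
    ap_ml_ratio        = 1.25,
    stance_factors     = c("EO-FA" = 1.0, "EO-FT" = 1.45, "EC-FT" = 2.3),
    age_ref            = 20,
    age_slope          = 0.012,
    disability_gain    = 0.25,
    subject_sd_log     = 0.30,
    trial_sd_log       = 0.25,
    sensor_noise_sd    = 0.01,
    gravity            = 9.81,
    tilt_max_deg       = 15,
    drift_base_sd      = 0.04,
    tremor_gain        = 0.06,
    tremor_band        = c(4, 8),
    dominant_asymmetry = 0.15,
    age_disability_slope = 0.02,
    clinical_cor_target  = 0.85,
    severity_mean      = c(HV = 0, NIND = 1.0, OIND = 1.2, RRMS = 1.6,
                           SPMS = 3.2, PPMS = 3.6, CIS = 0.5, RIS = 0.2),
    severity_shape     = 4
  )
}

# Deterministic per-trial seed derived from the cohort seed and trial
# coordinates; kept below 2^31 so it is a valid R integer seed.
trial_seed <- function(seed, subject_idx, test, trial_index) {
  test_idx <- match(test, ALL_TESTS)
  s <- (as.double(seed) * 2654435.0 + subject_idx * 7919.0 +
          test_idx * 613.0 + trial_index * 97.0)
  as.integer(s %% 2147483647)
}

#' Generate a synthetic study cohort with accelerometer trials
#'
#' Draws `n_subjects` subjects according to `diagnosis_mix`, generates their
#' clinical and imaging outcomes as monotone noisy functions of a latent
#' disability scalar, and simulates `n_trials` complete trial sets per
#' subject (three sway stances plus two drift hands). Healthy volunteers
#' carry zero disease severity; their latent disability is the age term
#' alone. Identical seeds give identical output.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param diagnosis_mix Named proportions over diagnosis groups; must sum
#'   to 1. Names from `HV, NIND, OIND, RRMS, SPMS, PPMS, CIS, RIS`.
#' @param n_trials Trials per subject per test (>= 2, so test-retest
#'   reliability is defined).
#' @param seed Integer seed; all randomness derives from it.
#' @param params Generator parameters, see [default_cohort_params()].
#' @return List with `subjects` (one row per subject; latent columns are
#'   synthetic ground truth never used by analysis stages) and `trials`
#'   (list of raw trial objects, see [raw_trial()]).
#' @export
generate_cohort <- function(n_subjects, diagnosis_mix = c(HV = 1),
                            n_trials = 2, seed = 1,
                            params = default_cohort_params()) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (n_trials < 2) stop("n_trials must be >= 2 (test-retest requires two trials)")
  if (is.null(names(diagnosis_mix)) || !all(names(diagnosis_mix) %in% DIAGNOSES))
    stop("diagnosis_mix must be named with diagnoses among: ",
         paste(DIAGNOSES, collapse = ", "))
  if (abs(sum(diagnosis_mix) - 1) > 1e-8)
    stop("diagnosis_mix proportions must sum to 1")

  set.seed(as.integer(seed %% 2147483647))
  subjects <- generate_subjects(n_subjects, diagnosis_mix, params)

  trials <- vector("list", n_subjects * n_trials * length(ALL_TESTS))
  k <- 1L
  for (i in seq_len(n_subjects)) {
    subj <- subjects[i, ]
    for (trial in seq_len(n_trials)) {
      for (stance in SWAY_STANCES) {
        trials[[k]] <- simulate_sway_trial(
          subj, stance, trial, trial_seed(seed, i, stance, trial), params)
        k <- k + 1L
      }
      for (hand in DRIFT_TESTS) {
        trials[[k]] <- simulate_drift_trial(
          subj, hand, trial, trial_seed(seed, i, hand, trial), params)
        k <- k + 1L
      }
    }
  }
  list(subjects = subjects, trials = trials, seed = seed, n_trials = n_trials)
}

# Draw the subject table. Uses the current RNG stream (seeded by caller).
generate_subjects <- function(n, diagnosis_mix, params) {
  diagnosis <- sample(names(diagnosis_mix), n, replace = TRUE,
                      prob = diagnosis_mix)
  # fill small cohorts deterministically toward the mix to avoid empty groups
  age <- pmin(90, pmax(18, stats::rnorm(n, 48, 14)))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  height <- ifelse(sex == "F", stats::rnorm(n, 164, 7), stats::rnorm(n, 177, 7))
  weight <- pmax(40, stats::rnorm(n, 0.45 * height - 4, 12))
  dominant_hand <- sample(c("right", "left"), n, replace = TRUE,
                          prob = c(0.9, 0.1))

  sev_mean <- params$severity_mean[diagnosis]
  shape <- params$severity_shape
  severity <- ifelse(sev_mean > 0,
                     stats::rgamma(n, shape = shape, rate = shape / pmax(sev_mean, 1e-9)),
                     0)
  latent_disability <- severity +
    params$age_disability_slope * (age - 18)

  # split disease severity into functional subsystem components
  w <- matrix(stats::rgamma(3 * n, shape = 2, rate = 1), ncol = 3)
  w <- w / rowSums(w)
  cerebellar    <- severity * w[, 1] * 3
  proprioceptive <- severity * w[, 2] * 3
  motoric       <- severity * w[, 3] * 3
  side <- stats::runif(n, 0.35, 0.65)  # left share of per-hand dysfunction

  half <- function(x, share) pmax(0, x * share)
  noise <- function(sd) abs(stats::rnorm(n, 0, sd))

  panels <- data.frame(
    panel7_left   = half(motoric, side) * 0.3 + noise(0.2),
    panel7_right  = half(motoric, 1 - side) * 0.3 + noise(0.2),
    panel8_left   = half(motoric, side) * 0.8 + noise(0.3),
    panel8_right  = half(motoric, 1 - side) * 0.8 + noise(0.3),
    panel10_left  = half(motoric, side) * 0.4 + noise(0.2),
    panel10_right = half(motoric, 1 - side) * 0.4 + noise(0.2),
    panel12_left  = half(cerebellar, side) * 0.8 + noise(0.3),
    panel12_right = half(cerebellar, 1 - side) * 0.8 + noise(0.3),
    panel12_le    = cerebellar * 0.9 + noise(0.3),
    panel14_left  = half(proprioceptive, side) * 0.8 + noise(0.3),
    panel14_right = half(proprioceptive, 1 - side) * 0.8 + noise(0.3),
    panel14_le    = proprioceptive * 0.9 + noise(0.3),
    panel16       = (cerebellar + proprioceptive) * 0.8 + noise(0.4)
  )

  # bounded clinical scales: wide logistic of latent disability, noise SD
  # chosen from the realized signal SD to hit the configured correlation
  r <- params$clinical_cor_target
  noisy_scale <- function(signal, lo, hi) {
    s_sd <- stats::sd(signal)
    e_sd <- if (s_sd > 0 && r > 0 && r < 1) s_sd * sqrt(1 / r^2 - 1) else 0
    pmin(hi, pmax(lo, signal + stats::rnorm(n, 0, e_sd)))
  }
  D <- latent_disability
  edss <- noisy_scale(10 * stats::plogis((D - 4) / 2.0), 0, 10)
  edss <- round(edss * 2) / 2
  combiwise <- noisy_scale(100 * stats::plogis((D - 4) / 2.2), 0, 100)
  neurex_total <- pmax(0, rowSums(panels) * 1.4 +
                         stats::rnorm(n, 0, max(stats::sd(rowSums(panels)) * 0.2, 0.1)))

  grade <- function(x) pmin(4, pmax(0, round(x + stats::rnorm(n, 0, 0.5))))
  mri <- data.frame(
    mri_brainstem_atrophy        = grade(severity / 1.4),
    mri_brainstem_lesion_load    = grade(severity / 1.2),
    mri_cerebellum_atrophy       = grade(cerebellar / 2.0),
    mri_cerebellum_lesion_load   = grade(cerebellar / 1.6),
    mri_medulla_upper_cspine_atrophy     = grade(severity / 1.4),
    mri_medulla_upper_cspine_lesion_load = grade(severity / 1.2)
  )

  cbind(
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age, sex = sex, height = height, weight = weight,
      dominant_hand = dominant_hand, diagnosis = diagnosis,
      edss = edss, combiwise = combiwise, neurex_total = neurex_total,
      latent_disability = latent_disability,
      latent_cerebellar = cerebellar,
      latent_proprioceptive = proprioceptive,
      latent_motoric = motoric,
      sway_subject_factor = exp(stats::rnorm(n, 0, params$subject_sd_log)),
      tilt_angle_deg = stats::runif(n, 0, params$tilt_max_deg),
      tilt_azimuth = stats::runif(n, 0, 2 * pi),
      stringsAsFactors = FALSE
    ),
    panels, mri
  )
}

#' Construct a raw accelerometer trial
#'
#' @param subject_id Subject identifier.
#' @param test One of `EO-FA, EO-FT, EC-FT, drift_left, drift_right`.
#' @param trial_index Positive integer.
#' @param acc Numeric matrix (n x 3) of device-frame accelerations in m/s^2.
#' @param sampling_hz Sampling frequency, Hz.
#' @return Object of class `raw_trial`.
#' @export
raw_trial <- function(subject_id, test, trial_index, acc, sampling_hz = 50) {
  stopifnot(is.matrix(acc), ncol(acc) == 3)
  structure(
    list(subject_id = subject_id, test = test,
         trial_index = as.integer(trial_index),
         sampling_hz = sampling_hz, acc = acc),
    class = "raw_trial")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("<raw_trial> %s %s trial %d: %d samples @ %g Hz\n",
              x$subject_id, x$test, x$trial_index, nrow(x$acc), x$sampling_hz))
  invisible(x)
}

# Band-limited stochastic sway process, unit SD: a few damped sinusoids with
# random phases below ~3 Hz plus AR(1) noise.
sway_process <- function(n, fs) {
  t <- (seq_len(n) - 1) / fs
  k <- sample(2:4, 1)
  x <- rep(0, n)
  for (j in seq_len(k)) {
    f <- stats::runif(1, 0.15, 2.8)
    ph <- stats::runif(1, 0, 2 * pi)
    tau <- stats::runif(1, 2, 8)
    x <- x + exp(-t / tau) * sin(2 * pi * f * t + ph)
  }
  ar <- as.numeric(stats::filter(stats::rnorm(n + 200), 0.93,
                                 method = "recursive"))[-seq_len(200)]
  x <- x / max(stats::sd(x), 1e-12)
  ar <- ar / max(stats::sd(ar), 1e-12)
  z <- 0.75 * x + 0.55 * ar
  z / stats::sd(z)
}

# Rotation matrix tilting the body vertical by `angle` radians about a
# horizontal axis at azimuth `azimuth`.
tilt_rotation <- function(angle, azimuth) {
  ax <- c(cos(azimuth), sin(azimuth), 0)
  rotation_about_axis(ax, angle)
}

rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Shared assembly: embed horizontal body-frame sway into a tilted device
# frame on top of gravity, add white sensor noise.
embed_trial <- function(subject, test, trial_index, ml, ap, params) {
  n <- length(ml)
  g <- params$gravity
  body <- cbind(ml, ap, rep(g, n))
  R <- tilt_rotation(subject$tilt_angle_deg * pi / 180, subject$tilt_azimuth)
  acc <- body %*% t(R) +
    matrix(stats::rnorm(3 * n, 0, params$sensor_noise_sd), ncol = 3)
  raw_trial(subject$subject_id, test, trial_index, acc, params$sampling_hz)
}

# Common amplitude law: stance/age/disability multiplicative effects, a
# stable per-subject factor, and a per-trial (between-day) lognormal factor.
sway_amplitude <- function(subject, base_sd, difficulty, params) {
  trial_factor <- exp(stats::rnorm(1, 0, params$trial_sd_log))
  base_sd * difficulty *
    (1 + params$age_slope * max(0, subject$age - params$age_ref)) *
    exp(params$disability_gain * subject$latent_disability) *
    subject$sway_subject_factor * trial_factor
}

#' Simulate one postural-sway trial
#'
#' Horizontal sway is a band-limited (dominant below ~3 Hz) stochastic
#' process whose standard deviation scales multiplicatively with stance
#' difficulty (EO-FA < EO-FT < EC-FT), age, and exp(gain * latent
#' disability); gravity plus the subject's fixed mounting tilt is embedded
#' in the raw axes and white sensor noise added.
#'
#' @param subject One-row subject data frame from [generate_cohort()].
#' @param stance One of `EO-FA`, `EO-FT`, `EC-FT`.
#' @param trial_index Positive integer.
#' @param seed Integer seed for this trial.
#' @param params See [default_cohort_params()].
#' @return A [raw_trial()].
#' @export
simulate_sway_trial <- function(subject, stance, trial_index, seed,
                                params = default_cohort_params()) {
  if (!stance %in% SWAY_STANCES)
    stop("unknown stance: ", stance)
  set.seed(as.integer(seed %% 2147483647))
  n <- round(params$trial_seconds * params$sampling_hz)
  sd_ml <- sway_amplitude(subject, params$base_sway_sd,
                          params$stance_factors[[stance]], params)
  ml <- sd_ml * sway_process(n, params$sampling_hz)
  ap <- sd_ml * params$ap_ml_ratio * sway_process(n, params$sampling_hz)
  embed_trial(subject, stance, trial_index, ml, ap, params)
}

#' Simulate one pronator-drift trial
#'
#' As [simulate_sway_trial()] but held in the hand with the arm extended: a
#' narrowband tremor component (4-8 Hz) is added whose amplitude scales
#' with the cerebellar latent component, with a configurable
#' dominant/non-dominant asymmetry.
#'
#' @inheritParams simulate_sway_trial
#' @param hand `drift_left` or `drift_right`.
#' @return A [raw_trial()].
#' @export
simulate_drift_trial <- function(subject, hand, trial_index, seed,
                                 params = default_cohort_params()) {
  if (!hand %in% DRIFT_TESTS)
    stop("unknown hand: ", hand)
  set.seed(as.integer(seed %% 2147483647))
  n <- round(params$trial_seconds * params$sampling_hz)
  fs <- params$sampling_hz
  t <- (seq_len(n) - 1) / fs

  is_dom <- (hand == "drift_right") == (subject$dominant_hand == "right")
  asym <- if (is_dom) 1 - params$dominant_asymmetry else 1 + params$dominant_asymmetry

  sd_h <- sway_amplitude(subject, params$drift_base_sd, asym, params)
  ml <- sd_h * sway_process(n, fs)
  ap <- sd_h * sway_process(n, fs)

  trem_amp <- params$tremor_gain * subject$latent_cerebellar * asym
  if (trem_amp > 0) {
    f <- stats::runif(1, params$tremor_band[1], params$tremor_band[2])
    env <- 1 + 0.3 * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi))
    ph <- stats::runif(2, 0, 2 * pi)
    ml <- ml + trem_amp * env * sin(2 * pi * f * t + ph[1])
    ap <- ap + trem_amp * env * sin(2 * pi * f * t + ph[2])
  }
  embed_trial(subject, hand, trial_index, ml, ap, params)
}

#' Write trials to a long-format CSV
#'
#' Columns: `subject_id, test, trial_index, t, ax, ay, az`.
#' @param trials List of [raw_trial()] objects.
#' @param path Output CSV path.
#' @export
write_trials_csv <- function(trials, path) {
  tabs <- lapply(trials, function(tr) {
    n <- nrow(tr$acc)
    data.frame(subject_id = tr$subject_id, test = tr$test,
               trial_index = tr$trial_index,
               t = (seq_len(n) - 1) / tr$sampling_hz,
               ax = tr$acc[, 1], ay = tr$acc[, 2], az = tr$acc[, 3])
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read trials from a long-format CSV written by [write_trials_csv()]
#'
#' @param path CSV path.
#' @param sampling_hz Sampling frequency of the stored records.
#' @return List of [raw_trial()] objects.
#' @export
read_trials_csv <- function(path, sampling_hz = 50) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(df$subject_id, df$test, df$trial_index, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$t), ]
    raw_trial(d$subject_id[1], d$test[1], d$trial_index[1],
              cbind(d$ax, d$ay, d$az), sampling_hz)
  })
}
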