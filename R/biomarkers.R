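# Digital biomarker extraction: the four sway measurements (RMS, Jerk,
# spectral centroid, spectral spread) in every permutation of direction,
# stance/hand and condition ratio, log10-transformed.
#
# Sway: 4 measurements x 3 directions (ML, AP, Net) x 3 stances = 36,
# plus EC-FT:EO-FT (Romberg) and EO-FT:EO-FA ratios for each of the 12
# measurement-direction pairs = 24, totalling 60 biomarkers.
# Drift: Net measurements only (hand-held orientation is uncontrolled),
# 4 measurements x {Dom, Ndom, Sum, Diff} = 16 biomarkers.

MEASUREMENTS <- c("RMS", "Jerk", "SC", "SS")
DIRECTIONS <- c("ML", "AP", "Net")
SWAY_CONDITIONS <- c(SWAY_STANCES, "Romberg", "Stance")
DRIFT_CONDITIONS <- c("Dom", "Ndom", "Sum", "Diff")

#' Root-mean-square of an acceleration series
#'
#' `sqrt(mean(a_i^2))`: the sway amplitude measurement, in m/s^2.
#' @param series Nonempty numeric vector.
#' @return RMS value.
#' @export
rms <- function(series) {
  if (length(series) == 0) stop("rms: empty series")
  sqrt(mean(series^2))
}

#' Sway jerkiness: time-integrated squared derivative of acceleration
#'
#' `integral (dAcc/dt)^2 dt` over the trial. The derivative uses central
#' differences in the interior and one-sided differences at the ends; the
#' integral is trapezoidal. Units (m/s^3)^2 * s.
#' @param series Numeric vector, length >= 2.
#' @param dt Sampling interval in seconds.
#' @return Jerk value.
#' @export
jerk <- function(series, dt) {
  if (length(series) < 2) stop("jerk: need at least 2 samples")
  if (dt <= 0) stop("jerk: dt must be positive")
  d <- pracma::gradient(series, dt)
  pracma::trapz(d^2) * dt
}

#' Net jerkiness from both horizontal series
#'
#' `0.5 * integral [(dML/dt)^2 + (dAP/dt)^2] dt`, i.e. the mean of the two
#' directional Jerk values.
#' @param ml,ap Equal-length numeric vectors (>= 2 samples).
#' @param dt Sampling interval in seconds.
#' @return Net Jerk value.
#' @export
net_jerk <- function(ml, ap, dt) {
  if (length(ml) != length(ap)) stop("net_jerk: length mismatch")
  (jerk(ml, dt) + jerk(ap, dt)) / 2
}

#' One-sided power spectral density over a frequency band
#'
#' Single-taper periodogram of the mean-removed series, normalized so that
#' `sum(psd) * df` approximates the series variance (Parseval-consistent),
#' restricted to the requested band.
#' @param series Numeric vector.
#' @param fs Sampling frequency, Hz.
#' @param band Length-2 numeric `(low, high)` in Hz, within `(0, fs/2]`.
#' @return List of class `power_spectrum` with `freqs`, `psd`, `band`, `df`.
#' @export
power_spectrum <- function(series, fs, band) {
  if (fs <= 0) stop("power_spectrum: fs must be positive")
  if (band[1] <= 0 || band[2] > fs / 2 || band[1] >= band[2])
    stop("power_spectrum: band must lie within (0, fs/2]")
  x <- series - mean(series)
  n <- length(x)
  X <- stats::fft(x)
  two_sided <- Mod(X)^2 / (fs * n)
  nh <- floor(n / 2)
  freqs <- (1:nh) * fs / n
  psd <- 2 * two_sided[2:(nh + 1)]
  if (n %% 2 == 0) psd[nh] <- psd[nh] / 2  # Nyquist bin is not doubled
  keep <- freqs >= band[1] & freqs <= band[2]
  structure(list(freqs = freqs[keep], psd = psd[keep],
                 band = band, df = fs / n),
            class = "power_spectrum")
}

#' Spectral centroid and spread of a power spectrum
#'
#' First two PSD-weighted moments of frequency over the band:
#' centroid `SC = sum(f_k S_k) / sum(S_k)` (Hz, the "center of gravity" of
#' sway frequency) and spread `SS = sum((f_k - SC)^2 S_k) / sum(S_k)`
#' (Hz^2, dispersion of sway frequency).
#' @param spec A [power_spectrum()].
#' @return Named vector `c(SC = , SS = )`.
#' @export
spectral_moments <- function(spec) {
  s <- sum(spec$psd)
  if (s <= 0) stop("spectral_moments: all-zero spectrum in band")
  sc <- sum(spec$freqs * spec$psd) / s
  ss <- sum((spec$freqs - sc)^2 * spec$psd) / s
  c(SC = sc, SS = ss)
}

# Raw (pre-log) measurement set for one calibrated series in one direction.
series_measurements <- function(x, dt, fs, band) {
  spec <- power_spectrum(x, fs, band)
  mom <- spectral_moments(spec)
  c(RMS = rms(x), Jerk = jerk(x, dt), SC = mom[["SC"]], SS = mom[["SS"]])
}

# Raw measurement table (4 x 3) for one trial; Net Jerk uses both
# horizontal series, all other Net measurements the radial series.
trial_measurements <- function(cal, band) {
  fs <- 1 / cal$dt
  out <- cbind(
    ML  = series_measurements(cal$ml, cal$dt, fs, band),
    AP  = series_measurements(cal$ap, cal$dt, fs, band),
    Net = series_measurements(cal$net, cal$dt, fs, band))
  out["Jerk", "Net"] <- net_jerk(cal$ml, cal$ap, cal$dt)
  out
}

# log10 with a small positive guard for numerically-zero raw values.
log10_guard <- function(x, floor = 1e-12) log10(pmax(x, floor))

# Signed log transform for the sign-indefinite Diff drift features:
# sgn(x) * log10(1 + |x|/scale). Order-preserving, symmetric, ~linear at 0.
signed_log10 <- function(x, scale = 1e-3) sign(x) * log10(1 + abs(x) / scale)

#' Extract the 60 postural-sway biomarkers from one trial set
#'
#' Computes RMS, Jerk, spectral centroid and spectral spread for the ML,
#' AP and Net series of each stance, then the EC-FT:EO-FT (Romberg) and
#' EO-FT:EO-FA condition ratios on the raw values, and log10-transforms
#' every emitted value. Feature names follow
#' `<measurement>_<direction>_<condition>` with condition in
#' `EO-FA, EO-FT, EC-FT, Romberg, Stance`.
#'
#' @param trials Named list of `calibrated_series`, one per stance
#'   (`EO-FA`, `EO-FT`, `EC-FT`).
#' @param band Spectral band edges in Hz (default 0.15-10).
#' @return Named numeric vector of exactly 60 log10-scale biomarkers.
#' @export
extract_sway_features <- function(trials, band = c(0.15, 10)) {
  missing <- setdiff(SWAY_STANCES, names(trials))
  if (length(missing) > 0)
    stop("missing stance(s): ", paste(missing, collapse = ", "))
  raw <- lapply(trials[SWAY_STANCES], trial_measurements, band = band)

  vals <- c()
  for (stance in SWAY_STANCES)
    for (dir in DIRECTIONS)
      for (m in MEASUREMENTS)
        vals[paste(m, dir, stance, sep = "_")] <- raw[[stance]][m, dir]
  for (dir in DIRECTIONS)
    for (m in MEASUREMENTS) {
      vals[paste(m, dir, "Romberg", sep = "_")] <-
        raw[["EC-FT"]][m, dir] / raw[["EO-FT"]][m, dir]
      vals[paste(m, dir, "Stance", sep = "_")] <-
        raw[["EO-FT"]][m, dir] / raw[["EO-FA"]][m, dir]
    }
  log10_guard(vals)
}

#' Extract the 16 pronator-drift biomarkers from a pair of hand trials
#'
#' Net-direction RMS, Jerk, spectral centroid and spread per hand,
#' relabeled dominant/non-dominant, plus across-hand sums and differences
#' (`Diff = Dom - Ndom`) computed on raw values. All features are
#' log10-transformed except Diff, which is sign-indefinite and uses the
#' signed transform `sgn(x) * log10(1 + |x|/1e-3)`.
#'
#' @param left,right `calibrated_series` for the two hands.
#' @param dominant_hand `"left"` or `"right"`.
#' @param band Spectral band edges in Hz (default 0.15-15, covering the
#'   4-8 Hz tremor band).
#' @return Named numeric vector of exactly 16 biomarkers.
#' @export
extract_drift_features <- function(left, right, dominant_hand,
                                   band = c(0.15, 15)) {
  if (is.null(left) || is.null(right)) stop("both hands required")
  if (!dominant_hand %in% c("left", "right"))
    stop("dominant_hand must be 'left' or 'right'")
  m_left <- trial_measurements(left, band)[, "Net"]
  m_right <- trial_measurements(right, band)[, "Net"]
  dom <- if (dominant_hand == "left") m_left else m_right
  ndom <- if (dominant_hand == "left") m_right else m_left

  vals <- c()
  for (m in MEASUREMENTS) {
    vals[paste(m, "Net", "Dom", sep = "_")] <- log10_guard(dom[[m]])
    vals[paste(m, "Net", "Ndom", sep = "_")] <- log10_guard(ndom[[m]])
    vals[paste(m, "Net", "Sum", sep = "_")] <- log10_guard(dom[[m]] + ndom[[m]])
    vals[paste(m, "Net", "Diff", sep = "_")] <- signed_log10(dom[[m]] - ndom[[m]])
  }
  vals
}

#' Names of the sway and drift biomarker sets
#'
#' @return List with `sway` (60 names) and `drift` (16 names).
#' @export
biomarker_names <- function() {
  sway <- c(
    as.vector(outer(MEASUREMENTS,
                    as.vector(outer(DIRECTIONS, SWAY_CONDITIONS, paste, sep = "_")),
                    paste, sep = "_")))
  drift <- as.vector(outer(MEASUREMENTS, paste("Net", DRIFT_CONDITIONS, sep = "_"),
                           paste, sep = "_"))
  list(sway = sort(sway), drift = sort(drift))
}

#' Feature dictionary
#'
#' One row per biomarker: name, test, measurement, direction, condition,
#' units of the raw value, and the transform applied.
#' @return data.frame with 76 rows.
#' @export
feature_dictionary <- function() {
  units <- c(RMS = "m/s^2", Jerk = "(m/s^3)^2*s", SC = "Hz", SS = "Hz^2")
  rows <- list()
  for (m in MEASUREMENTS) for (dir in DIRECTIONS) for (cond in SWAY_CONDITIONS)
    rows[[length(rows) + 1]] <- data.frame(
      name = paste(m, dir, cond, sep = "_"), test = "postural_sway",
      measurement = m, direction = dir, condition = cond,
      raw_units = if (cond %in% SWAY_STANCES) units[[m]] else "ratio",
      transform = "log10")
  for (m in MEASUREMENTS) for (cond in DRIFT_CONDITIONS)
    rows[[length(rows) + 1]] <- data.frame(
      name = paste(m, "Net", cond, sep = "_"), test = "pronator_drift",
      measurement = m, direction = "Net", condition = cond,
      raw_units = if (cond == "Diff") paste0("signed ", units[[m]]) else units[[m]],
      transform = if (cond == "Diff") "signed_log10" else "log10")
  do.call(rbind, rows)
}

#' Extract the full biomarker matrix for a cohort
#'
#' Calibrates every trial and produces one row per subject-trial with the
#' 60 sway and 16 drift biomarkers as columns.
#'
#' @param cohort Output of [generate_cohort()] (or a compatible list with
#'   `subjects` and `trials`).
#' @param sway_band,drift_band Spectral band edges in Hz.
#' @return data.frame: `subject_id`, `trial_index`, then 76 feature columns.
#' @export
extract_cohort_features <- function(cohort, sway_band = c(0.15, 10),
                                    drift_band = c(0.15, 15)) {
  cal <- lapply(cohort$trials, calibrate_trial)
  key <- vapply(cal, function(x)
    paste(x$subject_id, x$trial_index, sep = "|"), "")
  rows <- lapply(split(cal, key), function(trs) {
    tests <- vapply(trs, `[[`, "", "test")
    names(trs) <- tests
    subj_id <- trs[[1]]$subject_id
    dom <- cohort$subjects$dominant_hand[cohort$subjects$subject_id == subj_id]
    sway <- extract_sway_features(trs[SWAY_STANCES], band = sway_band)
    drift <- extract_drift_features(trs[["drift_left"]], trs[["drift_right"]],
                                    dom, band = drift_band)
    cbind(data.frame(subject_id = subj_id,
                     trial_index = trs[[1]]$trial_index),
          as.data.frame(as.list(c(sway, drift)), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id, out$trial_index), ]
}
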