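# Tilt calibration: raw device-frame tri-axial records -> body-axis
# medio-lateral / antero-posterior / radial (Net) acceleration series.

#' Calibrate a raw tri-axial trial into body-axis sway series
#'
#' Implements the standard tilt-correction convention for trunk-worn
#' accelerometer sway analysis: the record is trimmed to its first 9 s
#' (N = 450 samples at 50 Hz), the gravity direction is estimated as the
#' trial-mean acceleration vector, the frame is rotated by the minimal
#' rotation taking that vector onto the vertical axis, gravity is removed,
#' and the two demeaned horizontal components become the medio-lateral and
#' antero-posterior series according to the declared device orientation.
#' The radial (Net) series is `sqrt(ml^2 + ap^2)` pointwise, so Net RMS^2 =
#' ML RMS^2 + AP RMS^2 by construction. For hand-held drift tests the
#' device orientation is uncontrolled, so only orientation-invariant Net
#' quantities are meaningful downstream.
#'
#' @param raw A [raw_trial()] with at least 450 samples at 50 Hz.
#' @param seconds Window length to keep from the start (default 9 s).
#' @return Object of class `calibrated_series` with elements `ml`, `ap`,
#'   `net` (length-450 numeric), `dt`, and the trial identifiers.
#' @export
calibrate_trial <- function(raw, seconds = 9) {
  n_keep <- round(seconds * raw$sampling_hz)
  if (nrow(raw$acc) < n_keep)
    stop(sprintf("trial %s/%s/%d has %d samples; need >= %d",
                 raw$subject_id, raw$test, raw$trial_index,
                 nrow(raw$acc), n_keep))
  acc <- raw$acc[seq_len(n_keep), , drop = FALSE]

  m <- colMeans(acc)
  g <- sqrt(sum(m^2))
  if (g < 1e-9)
    stop("degenerate trial: zero-magnitude mean acceleration, cannot orient")
  R <- rotation_to_vertical(m / g)
  rot <- acc %*% t(R)

  ml <- rot[, 1] - mean(rot[, 1])
  ap <- rot[, 2] - mean(rot[, 2])
  structure(
    list(subject_id = raw$subject_id, test = raw$test,
         trial_index = raw$trial_index, dt = 1 / raw$sampling_hz,
         ml = ml, ap = ap, net = sqrt(ml^2 + ap^2), n_samples = n_keep),
    class = "calibrated_series")
}

# Minimal rotation (Rodrigues) taking unit vector u onto the vertical e3.
rotation_to_vertical <- function(u) {
  e3 <- c(0, 0, 1)
  c_ <- sum(u * e3)
  axis <- c(u[2] * e3[3] - u[3] * e3[2],
            u[3] * e3[1] - u[1] * e3[3],
            u[1] * e3[2] - u[2] * e3[1])
  s <- sqrt(sum(axis^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any horizontal axis
    return(rotation_about_axis(c(1, 0, 0), pi))
  }
  rotation_about_axis(axis, atan2(s, c_))
}

#' @export
print.calibrated_series <- function(x, ...) {
  cat(sprintf("<calibrated_series> %s %s trial %d: N=%d, dt=%g s\n",
              x$subject_id, x$test, x$trial_index, x$n_samples, x$dt))
  invisible(x)
}

#' Write a calibrated series as CSV (columns t, ml, ap, net)
#' @param cal A `calibrated_series`.
#' @param path Output path.
#' @export
write_calibrated_csv <- function(cal, path) {
  utils::write.csv(
    data.frame(t = (seq_len(cal$n_samples) - 1) * cal$dt,
               ml = cal$ml, ap = cal$ap, net = cal$net),
    path, row.names = FALSE)
  invisible(path)
}
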