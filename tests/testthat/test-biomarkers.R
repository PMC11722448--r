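# The four measurements and the 60/16 biomarker grammar.

test_that("rms matches constant, hand-computed and analytic sinusoid cases", {
  expect_equal(rms(rep(2, 100)), 2)
  expect_equal(rms(c(3, -4)), sqrt(12.5))
  t <- (0:449) / 50
  expect_equal(rms(sin(2 * pi * 1 * t)), 1 / sqrt(2), tolerance = 1e-3)
  expect_error(rms(numeric(0)), "empty")
})

test_that("jerk matches zero, analytic ramp and quadratic homogeneity", {
  dt <- 0.02
  expect_equal(jerk(rep(5, 450), dt), 0)
  ramp <- 2 * seq(0, 9, by = dt)  # slope 2 over 9 s -> integral m^2 T = 36
  expect_equal(jerk(ramp, dt), 36, tolerance = 0.01 * 36)
  set.seed(1)
  x <- rnorm(450)
  expect_equal(jerk(2 * x, dt), 4 * jerk(x, dt), tolerance = 1e-12)
  expect_error(jerk(1, dt), "2 samples")
  expect_error(jerk(c(1, 2), 0), "positive")
})

test_that("net jerk is the mean of the directional jerks", {
  dt <- 0.02
  set.seed(2)
  ml <- rnorm(450)
  ap <- rnorm(450)
  expect_equal(net_jerk(ml, ap, dt), (jerk(ml, dt) + jerk(ap, dt)) / 2,
               tolerance = 1e-12)
  expect_equal(net_jerk(ml, ml, dt), jerk(ml, dt), tolerance = 1e-12)
  expect_equal(net_jerk(ml, rep(1, 450), dt), jerk(ml, dt) / 2,
               tolerance = 1e-12)
  expect_error(net_jerk(ml, ap[-1], dt), "mismatch")
})

test_that("power spectrum localizes tones and is Parseval-consistent", {
  t <- (0:449) / 50
  tone <- sin(2 * pi * 3 * t)
  sp <- power_spectrum(tone, 50, c(0.15, 10))
  expect_lt(abs(sp$freqs[which.max(sp$psd)] - 3), sp$df + 1e-12)
  expect_true(all(sp$psd >= 0))
  expect_true(all(diff(sp$freqs) > 0))
  # full-band integral of the PSD equals the series variance
  set.seed(3)
  x <- rnorm(450)
  spx <- power_spectrum(x, 50, c(1e-6, 25))
  expect_equal(sum(spx$psd) * spx$df, mean((x - mean(x))^2),
               tolerance = 1e-10)
  expect_equal(sum(power_spectrum(rep(0, 450), 50, c(0.15, 10))$psd), 0)
  expect_error(power_spectrum(x, 50, c(0.15, 30)), "band")
})

test_that("white-noise PSD flattens under averaging", {
  set.seed(4)
  cv <- function(n) {
    sp <- power_spectrum(rnorm(n), 50, c(1, 24))
    stats::sd(sp$psd) / mean(sp$psd)
  }
  # the per-bin periodogram CV is ~1 regardless of n; averaging adjacent
  # bins of a longer series shrinks it
  sp_long <- power_spectrum(rnorm(45000), 50, c(1, 24))
  chunks <- split(sp_long$psd, ceiling(seq_along(sp_long$psd) / 100))
  smoothed <- vapply(chunks, mean, 0)
  expect_lt(stats::sd(smoothed) / mean(smoothed), 0.5)
})

test_that("spectral moments match point-mass, two-bin and flat cases", {
  pm <- structure(list(freqs = c(1, 2, 3), psd = c(0, 5, 0)),
                  class = "power_spectrum")
  expect_equal(unname(spectral_moments(pm)), c(2, 0))
  two <- structure(list(freqs = c(1, 3), psd = c(1, 1)),
                   class = "power_spectrum")
  expect_equal(unname(spectral_moments(two)), c(2, 1))
  flat <- structure(list(freqs = seq(0.5, 4.5, by = 0.1),
                         psd = rep(1, 41)), class = "power_spectrum")
  expect_equal(spectral_moments(flat)[["SC"]], 2.5, tolerance = 0.1)
  zero <- structure(list(freqs = c(1, 2), psd = c(0, 0)),
                    class = "power_spectrum")
  expect_error(spectral_moments(zero), "all-zero")
})

test_that("a complete sway trial yields exactly the 60-name grammar", {
  feats <- extract_sway_features(complete_sway_set())
  expect_length(feats, 60)
  expect_false(any(duplicated(names(feats))))
  expect_setequal(names(feats), biomarker_names()$sway)
  expect_error(extract_sway_features(complete_sway_set()[1:2]), "missing stance")
})

test_that("ratio biomarkers obey the log identity and equal-trial null", {
  trials <- complete_sway_set()
  feats <- extract_sway_features(trials)
  for (m in c("RMS", "Jerk", "SC", "SS")) for (d in c("ML", "AP", "Net")) {
    expect_equal(feats[[paste(m, d, "Romberg", sep = "_")]],
                 feats[[paste(m, d, "EC-FT", sep = "_")]] -
                   feats[[paste(m, d, "EO-FT", sep = "_")]],
                 tolerance = 1e-10)
    expect_equal(feats[[paste(m, d, "Stance", sep = "_")]],
                 feats[[paste(m, d, "EO-FT", sep = "_")]] -
                   feats[[paste(m, d, "EO-FA", sep = "_")]],
                 tolerance = 1e-10)
  }
  same <- trials
  same[["EC-FT"]] <- same[["EO-FT"]]
  feats_same <- extract_sway_features(same)
  romberg <- feats_same[grep("_Romberg$", names(feats_same))]
  expect_equal(unname(romberg), rep(0, 12), tolerance = 1e-12)
})

test_that("a complete drift pair yields the 16-name grammar with Sum/Diff identities", {
  pair <- complete_drift_pair()
  feats <- extract_drift_features(pair$left, pair$right, "right")
  expect_length(feats, 16)
  expect_setequal(names(feats), biomarker_names()$drift)
  for (m in c("RMS", "Jerk", "SC", "SS")) {
    dom <- 10^feats[[paste(m, "Net", "Dom", sep = "_")]]
    ndom <- 10^feats[[paste(m, "Net", "Ndom", sep = "_")]]
    expect_equal(10^feats[[paste(m, "Net", "Sum", sep = "_")]], dom + ndom,
                 tolerance = 1e-10)
  }
  # identical hands: all Diff features are exactly the transform of zero
  feats0 <- extract_drift_features(pair$left, pair$left, "right")
  expect_equal(unname(feats0[grep("_Diff$", names(feats0))]), rep(0, 4))
  expect_error(extract_drift_features(NULL, pair$right, "right"), "both hands")
})

test_that("amplitude scaling shifts RMS/Jerk logs and leaves SC/SS unchanged", {
  trials <- complete_sway_set()
  scaled <- lapply(trials, function(cal) {
    cal$ml <- 3 * cal$ml; cal$ap <- 3 * cal$ap; cal$net <- 3 * cal$net
    cal
  })
  f1 <- extract_sway_features(trials)
  f3 <- extract_sway_features(scaled)
  stance_names <- function(m) paste(m, rep(c("ML", "AP", "Net"), each = 3),
                                    c("EO-FA", "EO-FT", "EC-FT"), sep = "_")
  expect_equal(f3[stance_names("RMS")], f1[stance_names("RMS")] + log10(3),
               tolerance = 1e-10)
  expect_equal(f3[stance_names("Jerk")], f1[stance_names("Jerk")] + 2 * log10(3),
               tolerance = 1e-10)
  expect_equal(f3[stance_names("SC")], f1[stance_names("SC")], tolerance = 1e-10)
  expect_equal(f3[stance_names("SS")], f1[stance_names("SS")], tolerance = 1e-10)
})

test_that("the feature dictionary covers all 76 biomarkers", {
  dict <- feature_dictionary()
  expect_equal(nrow(dict), 76)
  expect_setequal(dict$name, c(biomarker_names()$sway, biomarker_names()$drift))
  expect_equal(sum(dict$transform == "signed_log10"), 4)
})
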