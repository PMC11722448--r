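# Synthetic cohort generator: counts, determinism, and whether the
# configured effect sizes (stance difficulty, disability, age, tremor)
# are recoverable from the generated signals.

test_that("cohort has complete trial sets and is deterministic under seed", {
  a <- generate_cohort(10, c(HV = 1), n_trials = 2, seed = 7)
  b <- generate_cohort(10, c(HV = 1), n_trials = 2, seed = 7)
  expect_equal(nrow(a$subjects), 10)
  expect_length(a$trials, 10 * 2 * 5)  # 3 stances + 2 hands per trial set
  expect_identical(a$subjects, b$subjects)
  expect_identical(lapply(a$trials, `[[`, "acc"),
                   lapply(b$trials, `[[`, "acc"))
  # every subject has every test twice
  key <- table(vapply(a$trials, function(tr)
    paste(tr$subject_id, tr$test), ""))
  expect_true(all(key == 2))
})

test_that("generator rejects invalid inputs", {
  expect_error(generate_cohort(10, c(HV = 0.5, RRMS = 0.4)), "sum to 1")
  expect_error(generate_cohort(10, c(HV = 1), n_trials = 1), "n_trials")
  expect_error(generate_cohort(1, c(HV = 1)), "n_subjects")
  expect_error(simulate_sway_trial(make_subject(), "EC-XX", 1, 1), "unknown stance")
  expect_error(simulate_drift_trial(make_subject(), "drift_up", 1, 1), "unknown hand")
})

test_that("disease groups carry higher latent disability than HV", {
  co <- generate_cohort(200, c(HV = 0.5, PPMS = 0.5), n_trials = 2, seed = 1)
  m <- tapply(co$subjects$latent_disability, co$subjects$diagnosis, mean)
  expect_gt(m[["PPMS"]], m[["HV"]])
  # HV latent disability is the age term alone
  hv <- co$subjects[co$subjects$diagnosis == "HV", ]
  p <- default_cohort_params()
  expect_equal(hv$latent_disability,
               p$age_disability_slope * (hv$age - 18), tolerance = 1e-12)
})

test_that("sway variance respects disability and stance-difficulty ordering", {
  s0 <- make_subject(latent = 0)
  s3 <- make_subject(latent = 3)
  hvar <- function(tr) {
    cal <- calibrate_trial(tr)
    stats::var(cal$ml) + stats::var(cal$ap)
  }
  # same seed pathway: identical process, amplitude scaled by exp(k*D)
  expect_gt(hvar(simulate_sway_trial(s3, "EO-FT", 1, 5)),
            hvar(simulate_sway_trial(s0, "EO-FT", 1, 5)))
  # matched seeds: EC-FT >= EO-FT >= EO-FA
  v <- vapply(c("EO-FA", "EO-FT", "EC-FT"), function(st)
    hvar(simulate_sway_trial(s0, st, 1, 5)), 0)
  expect_true(v[["EO-FA"]] <= v[["EO-FT"]] && v[["EO-FT"]] <= v[["EC-FT"]])
})

test_that("configured effects are ordered over replicate trials", {
  reps <- 100
  hsd <- function(subj, stance, seed) {
    cal <- calibrate_trial(simulate_sway_trial(subj, stance, 1, seed))
    sqrt(stats::var(cal$ml) + stats::var(cal$ap))
  }
  young <- make_subject(age = 25)
  old <- make_subject(age = 80)
  sd_young <- vapply(seq_len(reps), function(i) hsd(young, "EO-FT", i), 0)
  sd_old <- vapply(seq_len(reps), function(i) hsd(old, "EO-FT", i + reps), 0)
  expect_gt(mean(sd_old), mean(sd_young))
  sd_easy <- vapply(seq_len(reps), function(i) hsd(young, "EO-FA", 3000 + i), 0)
  sd_mid <- vapply(seq_len(reps), function(i) hsd(young, "EO-FT", 6000 + i), 0)
  sd_hard <- vapply(seq_len(reps), function(i) hsd(young, "EC-FT", 9000 + i), 0)
  expect_true(mean(sd_easy) < mean(sd_mid) && mean(sd_mid) < mean(sd_hard))
})

test_that("zero sway amplitude leaves pure gravity in the raw axes", {
  p <- default_cohort_params()
  p$base_sway_sd <- 0
  tr <- simulate_sway_trial(make_subject(), "EO-FA", 1, 3, params = p)
  mag <- sqrt(rowSums(tr$acc^2))
  expect_lt(abs(mean(mag) - 9.81) / 9.81, 0.05)
})

test_that("tremor requires a cerebellar component and shifts the spectrum", {
  p <- default_cohort_params()
  null_subj <- make_subject(cerebellar = 0)
  trem_subj <- make_subject(cerebellar = 5)
  centroid <- function(subj, seed) {
    cal <- calibrate_trial(simulate_drift_trial(subj, "drift_right", 1, seed, p))
    spectral_moments(power_spectrum(cal$net, 50, c(0.15, 15)))[["SC"]]
  }
  sc_null <- vapply(1:20, function(i) centroid(null_subj, i), 0)
  sc_trem <- vapply(1:20, function(i) centroid(trem_subj, i), 0)
  expect_gt(mean(sc_trem), mean(sc_null))
  expect_gt(mean(sc_trem), 3)  # pulled toward the 4-8 Hz band
  # null case: tremor-band power stays at the broadband floor
  band_power <- function(subj, seed) {
    cal <- calibrate_trial(simulate_drift_trial(subj, "drift_right", 1, seed, p))
    sp <- power_spectrum(cal$ml, 50, c(0.15, 15))
    sum(sp$psd[sp$freqs >= 4 & sp$freqs <= 8]) / sum(sp$psd)
  }
  expect_gt(mean(vapply(1:20, function(i) band_power(trem_subj, i), 0)),
            mean(vapply(1:20, function(i) band_power(null_subj, i), 0)))
})

test_that("clinical scales track latent disability at the configured strength", {
  co <- generate_cohort(500, c(HV = 0.3, NIND = 0.2, RRMS = 0.3,
                               SPMS = 0.1, PPMS = 0.1), 2, seed = 11)
  s <- co$subjects
  target <- default_cohort_params()$clinical_cor_target
  expect_lt(abs(cor(s$edss, s$latent_disability) - target), 0.1)
  expect_lt(abs(cor(s$combiwise, s$latent_disability) - target), 0.1)
  expect_gt(cor(s$neurex_total, s$latent_disability), 0.5)
  # scale invariants
  expect_true(all(s$edss >= 0 & s$edss <= 10 & (s$edss * 2) %% 1 == 0))
  expect_true(all(s$combiwise >= 0 & s$combiwise <= 100))
  expect_true(all(s$age >= 18 & s$age <= 90))
  panel_cols <- grep("^panel", names(s), value = TRUE)
  expect_true(all(as.matrix(s[, panel_cols]) >= 0))
  expect_true(all(as.matrix(s[, grep("^mri_", names(s))]) >= 0))
})

test_that("trial CSV round-trips", {
  co <- generate_cohort(2, c(HV = 1), 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(co$trials[1:4], path)
  back <- read_trials_csv(path)
  orig <- co$trials[1:4]
  key <- function(tr) paste(tr$subject_id, tr$test, tr$trial_index)
  back <- back[match(vapply(orig, key, ""), vapply(back, key, ""))]
  for (i in 1:4)
    expect_equal(back[[i]]$acc, orig[[i]]$acc, tolerance = 1e-6,
                 ignore_attr = TRUE)
})
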