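test_that("subject metadata honours the configured distributions", {
  cfg <- cohort_config(200, 200, seed = 77, movements = "back_extension",
                       speeds = "preferred")
  subs <- draw_subjects(cfg)
  expect_equal(nrow(subs), 400L)
  expect_true(all(subs$group %in% 0:1))
  expect_true(all(subs$sex %in% 0:1))
  expect_true(all(subs$age >= 18))
  # BMI identity holds exactly
  expect_equal(subs$bmi, subs$weight / (subs$height / 100)^2,
               tolerance = 1e-6)
  # planted BMI gap ~ 2.5 within Monte-Carlo error
  gap <- mean(subs$bmi[subs$group == 1]) - mean(subs$bmi[subs$group == 0])
  expect_equal(gap, 2.5, tolerance = 3 * sqrt(2 * 3^2 / 200))
  # same seed reproduces the table
  expect_identical(subs, draw_subjects(cfg))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(0, 5), ">= 1")
  expect_error(cohort_config(3, 3, age_sd = -1), "negative variance")
  expect_error(effect_profile(marker_noise_m = -0.1), ">= 0")
  expect_error(effect_profile(gfr_equalization = 2), "\\[0, 1\\]")
  cfg <- cohort_config(1, 1, seed = 1)
  expect_error(simulate_trial(draw_subjects(cfg)[1, ], "jump", "preferred"),
               "arg")
})

test_that("trials are bit-identical for the same subject and seed", {
  cfg <- tiny_cohort_config(1, 1, seed = 19, n_repetitions = 3L)
  s <- draw_subjects(cfg)[1, ]
  t1 <- simulate_trial(s, "rot_left", "maximum", cfg$effect, seed = 5,
                       n_repetitions = 3, rep_duration_s = 0.7,
                       gap_s = 0.35, lead_s = 0.5)
  t2 <- simulate_trial(s, "rot_left", "maximum", cfg$effect, seed = 5,
                       n_repetitions = 3, rep_duration_s = 0.7,
                       gap_s = 0.35, lead_s = 0.5)
  expect_identical(t1, t2)
  # sampling rates fixed by the acquisition design
  expect_equal(t1$fs$emg, 2048)
  expect_equal(t1$fs$markers, 120)
  expect_equal(t1$fs$plates, 1000)
  expect_equal(nrow(t1$rep_windows_truth), 3L)
  expect_true(all(vapply(t1$emg, function(m) all(is.finite(m)), logical(1))))
})

test_that("a constant-activity request yields a uniform RMS map", {
  cfg <- tiny_cohort_config(1, 1, seed = 23, n_repetitions = 3L)
  s <- draw_subjects(cfg)[1, ]
  tr <- simulate_trial(s, "back_flexion", "preferred",
                       effect_profile(ecg_amplitude = 0,
                                      wander_amplitude = 0),
                       seed = 6, n_repetitions = 3, rep_duration_s = 0.7,
                       gap_s = 0.35, lead_s = 0.5, uniform_activity = TRUE)
  m <- electrode_rms(tr$emg$left_lower, tr$layouts$left_lower)
  expect_lt(sd(m$values) / mean(m$values), 0.1)
})

test_that("a zero effect profile leaves the groups exchangeable", {
  cfg <- cohort_config(150, 150, seed = 41, effect = null_effect_profile())
  subs <- draw_subjects(cfg)
  for (v in c("age", "bmi", "height")) {
    p <- t.test(subs[[v]] ~ subs$group)$p.value
    expect_gt(p, 0.001)
  }
})

test_that("the planted time-to-max slowdown is recovered downstream", {
  # planted x1.5 on the NSLBP repetition duration: the group-mean ratio of
  # extracted time-to-max should recover the factor within 10%
  cfg <- tiny_cohort_config(6, 6, seed = 55,
                            effect = effect_profile(time_to_max_factor = 1.5))
  co <- generate_cohort(cfg, keep_trials = FALSE)
  tab <- suppressWarnings(build_feature_table(co))
  h <- tab$group == 0
  ratio <- mean(tab$traj_t2max_left_shoulder_y[!h]) /
    mean(tab$traj_t2max_left_shoulder_y[h])
  expect_equal(ratio, 1.5, tolerance = 0.1)
})

test_that("the planted EMG centroid shift is recovered downstream", {
  cfg <- tiny_cohort_config(6, 6, seed = 56)
  co <- generate_cohort(cfg, keep_trials = FALSE)
  tab <- suppressWarnings(build_feature_table(co))
  h <- tab$group == 0
  shift <- mean(tab$emg_centroid_global_y[!h]) -
    mean(tab$emg_centroid_global_y[h])
  expect_equal(shift, 10, tolerance = 0.1 * 10)
})

test_that("zero ECG amplitude leaves preprocessing nearly idle on that stage", {
  cfg <- tiny_cohort_config(1, 1, seed = 66, n_repetitions = 3L)
  s <- draw_subjects(cfg)[1, ]
  tr <- simulate_trial(s, "back_extension", "preferred",
                       effect_profile(ecg_amplitude = 0),
                       seed = 9, n_repetitions = 3, rep_duration_s = 0.7,
                       gap_s = 0.35, lead_s = 0.5)
  X <- tr$emg$left_lower
  lam <- select_lambda(colMeans(X))
  B <- t(whittaker_baseline(t(X), lam, decimate = 8L))
  Xb <- X - B
  Y <- suppressWarnings(remove_ecg(Xb))
  expect_lt(abs(sqrt(mean(Y^2)) / sqrt(mean(Xb^2)) - 1), 0.01)
})

test_that("cohort write/read round-trips trials exactly", {
  cfg <- tiny_cohort_config(1, 1, seed = 71, movements = "lat_flex_left",
                            speeds = "maximum", n_repetitions = 3L)
  co <- generate_cohort(cfg)
  d <- file.path(tempdir(), "lbp-roundtrip")
  on.exit(unlink(d, recursive = TRUE))
  mf <- write_cohort(co, d)
  # manifest covers n_subjects x movements x speeds trials
  expect_equal(mf$n_trials, 2L * 1L * 1L)
  co2 <- read_cohort(d)
  for (k in names(co$trials)) {
    expect_identical(co$trials[[k]]$emg, co2$trials[[k]]$emg)
    expect_equal(co$trials[[k]]$markers, co2$trials[[k]]$markers,
                 tolerance = 0)
    expect_equal(co$trials[[k]]$plates, co2$trials[[k]]$plates,
                 tolerance = 0)
  }
  expect_equal(co2$subjects$bmi, co$subjects$bmi)

  # corrupting an EMG file raises an error naming the trial
  f <- list.files(file.path(d, co$subjects$id[1]), pattern = "emg_left_lower",
                  full.names = TRUE)[1]
  dt <- data.table::fread(f)
  data.table::fwrite(dt[, 1:10], f)
  expect_error(read_cohort(d), "channels")
  expect_error(read_cohort(tempfile()), "manifest")
})
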