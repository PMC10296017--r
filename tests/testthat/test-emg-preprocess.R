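test_that("baseline-wander removal strips slow drift and keeps fast content", {
  fs <- 2048
  t <- seq_len(4 * fs) / fs
  drift <- 3 * sin(2 * pi * 0.3 * t)
  out <- remove_baseline_wander(drift, lambda = "auto")
  expect_lt(sqrt(mean(out^2)), 0.05 * sqrt(mean(drift^2)))

  expect_equal(remove_baseline_wander(rep(0, 500), lambda = 100), rep(0, 500))

  set.seed(11)
  noise <- as.numeric(stats::filter(rnorm(length(t)), c(1, -0.9),
                                    method = "convolution", sides = 1))
  noise[is.na(noise)] <- 0
  mix <- drift + noise
  cleaned <- remove_baseline_wander(mix, lambda = "auto")
  expect_gt(cor(cleaned, noise), 0.99)

  expect_error(remove_baseline_wander(c(1, NA, 3), lambda = 10), "finite")
})

test_that("L-curve lambda selection is deterministic with sane degenerate cases", {
  expect_equal(select_lambda(rnorm(200), grid = 42), 42)
  set.seed(3)
  x <- sin(2 * pi * 0.4 * seq_len(3000) / 1000) + rnorm(3000, 0, 0.3)
  expect_identical(select_lambda(x), select_lambda(x))
  expect_warning(select_lambda(rep(1, 500)), "flat L-curve")
})

test_that("selected lambda weakly decreases with planted drift amplitude", {
  set.seed(21)
  fs <- 1000
  t <- seq_len(4 * fs) / fs
  noise <- rnorm(length(t), 0, 0.5)
  lams <- vapply(c(0.5, 2, 8, 32), function(a)
    select_lambda(a * sin(2 * pi * 0.4 * t) + noise), numeric(1))
  expect_true(all(diff(log(lams)) <= 1e-9))
})

test_that("ECG template subtraction removes the artifact train", {
  set.seed(2)
  fs <- 2048
  n <- 6 * fs
  ecg <- lbpmotion:::.ecg_train(n, fs)
  gains <- runif(63, 0.5, 1.5)
  art <- outer(gains, ecg)

  out <- remove_ecg(art, fs)
  expect_equal(dim(out), dim(art))
  expect_lt(sqrt(mean(out^2)), 0.10 * sqrt(mean(art^2)))

  emg <- matrix(rnorm(63 * n, 0, 0.5), 63, n)
  mixed <- emg + art
  cleaned <- remove_ecg(mixed, fs)
  xc0 <- abs(sum((mixed - emg) * ecg))
  xc1 <- abs(sum((cleaned - emg) * ecg))
  expect_lt(xc1, 0.2 * xc0)

  # nothing to remove: aperiodic detections leave the signal untouched
  expect_warning(none <- remove_ecg(emg, fs), "unchanged|aperiodic")
  expect_lt(abs(sqrt(mean(none^2)) / sqrt(mean(emg^2)) - 1), 0.01)
})

test_that("outlier filling replaces spikes and only spikes", {
  set.seed(5)
  x <- rnorm(5000)
  spiked <- x; spiked[2500] <- 100 * max(abs(x))
  # k = 5: only the planted spike exceeds the detection band
  filled <- fill_outliers(spiked, window = 201, k = 5)
  expect_lt(abs(filled[2500]), 5)
  expect_identical(filled[-2500], spiked[-2500])

  clean <- rnorm(20000)
  frac <- mean(fill_outliers(clean, window = 2049, k = 3) != clean)
  expect_lt(frac, 0.01)

  expect_identical(fill_outliers(rep(3, 1000), window = 201, k = 3),
                   rep(3, 1000))
  expect_error(fill_outliers(rnorm(100), window = 200, k = 3), "odd")
  expect_error(fill_outliers(rnorm(100), window = 201, k = 3), "longer")
})

test_that("repetition segmentation recovers the planted windows", {
  cfg <- tiny_cohort_config(1, 1, seed = 31, n_repetitions = 10L)
  subs <- draw_subjects(cfg)
  co <- list(subjects = subs, config = cfg)
  for (i in 1:2) {
    tr <- cohort_trial(co, i, "back_extension", "preferred")
    w <- segment_repetitions(tr)
    expect_equal(nrow(w), 10L)
    expect_true(all(w$end_sample > w$start_sample))
    expect_true(all(diff(w$start_sample) > 0))
    # boundary error below 0.25 s against the generator's ground truth
    expect_lt(max(abs(w$start_s - tr$rep_windows_truth$start_s)), 0.25)
    expect_lt(max(abs(w$end_s - tr$rep_windows_truth$end_s)), 0.25)
  }
})

test_that("stationary plate signals raise a segmentation error", {
  set.seed(13)
  tr <- list(plates = data.frame(gfr_left = rnorm(8000, 350, 5),
                                 gfr_right = rnorm(8000, 350, 5)))
  expect_error(segment_repetitions(tr), class = "segmentation_error")
})

test_that("repetition resampling preserves endpoints and tensor shape", {
  expect_equal(resample_repetition(rep(2.5, 7), 6000), rep(2.5, 6000))
  ramp <- resample_repetition(seq(0, 1, length.out = 50), 6000)
  expect_equal(ramp[1], 0)
  expect_equal(ramp[6000], 1)
  expect_error(resample_repetition(matrix(1, 3, 1)), "at least 2")

  lays <- back_grid_set()
  grids <- lapply(lays, function(l) matrix(rnorm(63 * 40), 63, 40))
  res <- lapply(grids, resample_repetition, n_out = 6000L)
  tensor <- stack_grids(res, lays)
  expect_equal(dim(tensor), c(26L, 10L, 6000L))
  # unpopulated corner (1,1) stays zero; first channel sits at (1,2)
  expect_true(all(tensor[1, 1, ] == 0))
  expect_equal(tensor[1, 2, ], res$left_lower[1, ])
  expect_true(all(tensor[14, 6, ] == 0))      # right_upper corner (1,1)
  expect_equal(tensor[14, 7, ], res$right_upper[1, ])
  expect_error(stack_grids(lapply(res, function(m) m[1:10, ]), lays),
               "mismatch")
})

test_that("filters are length-preserving and near-idempotent", {
  set.seed(17)
  fs <- 2048
  n <- 5 * fs
  x <- rnorm(n) + 2 * sin(2 * pi * 0.4 * seq_len(n) / fs)
  once <- remove_baseline_wander(x, lambda = 1e8)
  twice <- remove_baseline_wander(once, lambda = 1e8)
  expect_equal(length(once), n)
  expect_lt(abs(sqrt(mean(twice^2)) / sqrt(mean(once^2)) - 1), 0.01)

  y <- fill_outliers(x, window = 513, k = 3)
  y2 <- fill_outliers(y, window = 513, k = 3)
  expect_lt(abs(sqrt(mean(y2^2)) / sqrt(mean(y^2)) - 1), 0.01)
})
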