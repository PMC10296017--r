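test_that("trajectory resampling preserves endpoints and waveforms", {
  expect_equal(resample_trajectory(rep(1.3, 7)), rep(1.3, 100))
  r <- resample_trajectory(c(0, 1))
  expect_equal(r[1], 0); expect_equal(r[100], 1)
  t <- seq(0, 1, by = 1 / 120)
  s <- sin(2 * pi * 2 * t)
  r100 <- resample_trajectory(s)
  back <- approx(seq(0, 1, length.out = 100), r100, xout = t)$y
  expect_lt(max(abs(back - s)), 1e-2)
  expect_error(resample_trajectory(1), "at least 2")
})

test_that("maximum amplitude and time-to-max follow their contracts", {
  expect_equal(max_amplitude(rep(5, 50), 170), 0)
  # ramp 0 -> 0.5 m at height 180 cm: 0.5 / 1.8
  expect_equal(max_amplitude(seq(0, 0.5, length.out = 60), 180), 0.5 / 1.8)
  set.seed(4)
  for (i in 1:50) {
    x <- rnorm(40)
    expect_equal(max_amplitude(x, 100), max(abs(x - x[1])), tolerance = 1e-12)
  }
  expect_error(max_amplitude(1:3, 0), "positive")

  x <- c(rep(0, 60), 1, rep(0, 39))
  expect_equal(time_to_max(x), 0.5)
  ramp <- seq(0, 1, length.out = 120)
  expect_equal(time_to_max(ramp), 119 / 120)
  tie <- rep(0, 120); tie[c(31, 91)] <- 2
  expect_equal(time_to_max(tie), 0.25)
})

test_that("sample entropy matches the brute-force template count", {
  expect_equal(trajectory_sample_entropy(rep(2, 30), r = 0.5), 0)
  # strictly periodic series: highly predictable, near zero
  per <- rep(c(0, 1, 0.5, -1), 50)
  expect_lt(trajectory_sample_entropy(per), 0.05)
  set.seed(12)
  for (i in 1:30) {
    x <- rnorm(30)
    expect_equal(trajectory_sample_entropy(x),
                 oracle_sampen(x), tolerance = 1e-12)
    x2 <- cumsum(rnorm(45))
    expect_equal(trajectory_sample_entropy(x2, m = 3L),
                 oracle_sampen(x2, m = 3L, r = 0.2 * sd(x2)),
                 tolerance = 1e-12)
  }
  expect_error(trajectory_sample_entropy(1:3), "too short")
})

test_that("sample entropy drops when jitter is smoothed away", {
  set.seed(8)
  t <- seq(0, 2, by = 1 / 120)
  base <- sin(pi * t / 2)
  rough <- base + 0.05 * rnorm(length(t))
  smooth <- base + 0.05 * as.numeric(stats::filter(rnorm(length(t)),
                                                   rep(1 / 15, 15),
                                                   circular = TRUE))
  expect_gt(trajectory_sample_entropy(rough),
            trajectory_sample_entropy(smooth))
})

test_that("relative axis angles agree with a quaternion oracle", {
  # identical orientations -> zero angle
  n <- 10
  Ra <- array(rep(diag(3), n), c(3, 3, n))
  expect_equal(max(abs(relative_axis_angle(Ra, Ra, "z"))), 0)

  set.seed(9)
  for (i in 1:25) {
    theta <- runif(1, -170, 170) * pi / 180
    q <- quat_from_axis_angle(c(0, 0, 1), theta)
    base <- quat_from_axis_angle(runif(3), runif(1, -1, 1))
    Ra <- array(quat_to_rotmat(base), c(3, 3, 1))
    Rb <- array(quat_to_rotmat(base) %*% quat_to_rotmat(q), c(3, 3, 1))
    ang <- relative_axis_angle(Ra, Rb, "z")
    # pure z-rotation composed after the common base orientation
    expect_equal(ang, theta * 180 / pi, tolerance = 1e-6)
  }
})

test_that("max-angle features find planted rotation peaks", {
  flat <- max_angle_features(rep(0, 240))
  expect_equal(flat$max_angle, 0)
  expect_equal(flat$time_to_max_angle, 0)
  ang <- c(seq(0, 45, length.out = 121), seq(45, 0, length.out = 119)[-1])
  mf <- max_angle_features(ang, fs = 120)
  expect_equal(mf$max_angle, 45)
  expect_equal(mf$time_to_max_angle, 1.0)
})

test_that("shoulder-line angle recovers a planted trunk rotation", {
  n <- 240
  theta <- 40 * pi / 180 * sin(pi * (seq_len(n) - 1) / n)^2
  left <- cbind(-0.2 * cos(theta), -0.2 * sin(theta), 1.4)
  right <- cbind(0.2 * cos(theta), 0.2 * sin(theta), 1.4)
  ang <- shoulder_angle_z(left, right)
  expect_equal(max(abs(ang)), 40, tolerance = 1e-6)
})

test_that("inter-subject variation equals direct RMSE formulas", {
  hm <- rep(0.3, 100)
  reps <- matrix(0.3, 4, 100)
  expect_equal(inter_subject_variation(reps, hm, 175), 0)
  # constant offset d at height h gives d / h
  expect_equal(inter_subject_variation(reps + 0.05, hm, 175),
               0.05 / 1.75, tolerance = 1e-12)
  set.seed(14)
  for (i in 1:30) {
    r <- matrix(rnorm(300), 3, 100)
    hm <- rnorm(100)
    man <- mean(apply(r, 1, oracle_rmse, b = hm)) / 1.8
    expect_equal(inter_subject_variation(r, hm, 180), man, tolerance = 1e-12)
  }
  expect_error(inter_subject_variation(reps, numeric(0), 170), "empty")
})

test_that("intra-subject variation is a leave-one-out RMSE", {
  reps <- matrix(1.2, 5, 100)
  expect_equal(intra_subject_variation(reps, 160), 0)
  # two reps differing by d: each LOO reference is the other
  two <- rbind(rep(0, 100), rep(0.08, 100))
  expect_equal(intra_subject_variation(two, 160), 0.08 / 1.6,
               tolerance = 1e-12)
  set.seed(15)
  for (i in 1:20) {
    r <- matrix(rnorm(500), 5, 100)
    loo <- vapply(1:5, function(k)
      oracle_rmse(r[k, ], colMeans(r[-k, , drop = FALSE])), numeric(1))
    expect_equal(intra_subject_variation(r, 170), mean(loo) / 1.7,
                 tolerance = 1e-12)
  }
  expect_error(intra_subject_variation(matrix(1, 1, 100), 170),
               "2 repetitions")
})

test_that("amplitude and timing features ignore the absolute offset", {
  set.seed(16)
  x <- cumsum(rnorm(200))
  expect_equal(max_amplitude(x + 5, 170), max_amplitude(x, 170))
  expect_equal(time_to_max(x + 5), time_to_max(x))
  expect_equal(trajectory_sample_entropy(x + 5),
               trajectory_sample_entropy(x), tolerance = 1e-12)
})
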