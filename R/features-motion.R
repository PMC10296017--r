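#' Resample a trajectory to a fixed length
#'
#' Linear interpolation to `n` samples, preserving endpoints exactly.
#' @param traj numeric position series (one repetition), >= 2 samples.
#' @param n output length.
#' @return numeric vector of length `n`.
#' @export
resample_trajectory <- function(traj, n = 100L) {
  if (length(traj) < 2L) stop("trajectory must have at least 2 samples")
  stats::approx(seq_along(traj), traj,
                xout = seq(1, length(traj), length.out = n))$y
}

#' Maximum movement amplitude, height-normalized
#'
#' Maximum absolute excursion from the first-frame position, divided by
#' subject height (metres / metres, dimensionless). Per-movement values
#' are the caller's mean over repetitions.
#'
#' @param traj position series in metres.
#' @param height_cm subject height in centimetres (> 0); `NULL` skips
#'   normalization and returns metres.
#' @return scalar amplitude.
#' @export
max_amplitude <- function(traj, height_cm = NULL) {
  a <- max(abs(traj - traj[1]))
  if (is.null(height_cm)) return(a)
  if (height_cm <= 0) stop("height must be positive")
  a / (height_cm / 100)
}

#' Time to maximum amplitude
#'
#' Time (s) at which the excursion from the first frame is maximal;
#' earliest sample on ties.
#' @param traj position series.
#' @param fs sampling rate, Hz.
#' @return seconds (>= 0).
#' @export
time_to_max <- function(traj, fs = 120) {
  (which.max(abs(traj - traj[1])) - 1L) / fs
}

#' Sample entropy of a trajectory
#'
#' `SampEn(m, r) = -log(A / B)` where `B` counts pairs of length-`m`
#' templates within Chebyshev distance `< r` and `A` the pairs still
#' matching at length `m + 1`; self-matches excluded. `r` defaults to
#' `0.2 * sd(traj)`. A constant series (sd 0) returns 0 by convention;
#' if no length-`m + 1` matches exist the value is `NA` (recorded as
#' missing by callers).
#'
#' @param traj numeric series, length >= m + 2.
#' @param m template length.
#' @param r tolerance; `NULL` for `0.2 * sd(traj)`.
#' @return scalar entropy (nats), `NA` if undefined.
#' @export
trajectory_sample_entropy <- function(traj, m = 2L, r = NULL) {
  n <- length(traj)
  if (n < m + 2L) stop("series too short for sample entropy")
  s <- stats::sd(traj)
  if (is.null(r)) {
    if (s == 0) return(0)
    r <- 0.2 * s
  }
  if (s == 0) return(0)
  # vectorized template matching on the pairwise Chebyshev distance
  nb <- n - m            # number of length-m templates (use first n-m, so
                         # every one extends to length m+1)
  d <- abs(outer(traj, traj, `-`))
  cheb <- d[seq_len(nb), seq_len(nb)]
  for (k in seq_len(m - 1)) {
    idx <- seq_len(nb) + k
    cheb <- pmax(cheb, d[idx, idx])
  }
  Bm <- (cheb < r)
  idx <- seq_len(nb) + m
  Am <- Bm & (d[idx, idx] < r)
  B <- (sum(Bm) - nb) / 2   # exclude self-matches
  A <- (sum(Am) - nb) / 2
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

#' Relative rotation angle between two orientation series
#'
#' For paired series of rotation matrices, returns the time series of the
#' relative rotation's twist angle about a chosen axis (twist-swing
#' decomposition), in degrees.
#'
#' @param Ra,Rb arrays `3 x 3 x n` of rotation matrices (world-to-segment).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return numeric vector of signed angles (degrees).
#' @export
relative_axis_angle <- function(Ra, Rb, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  if (!identical(dim(Ra)[1:2], c(3L, 3L)) || !identical(dim(Ra), dim(Rb)))
    stop("Ra and Rb must be matching 3 x 3 x n arrays")
  ax <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  n <- dim(Ra)[3]
  out <- numeric(n)
  for (i in seq_len(n)) {
    R <- t(Ra[, , i]) %*% Rb[, , i]
    if (abs(det(R) - 1) > 1e-6) stop("degenerate orientation at frame ", i)
    # twist about ax: project the relative quaternion onto the axis
    qw <- sqrt(max(0, 1 + R[1, 1] + R[2, 2] + R[3, 3])) / 2
    qv <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (4 * max(qw, 1e-12))
    p <- sum(qv * ax)
    out[i] <- 2 * atan2(p, qw) * 180 / pi
  }
  out
}

#' Maximum angle and time to maximum angle
#'
#' From a relative-angle series (degrees), the maximum absolute angle
#' reached and the time at which it is reached (earliest sample on ties).
#' Rotation movements use the shoulder-line angle about the vertical axis
#' (see [shoulder_angle_z()]).
#'
#' @param angle_deg angle series relative to the starting frame, degrees.
#' @param fs sampling rate, Hz.
#' @return list `max_angle` (deg), `time_to_max_angle` (s).
#' @export
max_angle_features <- function(angle_deg, fs = 120) {
  a <- abs(angle_deg - angle_deg[1])
  i <- which.max(a)
  list(max_angle = a[i], time_to_max_angle = (i - 1L) / fs)
}

#' Shoulder-line angle about the vertical axis
#'
#' Planar angle (degrees) of the left-to-right shoulder line in the
#' horizontal plane, relative to the first frame: the trunk-rotation angle
#' proxy used for rotation movements.
#'
#' @param left,right matrices `n x 3` (columns X, Y, Z) of shoulder marker
#'   positions.
#' @return numeric vector of signed angles, degrees, first value 0.
#' @export
shoulder_angle_z <- function(left, right) {
  v <- right - left
  ang <- atan2(v[, 2], v[, 1]) * 180 / pi
  ang <- ang - ang[1]
  # unwrap to avoid 360-degree jumps
  (ang + 180) %% 360 - 180
}

#' Inter-subject trajectory variation
#'
#' Height-normalized RMSE of each repetition (resampled to 100 samples)
#' against the healthy-group mean trajectory, averaged over repetitions.
#'
#' @param reps list of repetition position series (metres) or matrix with
#'   one resampled repetition per row.
#' @param healthy_mean reference 100-sample mean healthy trajectory.
#' @param height_cm subject height (cm).
#' @return scalar (dimensionless).
#' @export
inter_subject_variation <- function(reps, healthy_mean, height_cm) {
  if (length(healthy_mean) == 0 || all(is.na(healthy_mean)))
    stop("empty healthy reference")
  if (is.matrix(reps)) reps <- asplit(reps, 1)
  n <- length(healthy_mean)
  e <- vapply(reps, function(r) {
    r100 <- if (length(r) == n) as.numeric(r) else resample_trajectory(r, n)
    sqrt(mean((r100 - healthy_mean)^2))
  }, numeric(1))
  mean(e) / (height_cm / 100)
}

#' Intra-subject trajectory variation
#'
#' For each repetition, the RMSE against the mean of the subject's other
#' repetitions (leave-one-out), height-normalized and averaged.
#'
#' @inheritParams inter_subject_variation
#' @return scalar (dimensionless).
#' @export
intra_subject_variation <- function(reps, height_cm) {
  if (is.matrix(reps)) reps <- asplit(reps, 1)
  k <- length(reps)
  if (k < 2L) stop("at least 2 repetitions required")
  R <- t(vapply(reps, function(r)
    if (length(r) == 100L) as.numeric(r) else resample_trajectory(r, 100L),
    numeric(100L)))
  tot <- colSums(R)
  e <- vapply(seq_len(k), function(i) {
    loo <- (tot - R[i, ]) / (k - 1)
    sqrt(mean((R[i, ] - loo)^2))
  }, numeric(1))
  mean(e) / (height_cm / 100)
}
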