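# Independent brute-force oracles used to freeze expected values.
# These deliberately use plain loops / direct formulas, never the package's
# own implementation path.

oracle_centroid <- function(map) {
  lay <- map$layout
  sx <- sy <- tot <- 0
  # accumulate in the package's row-major channel order
  pos <- which(t(lay$populated), arr.ind = TRUE)
  for (i in seq_len(nrow(pos))) {
    cc <- unname(pos[i, 1L]); r <- unname(pos[i, 2L])
    w <- map$values[i]
    sx <- sx + w * cc; sy <- sy + w * r; tot <- tot + w
  }
  list(x = sx / tot, y = sy / tot)
}

oracle_entropy <- function(map) {
  n2 <- map$values^2
  p <- n2 / sum(n2)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  h
}

# O(N^2) direct template-counting sample entropy
oracle_sampen <- function(x, m = 2L, r = 0.2 * sd(x)) {
  n <- length(x)
  nb <- n - m
  A <- B <- 0L
  for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
    dm <- max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
    if (dm < r) {
      B <- B + 1L
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) < r) A <- A + 1L
    }
  }
  if (B == 0L || A == 0L) return(NA_real_)
  -log(A / B)
}

oracle_rmse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / length(a))
}

oracle_gfr_ratio <- function(left, right) {
  s <- 0; k <- 0L
  for (i in seq_along(left)) if (right[i] > 0) {
    s <- s + left[i] / right[i]; k <- k + 1L
  }
  s / k
}

# quaternion utilities for the rotation-angle oracle
quat_from_axis_angle <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(theta / 2), sin(theta / 2) * axis)
}
quat_mul <- function(q, p) {
  c(q[1] * p[1] - sum(q[2:4] * p[2:4]),
    q[1] * p[2:4] + p[1] * q[2:4] + c(
      q[3] * p[4] - q[4] * p[3],
      q[4] * p[2] - q[2] * p[4],
      q[2] * p[3] - q[3] * p[2]))
}
quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# small fast cohort settings shared by integration-style tests
tiny_cohort_config <- function(n_healthy, n_nslbp, seed,
                               movements = "back_extension",
                               speeds = "preferred", effect = effect_profile(),
                               n_repetitions = 4L) {
  cohort_config(n_healthy, n_nslbp, effect = effect, seed = seed,
                movements = movements, speeds = speeds,
                n_repetitions = n_repetitions,
                rep_duration_s = 0.7, gap_s = 0.35, lead_s = 0.5)
}

# planted-effect profile used for the classification sanity experiments:
# every variable family carries a wide group separation
separated_effect_profile <- function() {
  effect_profile(time_to_max_factor = 2, traj_entropy_factor = 0.3,
                 emg_centroid_shift_mm = 25, gfr_equalization = 0.95,
                 emg_focus_factor = 0.5, statok_factor = 2.5,
                 age_shift_y = 20, bmi_shift = 10)
}
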