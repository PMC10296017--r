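#' Planted group-effect profile
#'
#' Describes how the NSLBP group differs from the healthy group in a
#' synthetic cohort. Directions follow the exploratory findings this
#' package is built around: NSLBP subjects take longer to reach peak
#' excursion, move with less trajectory jitter (lower sample entropy),
#' show more cranially distributed low-back EMG activity, distribute load
#' more equally between feet, sway more, and skew older and heavier.
#' With the all-null profile ([null_effect_profile()]) the two groups are
#' exchangeable in distribution.
#'
#' @param time_to_max_factor multiplier on the NSLBP repetition duration
#'   (> 1 = slower movement, proportionally later peak).
#' @param traj_entropy_factor multiplier on trajectory jitter amplitude for
#'   NSLBP (< 1 = smoother/more rigid movement, lower sample entropy).
#' @param emg_centroid_shift_mm cranial (positive-y) shift of the NSLBP EMG
#'   activity center in the common back frame, millimetres.
#' @param gfr_equalization in `[0, 1]`: fraction by which the healthy
#'   left/right load asymmetry is removed in NSLBP (1 = perfectly equal).
#' @param emg_focus_factor multiplier on the NSLBP spatial envelope width
#'   (< 1 = more focal activity, lower grid entropy).
#' @param statok_factor multiplier on the NSLBP antero-posterior sway
#'   amplitude (sway anisotropy; the normalized statokinesigram is
#'   scale-invariant, so only shape changes are visible in it).
#' @param age_shift_y,bmi_shift,height_shift_cm additive shifts of the
#'   NSLBP metadata means relative to the healthy distributions.
#' @param marker_noise_m,emg_noise,ecg_amplitude,wander_amplitude
#'   noise scales (all must be >= 0): trajectory jitter (m, healthy),
#'   EMG stochastic texture (a.u.), planted ECG artifact amplitude and
#'   baseline-wander amplitude relative to EMG scale.
#' @return an `effect_profile` object.
#' @export
effect_profile <- function(time_to_max_factor = 1.4,
                           traj_entropy_factor = 0.6,
                           emg_centroid_shift_mm = 10,
                           gfr_equalization = 0.7,
                           emg_focus_factor = 0.85,
                           statok_factor = 1.3,
                           age_shift_y = 2.2,
                           bmi_shift = 2.5,
                           height_shift_cm = 0.5,
                           marker_noise_m = 0.004,
                           emg_noise = 1,
                           ecg_amplitude = 0.4,
                           wander_amplitude = 1.5) {
  p <- list(time_to_max_factor = time_to_max_factor,
            traj_entropy_factor = traj_entropy_factor,
            emg_centroid_shift_mm = emg_centroid_shift_mm,
            gfr_equalization = gfr_equalization,
            emg_focus_factor = emg_focus_factor,
            statok_factor = statok_factor,
            age_shift_y = age_shift_y,
            bmi_shift = bmi_shift,
            height_shift_cm = height_shift_cm,
            marker_noise_m = marker_noise_m,
            emg_noise = emg_noise,
            ecg_amplitude = ecg_amplitude,
            wander_amplitude = wander_amplitude)
  scales <- c("marker_noise_m", "emg_noise", "ecg_amplitude", "wander_amplitude")
  if (any(unlist(p[scales]) < 0)) stop("noise scales must be >= 0")
  if (gfr_equalization < 0 || gfr_equalization > 1)
    stop("gfr_equalization must lie in [0, 1]")
  structure(p, class = "effect_profile")
}

#' Null (no-group-difference) effect profile
#'
#' All factors 1, all shifts 0: the two groups are exchangeable in
#' distribution, so every downstream feature's group difference is
#' centered at zero.
#' @param ... noise-scale overrides passed to [effect_profile()].
#' @return an `effect_profile`.
#' @export
null_effect_profile <- function(...) {
  effect_profile(time_to_max_factor = 1, traj_entropy_factor = 1,
                 emg_centroid_shift_mm = 0, gfr_equalization = 0,
                 emg_focus_factor = 1, statok_factor = 1, age_shift_y = 0,
                 bmi_shift = 0, height_shift_cm = 0, ...)
}

#' Movement and speed enumerations
#' @export
movement_levels <- function() c("back_extension", "back_flexion",
                                "lat_flex_left", "lat_flex_right",
                                "rot_left", "rot_right")

#' @rdname movement_levels
#' @export
speed_levels <- function() c("preferred", "maximum")

#' Cohort generation configuration
#'
#' Metadata distributions default to the study population this package
#' emulates: healthy age 29.6 +/- 9.1 y, height 172.5 +/- 8 cm, BMI
#' 23.1 +/- 3; the NSLBP means are the healthy means plus the effect
#' profile's shifts (defaults land at age 31.8, BMI 25.6, height 173).
#' Weight is derived from BMI and height so `bmi = weight / (height/100)^2`
#' holds exactly.
#'
#' @param n_healthy,n_nslbp subjects per group (>= 1).
#' @param effect an [effect_profile()].
#' @param seed integer master seed.
#' @param movements,speeds subsets of [movement_levels()] /
#'   [speed_levels()] to generate trials for.
#' @param n_repetitions repetitions per trial.
#' @param age_mean,age_sd,height_mean,height_sd,bmi_mean,bmi_sd healthy
#'   metadata Gaussians (sd shared by both groups).
#' @param rep_duration_s,gap_s,lead_s repetition timing at preferred speed
#'   (maximum-speed repetitions are half as long), quiet gap between
#'   repetitions and lead-in/out, seconds.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_healthy, n_nslbp, effect = effect_profile(),
                          seed = 1L,
                          movements = movement_levels(),
                          speeds = speed_levels(),
                          n_repetitions = 10L,
                          age_mean = 29.6, age_sd = 9.1,
                          height_mean = 172.5, height_sd = 8,
                          bmi_mean = 23.1, bmi_sd = 3,
                          rep_duration_s = 2.0, gap_s = 1.0, lead_s = 1.0) {
  if (n_healthy < 1 || n_nslbp < 1) stop("group sizes must be >= 1")
  if (any(c(age_sd, height_sd, bmi_sd) < 0)) stop("negative variance rejected")
  movements <- match.arg(movements, movement_levels(), several.ok = TRUE)
  speeds <- match.arg(speeds, speed_levels(), several.ok = TRUE)
  structure(list(n_healthy = as.integer(n_healthy),
                 n_nslbp = as.integer(n_nslbp),
                 effect = effect, seed = as.integer(seed),
                 movements = movements, speeds = speeds,
                 n_repetitions = as.integer(n_repetitions),
                 age_mean = age_mean, age_sd = age_sd,
                 height_mean = height_mean, height_sd = height_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 rep_duration_s = rep_duration_s, gap_s = gap_s,
                 lead_s = lead_s),
            class = "cohort_config")
}

#' Draw subject metadata for a cohort
#'
#' @param config a [cohort_config()].
#' @return data.frame with `id`, `group` (Healthy = 0, NSLBP = 1), `sex`
#'   (Male = 0, Female = 1), `age` (y), `height` (cm), `weight` (kg),
#'   `bmi` (kg/m^2).
#' @export
draw_subjects <- function(config) {
  ef <- config$effect
  if (config$n_healthy < 1L || config$n_nslbp < 1L)
    stop("group sizes must be >= 1")
  n <- config$n_healthy + config$n_nslbp
  group <- c(rep(0L, config$n_healthy), rep(1L, config$n_nslbp))
  set.seed(config$seed)
  sex <- sample(0:1, n, replace = TRUE)
  age <- pmax(18, rnorm(n, config$age_mean + ef$age_shift_y * group, config$age_sd))
  height <- rnorm(n, config$height_mean + ef$height_shift_cm * group, config$height_sd)
  bmi <- pmax(15, rnorm(n, config$bmi_mean + ef$bmi_shift * group, config$bmi_sd))
  weight <- bmi * (height / 100)^2
  data.frame(id = sprintf("S%03d", seq_len(n)), group = group, sex = sex,
             age = age, height = height, weight = weight, bmi = bmi,
             stringsAsFactors = FALSE)
}

# deterministic per-trial seed below 2^31
.trial_seed <- function(seed, subj_idx, movement, speed) {
  m <- match(movement, movement_levels())
  s <- match(speed, speed_levels())
  as.integer((as.double(seed) * 7919 + subj_idx * 1009 + m * 101 + s * 17) %%
               2147483563)
}

# asymmetric raised-cosine pulse: 0 -> 1 at peak_frac -> 0 over n samples
.rep_pulse <- function(n, peak_frac) {
  tp <- max(2L, min(n - 1L, round(peak_frac * n)))
  up <- 0.5 - 0.5 * cos(pi * seq_len(tp) / tp)
  down <- 0.5 + 0.5 * cos(pi * seq_len(n - tp) / (n - tp))
  c(up, down)
}

# trapezoid gate with raised-cosine edges over ramp samples: crisp on/off
.rep_gate <- function(n, ramp) {
  ramp <- max(2L, min(ramp, n %/% 3L))
  up <- 0.5 - 0.5 * cos(pi * seq_len(ramp) / ramp)
  c(up, rep(1, n - 2L * ramp), rev(up))
}

# smooth (low-pass) noise: moving-average filtered white noise, unit sd
.smooth_noise <- function(n, span) {
  x <- rnorm(n + span)
  y <- stats::filter(x, rep(1 / span, span), sides = 1)
  y <- y[(span + 1):(span + n)]
  as.numeric(y) / sd(y)
}

#' Simulate one trial of one subject
#'
#' Produces a full multimodal recording: four HD-EMG grids (2048 Hz) with a
#' spatially smooth activity envelope (group-shifted cranially for NSLBP),
#' band-limited stochastic texture, a planted ECG train (~1.2 Hz) and
#' low-frequency baseline wander; marker trajectories (120 Hz) for the
#' shoulders, hips, T6 and C7 with smooth repetition waveforms (amplitude
#' scaled by subject height; NSLBP: later peak, less jitter); and dual
#' force-plate series (1000 Hz) with a configured left/right load ratio,
#' stabilized (low-variance) gaps between repetitions, and a
#' centre-of-pressure random walk.
#'
#' @param subject one row of [draw_subjects()] output.
#' @param movement one of [movement_levels()].
#' @param speed one of [speed_levels()].
#' @param effect an [effect_profile()].
#' @param seed integer seed; the same subject/seed always yields a
#'   bit-identical trial.
#' @param n_repetitions repetitions embedded in the trial.
#' @param rep_duration_s,gap_s,lead_s timing at preferred speed, seconds.
#' @param uniform_activity if TRUE the EMG spatial envelope is flat
#'   (constant-activity request), giving a uniform RMS map up to noise.
#' @param layouts four-grid layout set.
#' @return a `trial` list with elements `subject_id`, `movement`, `speed`,
#'   `emg` (list of four channels x time matrices), `layouts`, `markers`
#'   (data.frame, `<marker>_{X,Y,Z}` columns), `plates` (data.frame
#'   `t, gfr_left, gfr_right, cop_x, cop_y`), `rep_windows_truth`
#'   (data.frame `start_s`, `end_s`) and sampling rates.
#' @export
simulate_trial <- function(subject, movement, speed,
                           effect = effect_profile(), seed = 1L,
                           n_repetitions = 10L,
                           rep_duration_s = 2.0, gap_s = 1.0, lead_s = 1.0,
                           uniform_activity = FALSE,
                           layouts = back_grid_set()) {
  movement <- match.arg(movement, movement_levels())
  speed <- match.arg(speed, speed_levels())
  g <- subject$group
  if (!g %in% c(0L, 1L)) stop("subject$group must be 0 (Healthy) or 1 (NSLBP)")
  set.seed(seed)

  fs_emg <- 2048; fs_mrk <- 120; fs_plate <- 1000
  rep_s <- if (speed == "maximum") rep_duration_s / 2 else rep_duration_s
  if (g == 1L) rep_s <- rep_s * effect$time_to_max_factor
  n_rep <- as.integer(n_repetitions)
  total_s <- lead_s + n_rep * rep_s + (n_rep + 1) * gap_s
  # ground-truth movement intervals (seconds)
  starts <- lead_s + gap_s + (seq_len(n_rep) - 1) * (rep_s + gap_s)
  truth <- data.frame(start_s = starts, end_s = starts + rep_s)

  # ---- activity profile on an arbitrary clock -------------------------
  peak_frac <- 0.45
  profile_at <- function(fs, shape = c("pulse", "gate")) {
    shape <- match.arg(shape)
    n <- round(total_s * fs)
    a <- numeric(n)
    for (k in seq_len(n_rep)) {
      i0 <- round(truth$start_s[k] * fs) + 1L
      i1 <- round(truth$end_s[k] * fs)
      a[i0:i1] <- if (shape == "pulse") .rep_pulse(i1 - i0 + 1L, peak_frac)
                  else .rep_gate(i1 - i0 + 1L, round(0.08 * fs))
    }
    a
  }

  # ---- markers @120 Hz -------------------------------------------------
  n_m <- round(total_s * fs_mrk)
  height_m <- subject$height / 100
  jit <- effect$marker_noise_m * if (g == 1L) effect$traj_entropy_factor else 1
  prof_m <- profile_at(fs_mrk)
  markers <- c("left_shoulder", "right_shoulder", "hips", "t6", "c7")
  # base standing positions (m): x lateral, y antero-posterior, z vertical
  base <- list(left_shoulder = c(-0.20, 0, 0.82) * height_m,
               right_shoulder = c(0.20, 0, 0.82) * height_m,
               hips = c(0, 0, 0.53) * height_m,
               t6 = c(0, -0.02, 0.70) * height_m,
               c7 = c(0, -0.03, 0.85) * height_m)
  # movement displacement amplitudes (fraction of height) per marker/axis
  amp_shoulder <- switch(movement,
    back_extension = c(0.02, 0.18, -0.04),
    back_flexion   = c(0.02, 0.22, -0.25),
    lat_flex_left  = c(-0.20, 0.02, -0.12),
    lat_flex_right = c(0.20, 0.02, -0.12),
    rot_left       = c(0.0, 0.0, 0.0),   # rotation handled separately
    rot_right      = c(0.0, 0.0, 0.0))
  rot_max_deg <- switch(movement, rot_left = 45, rot_right = -45, 0)
  out <- data.frame(t = (seq_len(n_m) - 1) / fs_mrk)
  theta <- rot_max_deg * pi / 180 * prof_m
  for (mk in markers) {
    scale <- switch(mk, left_shoulder = 1, right_shoulder = 1,
                    hips = 0.15, t6 = 0.6, c7 = 0.9)
    b <- base[[mk]]
    if (grepl("rot", movement)) {
      # rotate shoulder line about the vertical axis through the hips
      r <- sqrt(b[1]^2 + b[2]^2)
      phi0 <- atan2(b[2], b[1])
      x <- r * cos(phi0 + theta * scale)
      y <- r * sin(phi0 + theta * scale)
      z <- rep(b[3], n_m)
    } else {
      x <- b[1] + amp_shoulder[1] * height_m * scale * prof_m
      y <- b[2] + amp_shoulder[2] * height_m * scale * prof_m
      z <- b[3] + amp_shoulder[3] * height_m * scale * prof_m
    }
    span <- max(3L, round(fs_mrk / 12))   # ~10 Hz jitter band
    out[[paste0(mk, "_X")]] <- x + jit * .smooth_noise(n_m, span)
    out[[paste0(mk, "_Y")]] <- y + jit * .smooth_noise(n_m, span)
    out[[paste0(mk, "_Z")]] <- z + jit * .smooth_noise(n_m, span)
  }

  # ---- force plates @1000 Hz ------------------------------------------
  n_p <- round(total_s * fs_plate)
  W <- subject$weight * 9.81
  base_log_ratio <- 0.20   # healthy left/right asymmetry, log scale
  lr <- base_log_ratio * (if (g == 1L) 1 - effect$gfr_equalization else 1) +
    rnorm(1, 0, 0.03)
  r <- exp(lr)
  prof_p <- profile_at(fs_plate, "gate")
  sway_y <- if (g == 1L) effect$statok_factor else 1
  # load dynamics during movement: an antisymmetric part (weight shifting
  # between feet) plus a common-mode part (vertical acceleration of the
  # trunk, which survives in the total force whatever the left/right
  # ratio); two bands so the variance never collapses transiently
  osc <- 0.8 * .smooth_noise(n_p, round(fs_plate / 5)) +
    0.6 * .smooth_noise(n_p, round(fs_plate / 25))
  osc_c <- 0.8 * .smooth_noise(n_p, round(fs_plate / 5)) +
    0.6 * .smooth_noise(n_p, round(fs_plate / 25))
  quiet_noise <- rnorm(n_p, 0, 0.15)
  dyn <- 0.06 * W * prof_p * osc
  dyn_c <- 0.05 * W * prof_p * osc_c
  left <- W * r / (1 + r) + (dyn + dyn_c) * r / (1 + r) + quiet_noise
  right <- W / (1 + r) + (dyn_c - dyn) / (1 + r) + rnorm(n_p, 0, 0.15)
  ar <- 0.995
  cop_x <- as.numeric(stats::filter(rnorm(n_p, 0, 1.5 * (0.2 + prof_p)),
                                    ar, method = "recursive"))
  cop_y <- as.numeric(stats::filter(rnorm(n_p, 0, 1.5 * sway_y * (0.2 + prof_p)),
                                    ar, method = "recursive"))
  plates <- data.frame(t = (seq_len(n_p) - 1) / fs_plate,
                       gfr_left = left, gfr_right = right,
                       cop_x = cop_x, cop_y = cop_y)

  # ---- HD EMG @2048 Hz -------------------------------------------------
  n_e <- round(total_s * fs_emg)
  prof_e <- 0.25 + 0.75 * profile_at(fs_emg)
  # activity center in the common back frame (mm): low and slightly left;
  # NSLBP shifted cranially. The envelope-center displacement is solved so
  # that the RMS-weighted global centroid moves by exactly the requested
  # millimetres despite the grid's finite extent.
  yc0 <- -58; xc <- -10; sig_mm <- 55
  if (g == 1L) sig_mm <- sig_mm * effect$emg_focus_factor
  yc <- yc0
  if (g == 1L && !uniform_activity && effect$emg_centroid_shift_mm != 0)
    yc <- yc0 + .envelope_delta(layouts, xc, yc0, sig_mm,
                                effect$emg_centroid_shift_mm,
                                sig0 = 55)
  ecg <- .ecg_train(n_e, fs_emg, rate_hz = 1.2) * effect$ecg_amplitude
  emg <- vector("list", length(layouts)); names(emg) <- names(layouts)
  for (id in names(layouts)) {
    lay <- layouts[[id]]
    pos <- electrode_positions(lay, "mm")
    env <- if (uniform_activity) rep(1, nrow(pos)) else
      0.15 + exp(-((pos$x - xc)^2 + (pos$y - yc)^2) / (2 * sig_mm^2))
    noise <- matrix(rnorm(nrow(pos) * n_e), nrow(pos), n_e)
    # shape the white texture toward an EMG-like band (first difference
    # removes the lowest frequencies)
    noise <- noise - 0.85 * cbind(0, noise[, -n_e, drop = FALSE])
    X <- (effect$emg_noise * env * noise) * rep(prof_e, each = nrow(pos))
    # ECG pickup: stronger on medial (near-spine) columns
    ecg_gain <- 0.5 + 0.5 * exp(-abs(pos$x) / 40)
    X <- X + outer(ecg_gain, ecg)
    # baseline wander: < 1 Hz summed sinusoids, per-channel random phase,
    # assembled as one rank-6 matrix product
    t <- seq_len(n_e) / fs_emg
    freqs <- c(0.18, 0.35, 0.7)
    basis <- rbind(sin(2 * pi * outer(freqs, t)), cos(2 * pi * outer(freqs, t)))
    ph <- matrix(runif(nrow(pos) * 3, 0, 2 * pi), nrow(pos), 3)
    coefs <- (effect$wander_amplitude / 3) * cbind(cos(ph), sin(ph))
    X <- X + coefs %*% basis
    emg[[id]] <- X
  }

  structure(list(subject_id = subject$id, movement = movement, speed = speed,
                 emg = emg, layouts = layouts, markers = out, plates = plates,
                 rep_windows_truth = truth,
                 fs = list(emg = fs_emg, markers = fs_mrk, plates = fs_plate)),
            class = "trial")
}

# envelope-center displacement achieving a requested shift (mm) of the
# RMS-weighted centroid over the four grids, accounting for boundary
# truncation of the spatial envelope
.envelope_delta <- function(layouts, xc, yc, sig, shift, sig0 = sig) {
  pos <- do.call(rbind, lapply(layouts, electrode_positions, frame = "mm"))
  cen <- function(d, s = sig) {
    w <- 0.15 + exp(-((pos$x - xc)^2 + (pos$y - yc - d)^2) / (2 * s^2))
    sum(w * pos$y) / sum(w)
  }
  target <- cen(0, sig0) + shift
  stats::uniroot(function(d) cen(d) - target,
                 interval = c(0, abs(shift) * 6 + 20),
                 extendInt = "upX", tol = 1e-6)$root
}

# periodic ECG-like artifact train: Ricker QRS plus a small T wave
.ecg_train <- function(n, fs, rate_hz = 1.2) {
  period <- round(fs / rate_hz)
  beat_t <- seq(round(period / 2), n, by = period)
  qrs_w <- round(0.02 * fs)
  t_off <- round(0.16 * fs); t_w <- round(0.06 * fs)
  x <- numeric(n)
  k <- seq(-3 * qrs_w, 3 * qrs_w)
  ricker <- (1 - (k / qrs_w)^2) * exp(-k^2 / (2 * qrs_w^2))
  kt <- seq(-2 * t_w, 2 * t_w)
  twave <- 0.25 * exp(-kt^2 / (2 * t_w^2))
  for (b in beat_t) {
    i <- b + k; ok <- i >= 1 & i <= n
    x[i[ok]] <- x[i[ok]] + ricker[ok]
    j <- b + t_off + kt; ok <- j >= 1 & j <= n
    x[j[ok]] <- x[j[ok]] + twave[ok]
  }
  x
}

#' Generate a full synthetic cohort
#'
#' Draws subject metadata and (optionally) all trials for the configured
#' movements and speeds. Deterministic given the config seed: per-trial
#' seeds are derived arithmetically from the master seed, subject index,
#' movement and speed.
#'
#' @param config a [cohort_config()].
#' @param keep_trials if FALSE only metadata and the trial plan are
#'   returned (trials can be re-simulated on demand with
#'   [cohort_trial()]); avoids holding large cohorts in memory.
#' @return a `cohort` list with `subjects`, `config`, and (if kept)
#'   `trials` (list named `<id>.<movement>.<speed>`).
#' @export
generate_cohort <- function(config, keep_trials = TRUE) {
  subjects <- draw_subjects(config)
  cohort <- structure(list(subjects = subjects, config = config,
                           trials = NULL), class = "cohort")
  if (keep_trials) {
    trials <- list()
    for (i in seq_len(nrow(subjects)))
      for (mv in config$movements)
        for (sp in config$speeds) {
          tr <- cohort_trial(cohort, i, mv, sp)
          trials[[paste(subjects$id[i], mv, sp, sep = ".")]] <- tr
        }
    cohort$trials <- trials
  }
  cohort
}

#' Re-simulate one trial of a cohort deterministically
#'
#' @param cohort a `cohort` (trials need not be materialized).
#' @param subj_idx subject row index.
#' @param movement,speed trial condition.
#' @return a `trial`.
#' @export
cohort_trial <- function(cohort, subj_idx, movement, speed) {
  cfg <- cohort$config
  simulate_trial(cohort$subjects[subj_idx, ], movement, speed,
                 effect = cfg$effect,
                 seed = .trial_seed(cfg$seed, subj_idx, movement, speed),
                 n_repetitions = cfg$n_repetitions,
                 rep_duration_s = cfg$rep_duration_s,
                 gap_s = cfg$gap_s, lead_s = cfg$lead_s)
}
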