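#' Extract all per-trial features
#'
#' Runs the full single-trial chain: repetition segmentation from
#' force-plate stabilization, EMG cleaning (baseline wander, ECG, outlier
#' filling), per-repetition RMS maps, activity centroids and grid
#' entropies, shoulder-trajectory features (amplitude, time to maximum,
#' sample entropy, intra-subject variation), shoulder-line rotation angle,
#' statokinesigram area and ground-reaction-force ratio. Per-movement
#' values are means over valid repetitions. Inter-subject variation
#' requires the healthy reference and is filled in by
#' [build_feature_table()].
#'
#' @param trial a `trial`.
#' @param subject matching row of the cohort's subject table.
#' @param lambda baseline-smoother weight (`"auto"` or numeric).
#' @param mad_k outlier threshold (scaled MADs).
#' @param windows optional precomputed repetition windows (plate clock);
#'   default runs [segment_repetitions()].
#' @return list with `features` (named numeric vector) and
#'   `shoulder_reps` (per marker/axis matrices of 100-sample resampled
#'   repetitions, used for the variation features).
#' @export
extract_trial_features <- function(trial, subject, lambda = "auto",
                                   mad_k = 3, windows = NULL) {
  fs_e <- trial$fs$emg; fs_m <- trial$fs$markers; fs_p <- trial$fs$plates
  if (is.null(windows)) windows <- segment_repetitions(trial, fs = fs_p)
  n_rep <- nrow(windows)
  feats <- c()

  # ---- EMG ------------------------------------------------------------
  win_e <- convert_windows(windows, fs_p, fs_e)
  if (identical(lambda, "auto"))  # one weight per trial: the wander
    lambda <- select_lambda(colMeans(trial$emg[[1]]),  # timescale is shared
                            grid = baseline_lambda_grid(fs_e))
  cleaned <- lapply(trial$emg, preprocess_grid, fs = fs_e, lambda = lambda,
                    mad_k = mad_k)
  gids <- names(cleaned)
  cen <- array(NA_real_, c(n_rep, length(gids), 2),
               dimnames = list(NULL, gids, c("x", "y")))
  ent <- matrix(NA_real_, n_rep, length(gids), dimnames = list(NULL, gids))
  glob <- matrix(NA_real_, n_rep, 2)
  for (k in seq_len(n_rep)) {
    i0 <- win_e$start_sample[k] + 1L; i1 <- win_e$end_sample[k]
    maps <- lapply(gids, function(g)
      electrode_rms(cleaned[[g]][, i0:i1, drop = FALSE], trial$layouts[[g]]))
    names(maps) <- gids
    for (g in gids) {
      cc <- grid_centroid(maps[[g]])
      cen[k, g, ] <- c(cc$x, cc$y)
      ent[k, g] <- grid_entropy(maps[[g]])
    }
    gc <- global_centroid(maps)
    glob[k, ] <- c(gc$x, gc$y)
  }
  for (g in gids) {
    feats[paste0("emg_centroid_", g, "_x")] <- mean(cen[, g, "x"])
    feats[paste0("emg_centroid_", g, "_y")] <- mean(cen[, g, "y"])
    feats[paste0("emg_entropy_", g)] <- mean(ent[, g])
  }
  feats["emg_centroid_global_x"] <- mean(glob[, 1])
  feats["emg_centroid_global_y"] <- mean(glob[, 2])

  # ---- markers --------------------------------------------------------
  win_m <- convert_windows(windows, fs_p, fs_m)
  shoulder_reps <- list()
  for (mk in c("left_shoulder", "right_shoulder")) {
    for (ax in c("X", "Y", "Z")) {
      col <- trial$markers[[paste0(mk, "_", ax)]]
      amp <- t2m <- se <- numeric(n_rep)
      R <- matrix(NA_real_, n_rep, 100L)
      for (k in seq_len(n_rep)) {
        i0 <- win_m$start_sample[k] + 1L; i1 <- win_m$end_sample[k]
        seg <- col[i0:min(i1, length(col))]
        amp[k] <- max_amplitude(seg)
        t2m[k] <- time_to_max(seg, fs_m)
        se[k] <- trajectory_sample_entropy(seg)
        R[k, ] <- resample_trajectory(seg, 100L)
      }
      key <- paste(tolower(mk), tolower(ax), sep = "_")
      h_m <- subject$height / 100
      feats[paste0("traj_maxamp_", key)] <- mean(amp) / h_m
      feats[paste0("traj_maxamp_raw_", key)] <- mean(amp)
      feats[paste0("traj_t2max_", key)] <- mean(t2m)
      feats[paste0("traj_sampen_", key)] <- mean(se, na.rm = TRUE)
      feats[paste0("traj_intravar_", key)] <-
        intra_subject_variation(R, subject$height)
      shoulder_reps[[key]] <- R
    }
  }

  # shoulder-line rotation angle about the vertical axis
  L <- as.matrix(trial$markers[, paste0("left_shoulder_", c("X", "Y", "Z"))])
  Rg <- as.matrix(trial$markers[, paste0("right_shoulder_", c("X", "Y", "Z"))])
  ma <- tt <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    i0 <- win_m$start_sample[k] + 1L; i1 <- min(win_m$end_sample[k], nrow(L))
    ang <- shoulder_angle_z(L[i0:i1, , drop = FALSE], Rg[i0:i1, , drop = FALSE])
    af <- max_angle_features(ang, fs_m)
    ma[k] <- af$max_angle; tt[k] <- af$time_to_max_angle
  }
  feats["angle_max_shoulder_z"] <- mean(ma)
  feats["angle_t2max_shoulder_z"] <- mean(tt)

  # ---- balance --------------------------------------------------------
  areas <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    i0 <- windows$start_sample[k] + 1L; i1 <- windows$end_sample[k]
    nz <- normalize_statokinesigram(trial$plates$cop_x[i0:i1],
                                    trial$plates$cop_y[i0:i1])
    areas[k] <- ellipse_area_95(nz$cop_x, nz$cop_y)
  }
  feats["statok_area"] <- mean(areas)
  feats["gfr_ratio"] <- gfr_ratio(trial$plates$gfr_left, trial$plates$gfr_right)
  feats["gfr_fa"] <- gfr_fa_transform(feats[["gfr_ratio"]])
  feats["foot_bary_x"] <- mean(trial$plates$cop_x)
  feats["foot_bary_y"] <- mean(trial$plates$cop_y)

  list(features = feats, shoulder_reps = shoulder_reps)
}

#' Build the cohort feature table
#'
#' One row per subject x movement x speed. Trials are simulated (or taken
#' from the materialized cohort), preprocessed and reduced to features in
#' a single streaming pass; afterwards the healthy-group mean trajectory
#' per movement/speed/marker/axis is formed and the inter-subject
#' variation columns are filled (the reference excludes the subject under
#' evaluation for healthy subjects).
#'
#' @param cohort a `cohort` (trials materialized or re-simulable).
#' @param lambda,mad_k preprocessing parameters.
#' @param verbose print progress.
#' @return data.frame feature table; attribute `"healthy_means"` carries
#'   the reference trajectories.
#' @export
build_feature_table <- function(cohort, lambda = "auto", mad_k = 3,
                                verbose = FALSE) {
  cfg <- cohort$config
  subjects <- cohort$subjects
  rows <- list(); reps_store <- list()
  for (i in seq_len(nrow(subjects))) {
    for (mv in cfg$movements) for (sp in cfg$speeds) {
      key <- paste(subjects$id[i], mv, sp, sep = ".")
      tr <- if (!is.null(cohort$trials)) cohort$trials[[key]]
            else cohort_trial(cohort, i, mv, sp)
      if (verbose) message("features: ", key)
      ex <- extract_trial_features(tr, subjects[i, ], lambda = lambda,
                                   mad_k = mad_k)
      rows[[key]] <- data.frame(subject_id = subjects$id[i],
                                group = subjects$group[i],
                                sex = subjects$sex[i],
                                age = subjects$age[i],
                                height = subjects$height[i],
                                weight = subjects$weight[i],
                                bmi = subjects$bmi[i],
                                movement = mv, speed = sp,
                                t(ex$features), check.names = FALSE,
                                stringsAsFactors = FALSE)
      reps_store[[key]] <- ex$shoulder_reps
    }
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))

  # healthy reference trajectories: per movement/speed/marker-axis, the
  # mean of the healthy subjects' repetition-mean 100-sample trajectories
  healthy_ids <- subjects$id[subjects$group == 0L]
  axes <- names(reps_store[[1]])
  hmeans <- list()
  for (mv in cfg$movements) for (sp in cfg$speeds) for (ax in axes) {
    mats <- lapply(healthy_ids, function(id)
      colMeans(reps_store[[paste(id, mv, sp, sep = ".")]][[ax]]))
    hmeans[[paste(mv, sp, ax, sep = ".")]] <-
      list(per_subject = do.call(rbind, mats), ids = healthy_ids)
  }
  for (ax in axes) tab[[paste0("traj_intervar_", ax)]] <- NA_real_
  for (r in seq_len(nrow(tab))) {
    id <- tab$subject_id[r]; mv <- tab$movement[r]; sp <- tab$speed[r]
    for (ax in axes) {
      hm <- hmeans[[paste(mv, sp, ax, sep = ".")]]
      use <- hm$ids != id              # exclude self for healthy subjects
      ref <- if (any(use)) colMeans(hm$per_subject[use, , drop = FALSE])
             else colMeans(hm$per_subject)
      tab[[paste0("traj_intervar_", ax)]][r] <-
        inter_subject_variation(reps_store[[paste(id, mv, sp, sep = ".")]][[ax]],
                                ref, tab$height[r])
    }
  }
  attr(tab, "healthy_means") <- lapply(hmeans, function(h)
    colMeans(h$per_subject))
  tab
}
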