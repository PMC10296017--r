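#' Write a cohort to a directory
#'
#' Layout: `manifest.json` at the root (subject metadata, config summary,
#' trial index), one sub-directory per subject, and per trial four
#' delimited-text EMG channel tables (columns = electrodes in row-major
#' 13 x 5 order, grids `left_lower`, `left_upper`, `right_lower`,
#' `right_upper`), one marker table (`<marker>_{X,Y,Z}` columns) and one
#' plate table (`t, gfr_left, gfr_right, cop_x, cop_y`). Numeric values
#' round-trip exactly.
#'
#' @param cohort a materialized `cohort` (see [generate_cohort()]).
#' @param dir writable output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$trials)) stop("cohort has no materialized trials to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  # full round-trip precision: 17 significant digits uniquely identify a
  # double, so numeric tables are written through sprintf("%.17g")
  wt <- function(df, f) {
    out <- lapply(df, function(col)
      if (is.double(col)) sprintf("%.17g", col) else col)
    data.table::fwrite(data.table::as.data.table(out), f, quote = FALSE)
  }
  trials_idx <- list()
  for (key in names(cohort$trials)) {
    tr <- cohort$trials[[key]]
    sdir <- file.path(dir, tr$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    stem <- paste(tr$movement, tr$speed, sep = "_")
    files <- list()
    for (gid in names(tr$emg)) {
      f <- file.path(sdir, sprintf("%s_emg_%s.csv", stem, gid))
      wt(data.table::as.data.table(t(tr$emg[[gid]])), f)
      files[[paste0("emg_", gid)]] <- basename(f)
    }
    f <- file.path(sdir, paste0(stem, "_markers.csv"))
    wt(tr$markers, f); files$markers <- basename(f)
    f <- file.path(sdir, paste0(stem, "_plates.csv"))
    wt(tr$plates, f); files$plates <- basename(f)
    trials_idx[[key]] <- list(subject_id = tr$subject_id,
                              movement = tr$movement, speed = tr$speed,
                              dir = tr$subject_id, files = files,
                              n_channels = as.list(vapply(tr$emg, nrow, integer(1))),
                              rep_windows_truth = tr$rep_windows_truth,
                              fs = tr$fs)
  }
  manifest <- list(format = "lbpmotion-cohort/1",
                   subjects = cohort$subjects,
                   n_trials = length(trials_idx),
                   trials = trials_idx)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return a `cohort` with `subjects` and `trials`; numeric arrays equal
#'   the written ones exactly.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest: ", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "lbpmotion-cohort/1"))
    stop("schema mismatch in ", mf, ": unknown format field")
  subjects <- as.data.frame(manifest$subjects)
  trials <- list()
  for (key in names(manifest$trials)) {
    ti <- manifest$trials[[key]]
    sdir <- file.path(dir, ti$dir)
    emg <- list()
    for (gid in c("left_lower", "left_upper", "right_lower", "right_upper")) {
      f <- file.path(sdir, ti$files[[paste0("emg_", gid)]])
      if (!file.exists(f)) stop("missing EMG file: ", f)
      m <- t(as.matrix(data.table::fread(f)))
      expected <- ti$n_channels[[gid]]
      if (nrow(m) != expected)
        stop(sprintf("corrupt trial %s: %s has %d channels, expected %d",
                     key, basename(f), nrow(m), expected))
      dimnames(m) <- NULL
      emg[[gid]] <- m
    }
    mkf <- file.path(sdir, ti$files$markers)
    plf <- file.path(sdir, ti$files$plates)
    if (!file.exists(mkf)) stop("missing marker file: ", mkf)
    if (!file.exists(plf)) stop("missing plate file: ", plf)
    trials[[key]] <- structure(
      list(subject_id = ti$subject_id, movement = ti$movement,
           speed = ti$speed, emg = emg, layouts = back_grid_set(),
           markers = as.data.frame(data.table::fread(mkf)),
           plates = as.data.frame(data.table::fread(plf)),
           rep_windows_truth = as.data.frame(ti$rep_windows_truth),
           fs = ti$fs),
      class = "trial")
  }
  structure(list(subjects = subjects, config = NULL, trials = trials),
            class = "cohort")
}
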