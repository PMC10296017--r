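#' @importFrom Matrix Diagonal bandSparse crossprod solve
#' @importFrom stats approx median qt runmed sd var quantile rnorm runif mad
NULL

# second-difference penalty matrix D (n-2 x n)
.second_diff <- function(n) {
  Matrix::bandSparse(n - 2L, n, k = 0:2,
                     diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                      rep(1, n - 2L)))
}

#' Whittaker baseline estimate
#'
#' Penalized least-squares smoother: the baseline `z` minimizes
#' `|x - z|^2 + lambda * |D2 z|^2` with a second-difference penalty, i.e.
#' the classic quadratic-variation smoother used for baseline-wander
#' estimation in biosignals. Accepts a matrix to smooth many channels with
#' one factorization.
#'
#' @param x numeric vector, or matrix with one channel per column.
#' @param lambda positive regularization weight.
#' @param decimate integer >= 1; values above 1 solve the penalized system
#'   on a decimated grid (with `lambda` rescaled by `decimate^-4`, the
#'   sampling-rate scaling of the second-order penalty) and interpolate
#'   the smooth baseline back, a cheap approximation appropriate when the
#'   baseline timescale is far above the sample spacing.
#' @return baseline of the same shape as `x`.
#' @export
whittaker_baseline <- function(x, lambda, decimate = 1L) {
  mat <- is.matrix(x)
  X <- if (mat) x else matrix(x, ncol = 1L)
  n <- nrow(X)
  if (n < 3L) stop("signal too short (need length >= 3)")
  if (!all(is.finite(X))) stop("non-finite values in input signal")
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be positive")
  if (decimate > 1L && n > 3L * decimate) {
    idx <- seq(1L, n, by = as.integer(decimate))
    Zd <- whittaker_baseline(X[idx, , drop = FALSE], lambda / decimate^4)
    pos <- pmin(findInterval(seq_len(n), idx), length(idx) - 1L)
    w <- (seq_len(n) - idx[pos]) / (idx[pos + 1L] - idx[pos])
    Z <- Zd[pos, , drop = FALSE] * (1 - w) + Zd[pos + 1L, , drop = FALSE] * w
    return(if (mat) Z else drop(Z))
  }
  D <- .second_diff(n)
  A <- Matrix::Diagonal(n) + lambda * Matrix::crossprod(D)
  Z <- as.matrix(Matrix::solve(A, X))
  if (mat) Z else drop(Z)
}

#' Remove baseline wander from a signal
#'
#' Subtracts a smooth baseline estimated by [whittaker_baseline()]. With
#' `lambda = "auto"` the weight is chosen per signal by [select_lambda()].
#'
#' @param signal numeric vector or channels-in-columns matrix.
#' @param lambda positive number or `"auto"`.
#' @return cleaned signal, same shape as the input.
#' @export
remove_baseline_wander <- function(signal, lambda = "auto") {
  if (identical(lambda, "auto") || identical(lambda, "AUTO")) {
    ref <- if (is.matrix(signal)) rowMeans(signal) else signal
    lambda <- select_lambda(ref)
  }
  signal - whittaker_baseline(signal, lambda)
}

#' Automatic smoothing weight by L-curve knee
#'
#' Sweeps `lambda` over a logarithmic grid and, on the L-curve of
#' `log` residual norm against `log` baseline roughness (second-difference
#' norm), returns the grid point of maximum curvature (the knee).
#' Deterministic; if the curve is flat (no knee, e.g. a constant signal)
#' the grid midpoint is returned with a warning.
#'
#' For long signals the sweep runs on a decimated copy and the selected
#' weight is rescaled by the decimation factor to the fourth power (the
#' sampling-rate scaling of a second-order difference penalty), keeping
#' the selection cheap without changing the effective smoothing timescale.
#'
#' @param signal numeric vector, length >= 100.
#' @param grid candidate lambdas, default `10^seq(-2, 6, length.out = 25)`.
#' @param max_n decimate the sweep input to at most this many samples.
#' @return selected lambda (scalar).
#' @export
select_lambda <- function(signal, grid = 10^seq(-2, 6, length.out = 25),
                          max_n = 4000L) {
  if (length(grid) == 1L) return(grid)
  if (length(signal) < 100L) stop("signal too short for lambda selection (need >= 100)")
  if (!all(is.finite(signal))) stop("non-finite values in input signal")
  if (stats::sd(signal) == 0) {
    warning("flat L-curve: no knee found, returning grid midpoint")
    return(grid[ceiling(length(grid) / 2)])
  }
  if (length(signal) > max_n) {
    dec <- ceiling(length(signal) / max_n)
    lam <- select_lambda(signal[seq(1L, length(signal), by = dec)],
                         grid = grid, max_n = length(signal))
    return(lam * dec^4)
  }
  n <- length(signal)
  D <- .second_diff(n)
  DtD <- Matrix::crossprod(D)
  I <- Matrix::Diagonal(n)
  res <- rough <- numeric(length(grid))
  for (i in seq_along(grid)) {
    z <- as.numeric(Matrix::solve(I + grid[i] * DtD, signal))
    res[i] <- sqrt(sum((signal - z)^2))
    rough[i] <- sqrt(sum(diff(z, differences = 2L)^2))
  }
  eps <- 1e-300
  lx <- log(res + eps); ly <- log(rough + eps)
  if (max(abs(diff(lx))) < 1e-8 || max(abs(diff(ly))) < 1e-8) {
    warning("flat L-curve: no knee found, returning grid midpoint")
    return(grid[ceiling(length(grid) / 2)])
  }
  # discrete curvature along the parameterized curve (lx, ly)
  t <- log(grid)
  dx <- .cdiff(lx, t); dy <- .cdiff(ly, t)
  ddx <- .cdiff(dx, t); ddy <- .cdiff(dy, t)
  kappa <- (dx * ddy - dy * ddx) / (dx^2 + dy^2)^1.5
  kappa[!is.finite(kappa)] <- -Inf
  # one-sided differences make the first/last candidates unreliable
  kappa[c(1L, 2L, length(kappa) - 1L, length(kappa))] <- -Inf
  grid[which.max(kappa)]
}

#' Lambda grid matched to baseline timescales
#'
#' The second-difference smoother at weight `lambda` behaves like a
#' low-pass of cutoff `fs / (2 pi lambda^(1/4))`; this grid spans baseline
#' cutoffs from `f_hi` down to `f_lo` Hz, so the knee search stays in the
#' regime where only wander (not signal) is absorbed by the baseline.
#'
#' @param fs sampling rate, Hz.
#' @param f_lo,f_hi slowest and fastest baseline cutoff, Hz.
#' @param length grid size.
#' @return numeric vector of lambda candidates (increasing).
#' @export
baseline_lambda_grid <- function(fs, f_lo = 0.05, f_hi = 5, length = 25L) {
  fc <- 10^seq(log10(f_hi), log10(f_lo), length.out = length)
  (fs / (2 * pi * fc))^4
}

# central differences on a possibly non-uniform grid
.cdiff <- function(y, t) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d
}

#' Detect heartbeat instants on a multichannel EMG recording
#'
#' QRS complexes are located on the band-pass (5-30 Hz) filtered
#' cross-channel average -- the band holding most QRS energy while
#' excluding slow activity-envelope modulation -- as local maxima of the
#' squared filtered signal above an adaptive threshold, with a 0.3 s
#' refractory spacing.
#'
#' @param samples channels x time matrix.
#' @param fs sampling rate, Hz.
#' @param mask optional logical vector: restrict candidate peaks to these
#'   samples.
#' @param quiet_thr optional logical vector: anchor the detection
#'   threshold to these (stabilized) samples while still searching the
#'   whole record.
#' @return integer vector of beat sample indices (possibly empty).
#' @export
detect_heartbeats <- function(samples, fs = 2048, mask = NULL,
                              quiet_thr = NULL) {
  .detect_from_energy(.beat_energy(samples, fs), fs, mask, quiet_thr)
}

.detect_from_energy <- function(e, fs, mask = NULL, quiet_thr = NULL) {
  if (!is.null(mask)) e[!mask] <- 0
  thr <- if (!is.null(quiet_thr) && any(quiet_thr))
    0.3 * max(e[quiet_thr]) else 0.3 * max(e)
  min_gap <- round(0.3 * fs)
  cand <- which(e > thr)
  if (!length(cand)) return(integer(0))
  beats <- integer(0)
  while (length(cand)) {
    blk <- cand[cand < cand[1] + min_gap]
    beats <- c(beats, blk[which.max(e[blk])])
    cand <- cand[cand >= cand[1] + min_gap]
  }
  beats <- sort(beats)
  beats[c(TRUE, diff(beats) >= min_gap)]
}

# QRS-emphasizing energy trace: squared band-pass (5-30 Hz) cross-channel
# average; the averaging suppresses channel-independent EMG while the
# common-mode cardiac waveform survives
.beat_energy <- function(samples, fs) {
  avg <- colMeans(samples)
  bf <- signal::butter(2, c(5, 30) / (fs / 2), type = "pass")
  lp <- signal::filtfilt(bf, avg - mean(avg))
  lp^2
}

# smoothed whole-grid RMS envelope (activity level per sample);
# cumulative-sum moving average for O(n) cost
.grid_envelope <- function(samples, fs, win_s = 0.25) {
  r <- colMeans(samples^2)
  w <- round(win_s * fs)
  n <- length(r)
  cs <- cumsum(c(0, r))
  lo <- pmax(0L, seq_len(n) - 1L - w %/% 2L)
  hi <- pmin(n, seq_len(n) + w %/% 2L)
  sqrt(pmax(0, (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)))
}

# fit a regular beat grid (period + phase) over the record: candidate
# periods come from pairwise spacings of detected events (and their small
# integer fractions) in the cardiac range; each (period, phase) comb is
# scored by the beat energy it collects at its quiet-segment grid points,
# so movement-locked energy cannot steer the fit
.beat_grid <- function(beats, e, quiet, fs) {
  n <- length(e)
  tol <- round(0.05 * fs)
  d <- as.vector(outer(beats, beats, `-`))
  cand_p <- unique(unlist(lapply(1:4, function(k) round(d / k))))
  cand_p <- cand_p[cand_p >= 0.4 * fs & cand_p <= 2 * fs]
  # coarse (10 ms) period and (25 ms) phase candidates are enough here:
  # the subsequent least-squares refinement restores full precision
  step_p <- max(1L, round(0.01 * fs))
  cand_p <- unique(round(cand_p / step_p) * step_p)
  if (!length(cand_p)) return(NULL)
  score_comb <- function(P, p0) {
    grid <- round(seq(p0 %% P, n, by = P))
    grid <- grid[grid >= 1]
    gq <- grid[quiet[pmin(pmax(grid, 1L), n)]]
    if (length(gq) < 2L) return(list(score = -Inf, grid = grid))
    loc <- vapply(gq, function(g)
      max(e[max(1L, g - tol):min(n, g + tol)]), numeric(1))
    # sum / sqrt(count): a comb at a multiple of the true period collects
    # the same energy over fewer points and a submultiple dilutes it over
    # empty points; both score below the true comb under this rule
    list(score = sum(loc) / sqrt(length(gq)), grid = grid)
  }
  best <- NULL; best_score <- -Inf; best_P <- NA
  step_ph <- max(1L, round(0.025 * fs))
  for (P in sort(unique(cand_p))) {
    for (p0 in unique(round((beats %% P) / step_ph) * step_ph)) {
      sc <- score_comb(P, p0)
      if (sc$score > best_score + 1e-12) {
        best_score <- sc$score; best <- sc$grid; best_P <- P
      }
    }
  }
  if (!is.finite(best_score)) {
    if (!all(quiet)) return(.beat_grid(beats, e, rep(TRUE, n), fs))
    return(NULL)
  }
  grid <- best
  # snap grid points to a nearby detected candidate where one exists
  for (i in seq_along(grid)) {
    dd <- abs(beats - grid[i])
    if (min(dd) <= tol) grid[i] <- beats[which.min(dd)]
  }
  explained <- sum(vapply(beats, function(b)
    min(abs(grid - b)) <= tol, logical(1)))
  list(grid = as.integer(grid), period = best_P, explained = explained,
       n_candidates = length(beats))
}

#' Remove ECG contamination by template subtraction
#'
#' Detects heartbeats on the low-pass cross-channel average, builds a
#' per-channel beat template by averaging epochs aligned on the detected
#' instants, and subtracts the template at each occurrence. Output length
#' is unchanged. If no beats are detected the input is returned unchanged
#' with a warning.
#'
#' @param samples channels x time matrix at `fs` Hz (>= 4 s of signal).
#' @param fs sampling rate, Hz.
#' @param half_width_s epoch half width around each beat, seconds.
#' @return cleaned channels x time matrix.
#' @export
remove_ecg <- function(samples, fs = 2048, half_width_s = 0.30) {
  samples <- as.matrix(samples)
  n <- ncol(samples)
  if (n < 4 * fs) stop("need at least 4 s of signal for ECG removal")
  # stabilized (low-EMG) samples: heartbeats are sought there first, since
  # no voluntary activity competes with the cardiac waveform in the gaps
  env <- .grid_envelope(samples, fs)
  lenv <- log(env + 1e-12)
  # movement structure = wide envelope dynamics AND sustained active runs;
  # only then is the low-envelope mask a map of the stabilized gaps (for a
  # stationary recording it merely traces noise, and is not used)
  spread_wide <- diff(stats::quantile(lenv, c(0.1, 0.9), names = FALSE)) > 1
  act <- rle(lenv >= .otsu(lenv))
  long_run <- max(c(0, act$lengths[act$values])) > 0.4 * fs
  quiet <- if (spread_wide && long_run) lenv < .otsu(lenv) else rep(TRUE, n)
  # peaks over the whole record, but with the detection threshold anchored
  # to the stabilized gaps so movement bursts cannot raise it above the
  # cardiac peaks
  e <- .beat_energy(samples, fs)
  cand <- .detect_from_energy(e, fs, quiet_thr = quiet)
  if (length(cand) < 3L) cand <- .detect_from_energy(e, fs)
  if (length(cand) < 3L) {
    warning("no heartbeats detected; returning input unchanged")
    return(samples)
  }
  bg <- .beat_grid(cand, e, quiet, fs)
  if (is.null(bg) || bg$explained < 2L) {
    warning("detected events are aperiodic; returning input unchanged")
    return(samples)
  }
  beats <- bg$grid
  # refine period and phase by least squares on the accurate beats: those
  # detected inside stabilized gaps and consistent with the fitted comb
  tol <- round(0.05 * fs)
  qc <- cand[quiet[cand]]
  qc <- qc[vapply(qc, function(b) min(abs(beats - b)) <= tol, logical(1))]
  if (length(qc) >= 2L) {
    k <- round((qc - qc[1]) / bg$period)
    if (length(unique(k)) >= 2L) {
      P2 <- sum((k - mean(k)) * (qc - mean(qc))) / sum((k - mean(k))^2)
      if (P2 >= 0.4 * fs && P2 <= 2 * fs) {
        ph <- mean(qc - k * P2)
        ph <- ph - floor((ph - 1) / P2) * P2
        beats <- as.integer(round(seq(ph, n, by = P2)))
        beats <- beats[beats >= 1L]
      }
    }
  }
  hw <- round(half_width_s * fs)
  full <- beats[beats - hw >= 1L & beats + hw <= n]
  if (length(full) < 2L) {
    warning("too few complete beat epochs; returning input unchanged")
    return(samples)
  }
  # per-channel template: mean over aligned epochs, preferring epochs
  # centred in stabilized gaps (the cleanest views of the beat)
  tmpl_beats <- full[quiet[full]]
  if (length(tmpl_beats) < 2L) tmpl_beats <- full
  nch <- nrow(samples)
  wlen <- 2L * hw + 1L
  tmpl <- matrix(0, nch, wlen)
  for (b in tmpl_beats) tmpl <- tmpl + samples[, (b - hw):(b + hw), drop = FALSE]
  tmpl <- tmpl / length(tmpl_beats)
  # a cardiac artifact is coherent across electrodes: every channel sees a
  # scaled copy of the same beat waveform. Incoherent per-channel
  # templates mean the fitted rhythm was movement- or noise-locked, and
  # subtracting them would corrupt the EMG.
  core <- (hw + 1L - round(0.06 * fs)):(hw + 1L + round(0.06 * fs))
  mean_t <- colMeans(tmpl[, core, drop = FALSE])
  coh <- stats::median(abs(apply(tmpl[, core, drop = FALSE], 1L,
                                 stats::cor, y = mean_t)))
  if (!is.finite(coh) || coh < 0.4) {
    warning("no coherent cardiac template found (aperiodic or absent ECG); returning input unchanged")
    return(samples)
  }
  # taper only the outer edges (Tukey window) so subtraction does not
  # introduce steps while the beat morphology is removed at full scale
  w <- rep(1, wlen)
  ramp <- max(2L, round(0.1 * wlen))
  edge <- 0.5 - 0.5 * cos(pi * seq_len(ramp) / ramp)
  w[seq_len(ramp)] <- edge
  w[wlen + 1L - seq_len(ramp)] <- edge
  tmpl <- sweep(tmpl, 2L, w, `*`)
  out <- samples
  for (b in beats) {
    lo <- max(1L, b - hw); hi <- min(n, b + hw)
    tlo <- lo - (b - hw) + 1L
    out[, lo:hi] <- out[, lo:hi] - tmpl[, tlo:(tlo + hi - lo), drop = FALSE]
  }
  out
}

#' Replace moving-median outliers by interpolation
#'
#' Samples farther than `k` scaled MADs from the moving median are replaced
#' by linear interpolation of the surrounding retained samples; all other
#' samples are returned bit-identical. A constant signal (MAD 0) is a
#' no-op.
#'
#' @param signal numeric vector.
#' @param window odd moving-median window length (samples), default 2049
#'   (~1 s at 2048 Hz).
#' @param k MAD multiplier.
#' @return signal with outliers filled.
#' @export
fill_outliers <- function(signal, window = 2049L, k = 3) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (k <= 0) stop("k must be positive")
  n <- length(signal)
  if (window > n) stop("window longer than signal")
  # for wide windows the moving median is evaluated on a decimated grid
  # and interpolated: the estimate varies on the window timescale, so the
  # coarse evaluation loses nothing while keeping long signals cheap
  dec <- max(1L, window %/% 65L)
  if (dec > 1L) {
    idx <- seq(1L, n, by = dec)
    wdec <- max(3L, (window %/% dec) %/% 2L * 2L + 1L)
    mdec <- stats::runmed(signal[idx], wdec, endrule = "median")
    med <- stats::approx(idx, mdec, xout = seq_len(n), rule = 2)$y
  } else
  med <- stats::runmed(signal, window, endrule = "median")
  dev <- abs(signal - med)
  smad <- 1.4826 * stats::median(dev)   # scaled MAD of the detrended residual
  bad <- dev > k * smad & smad > 0
  if (!any(bad)) return(signal)
  idx <- seq_len(n)
  good <- !bad
  if (sum(good) < 2L) stop("too few inliers to interpolate")
  signal[bad] <- stats::approx(idx[good], signal[good], xout = idx[bad],
                               rule = 2)$y
  signal
}

#' Segment a trial into movement repetitions from force-plate stabilization
#'
#' Movement windows are bounded by quiet intervals in which the
#' sliding-window variance of the total vertical ground reaction force
#' stays below a threshold for at least `dwell_s` seconds. The threshold is
#' chosen automatically on the log-variance trace by a two-class (Otsu)
#' split, or can be given. Windows are returned in plate-clock samples,
#' half-open `[start, end)`, 0-based, ordered.
#'
#' @param trial a trial object (see [simulate_trial()]) or a list with a
#'   `plates` data frame holding `gfr_left` and `gfr_right`.
#' @param fs plate sampling rate, Hz.
#' @param win_s sliding variance window, seconds.
#' @param dwell_s minimum quiet duration, seconds.
#' @param threshold `"auto"` or a numeric variance threshold.
#' @param min_dur_s movement windows shorter than this are discarded as
#'   spurious blips.
#' @return data.frame with `repetition`, `start_sample`, `end_sample`,
#'   `start_s`, `end_s`.
#' @export
segment_repetitions <- function(trial, fs = 1000, win_s = 0.10,
                                dwell_s = 0.08, threshold = "auto",
                                min_dur_s = 0.25) {
  plates <- if (!is.null(trial$plates)) trial$plates else trial
  if (is.null(plates$gfr_left) || is.null(plates$gfr_right))
    stop("plate series (gfr_left/gfr_right) are required for segmentation")
  tot <- plates$gfr_left + plates$gfr_right
  n <- length(tot)
  w <- max(3L, round(win_s * fs))
  # sliding variance via cumulative sums
  cs <- cumsum(c(0, tot)); cs2 <- cumsum(c(0, tot^2))
  i0 <- seq_len(n - w + 1L)
  s <- cs[i0 + w] - cs[i0]; s2 <- cs2[i0 + w] - cs2[i0]
  v <- pmax(0, (s2 - s^2 / w) / (w - 1L))
  lv <- log(v + 1e-12)
  thr <- if (identical(threshold, "auto")) exp(.otsu(lv)) - 1e-12 else threshold
  quiet <- v < thr
  # a genuine quiet/active alternation spreads the log-variance trace over
  # orders of magnitude; a stationary signal keeps it narrow
  spread <- diff(stats::quantile(lv, c(0.1, 0.9), names = FALSE))
  if (spread < 1.5) {
    err <- structure(class = c("segmentation_error", "error", "condition"),
                     list(message = "no quiet/active structure in the plate variance trace",
                          call = sys.call(), variance = v, threshold = thr))
    stop(err)
  }
  r <- rle(quiet)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  dwell <- round(dwell_s * fs)
  qi <- which(r$values & r$lengths >= dwell)
  if (length(qi) < 2L) {
    err <- structure(class = c("segmentation_error", "error", "condition"),
                     list(message = "fewer than 1 repetition found (no alternation of quiet and active phases)",
                          call = sys.call(), variance = v, threshold = thr))
    stop(err)
  }
  # movement windows lie between consecutive quiet intervals
  st <- ends[qi[-length(qi)]] + 1L          # first active sample (1-based, variance grid)
  en <- starts[qi[-1]] - 1L                 # last active sample
  keep <- (en - st) >= min_dur_s * fs
  st <- st[keep]; en <- en[keep]
  if (!length(st)) {
    err <- structure(class = c("segmentation_error", "error", "condition"),
                     list(message = "fewer than 1 repetition found (all active windows below the minimum duration)",
                          call = sys.call(), variance = v, threshold = thr))
    stop(err)
  }
  # variance-window index -> signal sample: the movement onset is the
  # right edge of the last fully quiet window, the offset the left edge of
  # the first fully quiet window after it
  start0 <- pmax(0L, st + w - 2L)           # 0-based
  end0 <- pmin(n, en)                       # half-open
  data.frame(repetition = seq_along(start0),
             start_sample = start0, end_sample = end0,
             start_s = start0 / fs, end_s = end0 / fs)
}

# Otsu threshold on a numeric vector (maximal between-class variance)
.otsu <- function(x, nbins = 128L) {
  h <- graphics::hist(x, breaks = nbins, plot = FALSE)
  p <- h$counts / sum(h$counts); mids <- h$mids
  w1 <- cumsum(p); mu <- cumsum(p * mids); muT <- mu[length(mu)]
  sb <- (muT * w1 - mu)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

#' Convert a plate-clock window to another sampling rate
#'
#' @param windows data.frame from [segment_repetitions()].
#' @param fs_from,fs_to source and target sampling rates.
#' @return data.frame with converted `start_sample`/`end_sample` (0-based,
#'   half-open).
#' @export
convert_windows <- function(windows, fs_from = 1000, fs_to = 2048) {
  out <- windows
  out$start_sample <- as.integer(floor(windows$start_sample * fs_to / fs_from))
  out$end_sample <- as.integer(ceiling(windows$end_sample * fs_to / fs_from))
  out$start_s <- out$start_sample / fs_to
  out$end_s <- out$end_sample / fs_to
  out
}

#' Resample one repetition to a fixed number of samples
#'
#' Linear interpolation per channel, preserving endpoints exactly.
#'
#' @param rep channels x time matrix (or vector), >= 2 samples.
#' @param n_out output length, default 6000.
#' @return channels x `n_out` matrix (or length-`n_out` vector).
#' @export
resample_repetition <- function(rep, n_out = 6000L) {
  vec <- !is.matrix(rep)
  X <- if (vec) matrix(rep, nrow = 1L) else rep
  n <- ncol(X)
  if (n < 2L) stop("repetition must have at least 2 samples")
  xo <- seq(1, n, length.out = n_out)
  out <- t(apply(X, 1L, function(ch) stats::approx(seq_len(n), ch, xout = xo)$y))
  if (vec) drop(out) else out
}

#' Stack four resampled grids into the CNN input tensor
#'
#' Tiles the four 13 x 5 patches into one 26 x 10 spatial sheet (left grids
#' in columns 1-5, right grids in columns 6-10; lower grids in rows 1-13,
#' upper grids in rows 14-26) over `n_out` time samples, giving a
#' `26 x 10 x n_out` array. Unpopulated electrode positions are zero.
#'
#' @param grids named list with elements `left_lower`, `left_upper`,
#'   `right_lower`, `right_upper`, each a channels x time matrix already
#'   resampled to a common length.
#' @param layouts matching list of [grid_layout()]s.
#' @return numeric array `dim = c(26, 10, n_out)`.
#' @export
stack_grids <- function(grids, layouts = back_grid_set()) {
  need <- c("left_lower", "left_upper", "right_lower", "right_upper")
  if (!all(need %in% names(grids))) stop("grids must be named ", paste(need, collapse = ", "))
  nt <- unique(vapply(grids[need], ncol, integer(1)))
  if (length(nt) != 1L) stop("all grids must share the same (resampled) length")
  out <- array(0, dim = c(26L, 10L, nt))
  place <- function(id, rows, cols) {
    lay <- layouts[[id]]
    if (nrow(grids[[id]]) != lay$n_channels)
      stop(sprintf("channel count mismatch for %s", id))
    pos <- electrode_positions(lay, "index")
    for (i in seq_len(nrow(pos)))
      out[rows[pos$row[i]], cols[pos$col[i]], ] <<- grids[[id]][i, ]
  }
  place("left_lower", 1:13, 1:5)
  place("left_upper", 14:26, 1:5)
  place("right_lower", 1:13, 6:10)
  place("right_upper", 14:26, 6:10)
  out
}

# vectorized outlier filling over the rows of a channels x time matrix;
# same detection rule as fill_outliers (decimated moving median, scaled
# MAD of the detrended residual), interpolated replacement
.fill_outliers_matrix <- function(X, window, k) {
  n <- ncol(X)
  window <- min(window, if (n %% 2L) n else n - 1L)
  dec <- max(1L, window %/% 65L)
  idx <- seq(1L, n, by = dec)
  wdec <- max(3L, (window %/% dec) %/% 2L * 2L + 1L)
  Md <- t(apply(X[, idx, drop = FALSE], 1L, stats::runmed, k = wdec,
                endrule = "constant"))
  # nearest-point lookup of the decimated medians (the moving median
  # varies on the window timescale, far above the decimation step)
  pos <- pmin(length(idx), pmax(1L, as.integer(round((seq_len(n) - 1L) / dec)) + 1L))
  dev <- abs(X - Md[, pos, drop = FALSE])
  smad <- 1.4826 * apply(abs(X[, idx, drop = FALSE] - Md), 1L, stats::median)
  bad <- dev > k * smad & smad > 0
  for (i in which(rowSums(bad) > 0)) {
    b <- bad[i, ]
    bi <- which(b); gi <- which(!b)
    if (length(gi) < 2L) next
    p <- findInterval(bi, gi)
    li <- gi[pmax(p, 1L)]; ri <- gi[pmin(p + 1L, length(gi))]
    w <- ifelse(ri > li, (bi - li) / (ri - li), 0)
    X[i, bi] <- X[i, li] * (1 - w) + X[i, ri] * w
  }
  X
}

#' Full EMG preprocessing for one grid recording
#'
#' Baseline-wander removal (lambda selected on the cross-channel mean when
#' `lambda = "auto"`; the smooth baseline is solved on a decimated grid
#' and interpolated), ECG template subtraction, and per-channel outlier
#' filling.
#'
#' @param samples channels x time matrix at `fs` Hz.
#' @param fs sampling rate.
#' @param lambda `"auto"` or positive numeric.
#' @param mad_k outlier threshold in scaled MADs.
#' @param outlier_window moving-median window (odd samples).
#' @return cleaned channels x time matrix.
#' @export
preprocess_grid <- function(samples, fs = 2048, lambda = "auto", mad_k = 3,
                            outlier_window = 2049L) {
  X <- t(as.matrix(samples))            # time x channels for batched solve
  if (identical(lambda, "auto"))
    lambda <- select_lambda(rowMeans(X), grid = baseline_lambda_grid(fs))
  X <- X - whittaker_baseline(X, lambda, decimate = 8L)
  cleaned <- remove_ecg(t(X), fs = fs)
  .fill_outliers_matrix(cleaned, outlier_window, mad_k)
}
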