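#' Critical correlation for a given sample size and alpha
#'
#' The smallest |r| significant in a two-tailed Student t test of a
#' Pearson correlation: `r* = t* / sqrt(t*^2 + n - 2)` with `t*` the
#' two-tailed critical value at `df = n - 2`. Rounded only for display
#' (e.g. `r*(46, 0.05) = 0.29` at two decimals).
#'
#' @param n sample size (>= 3).
#' @param alpha significance level in (0, 1).
#' @return critical |r| (unrounded).
#' @export
critical_correlation <- function(n, alpha) {
  if (n < 3) stop("n must be >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  tstar <- stats::qt(1 - alpha / 2, df = n - 2)
  tstar / sqrt(tstar^2 + n - 2)
}

#' Critical-correlation table for the standard significance tiers
#'
#' @param n sample size.
#' @param alphas significance tiers (default 0.05, 0.01, 0.005, 0.001,
#'   starred `*`, `**`, `+`, `++` in reports).
#' @return named numeric vector of critical |r| values.
#' @export
critical_table <- function(n, alphas = c(0.05, 0.01, 0.005, 0.001)) {
  stats::setNames(vapply(alphas, function(a) critical_correlation(n, a),
                         numeric(1)), format(alphas))
}

#' Ensemble choice of the number of factors
#'
#' Runs four scree-based retention rules on the correlation-matrix
#' eigenvalues -- Kaiser (eigenvalue > 1), Horn parallel analysis
#' (Monte-Carlo mean-eigenvalue criterion), optimal coordinates and
#' acceleration factor -- and returns the rounded mean of the four counts.
#'
#' @param data numeric matrix/data.frame (rows = observations).
#' @param n_sim parallel-analysis replicates.
#' @param seed seed for the parallel-analysis Monte-Carlo.
#' @return integer factor count; attribute `"counts"` has the four votes.
#' @export
n_factors_ensemble <- function(data, n_sim = 100L, seed = 1L) {
  x <- as.matrix(data)
  if (ncol(x) < 2L || nrow(x) < 3L) stop("need >= 2 variables and >= 3 rows")
  R <- stats::cor(x)
  if (!all(is.finite(R)) || rcond(R) < 1e-12)
    stop("singular correlation matrix")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  p <- length(ev); n <- nrow(x)

  n_kaiser <- sum(ev > 1)

  set.seed(seed)
  sim <- matrix(0, n_sim, p)
  for (s in seq_len(n_sim)) {
    sim[s, ] <- eigen(stats::cor(matrix(stats::rnorm(n * p), n, p)),
                      symmetric = TRUE, only.values = TRUE)$values
  }
  pa_ok <- ev > colMeans(sim)
  n_pa <- if (pa_ok[1]) which.min(c(pa_ok, FALSE)) - 1L else 0L

  # optimal coordinates: predicted eigenvalue at i by extrapolating the
  # line through (i + 1, ev[i+1]) and (p, ev[p]); count while observed
  # exceeds predicted
  n_oc <- 0L
  for (i in seq_len(p - 2L)) {
    slope <- (ev[p] - ev[i + 1]) / (p - (i + 1))
    pred <- ev[i + 1] + slope * (i - (i + 1))
    if (ev[i] >= pred && ev[i] > 1) n_oc <- i else break
  }
  n_oc <- max(n_oc, 1L)

  # acceleration factor: largest second difference of the scree
  af <- ev[seq_len(p - 2L)] - 2 * ev[seq_len(p - 2L) + 1L] + ev[seq_len(p - 2L) + 2L]
  n_af <- max(1L, which.max(af))

  counts <- c(kaiser = n_kaiser, parallel = n_pa, oc = n_oc, af = n_af)
  structure(as.integer(round(mean(counts))), counts = counts)
}

#' Maximum-likelihood factor extraction
#'
#' Unrotated ML factor solution of the correlation matrix (the classic
#' normal-theory maximum-likelihood factor model). Heywood cases are
#' bounded at a small uniqueness floor with a warning.
#'
#' @param data numeric matrix/data.frame.
#' @param n_factors number of factors (>= 1, < number of variables).
#' @return list with `loadings` (variables x factors), `uniquenesses`,
#'   `converged`.
#' @export
fit_fa_ml <- function(data, n_factors) {
  x <- as.matrix(data)
  if (n_factors < 1) stop("n_factors must be >= 1")
  if (n_factors >= ncol(x)) stop("n_factors must be below the variable count")
  R <- stats::cor(x)
  try_fit <- function(k, ridge = 0) {
    Rk <- R * (1 - ridge) + diag(ridge, ncol(R))
    tryCatch(stats::factanal(covmat = Rk, n.obs = nrow(x), factors = k,
                             rotation = "none",
                             control = list(nstart = 5, lower = 0.005)),
             error = function(e) NULL)
  }
  fit <- NULL
  k <- n_factors
  while (is.null(fit) && k >= 1L) {
    fit <- try_fit(k)
    # small samples with near-collinear variables can defeat the
    # optimizer; a light ridge on the correlation matrix stabilizes it
    if (is.null(fit)) fit <- try_fit(k, ridge = 0.02)
    if (is.null(fit)) k <- k - 1L
  }
  if (is.null(fit)) stop("maximum-likelihood factor extraction failed")
  if (k < n_factors)
    warning(sprintf("reduced the factor count from %d to %d for a stable fit",
                    n_factors, k))
  u <- fit$uniquenesses
  if (any(u <= 0.005 + 1e-9))
    warning("Heywood case: uniqueness bounded at the 0.005 floor")
  L <- unclass(fit$loadings)
  attr(L, "dimnames") <- list(colnames(x), paste0("F", seq_len(ncol(L))))
  list(loadings = L, uniquenesses = u, converged = fit$converged %||% TRUE)
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the varimax simplicity criterion; with a
#' single factor the loadings are returned unchanged. The rotated loadings
#' reproduce the same common-variance structure
#' (`L L'` is invariant).
#'
#' @param loadings variables x factors matrix.
#' @return rotated loadings matrix.
#' @export
varimax_rotate <- function(loadings) {
  L <- as.matrix(loadings)
  if (ncol(L) < 2L) return(L)
  r <- stats::varimax(L)
  out <- L %*% r$rotmat
  dimnames(out) <- dimnames(L)
  out
}

#' Variables used in the per-movement factor analysis
#'
#' Builds the 13-variable input for one movement x speed: age, group, sex,
#' BMI, the axis-of-interest shoulder movement-strategy pair (maximum
#' amplitude and time-to-maximum, or maximum angle and time-to-maximum
#' angle for rotation movements), trajectory sample entropy, inter- and
#' intra-subject variation, the two lower-back EMG grid entropies, the
#' global EMG centroid Y position and the zero-centred GFR ratio.
#' The default axis of interest is Y for back extension and the rotations
#' and Z for back flexion and the lateral flexions; `axis` overrides it
#' (the Z -> Y -> X fallback used when no significant group component
#' emerges).
#'
#' @param table feature table from [build_feature_table()].
#' @param movement,speed condition to analyse.
#' @param axis `"auto"` or one of `"x"`, `"y"`, `"z"`.
#' @return data.frame, one row per subject; missing values mean-imputed
#'   (count in attribute `"n_imputed"`).
#' @export
fa_input <- function(table, movement, speed, axis = "auto") {
  movement <- match.arg(movement, movement_levels())
  speed <- match.arg(speed, speed_levels())
  if (axis == "auto")
    axis <- if (movement %in% c("back_flexion", "lat_flex_left",
                                "lat_flex_right")) "z" else "y"
  sub <- table[table$movement == movement & table$speed == speed, ]
  if (!nrow(sub)) stop("no rows for ", movement, "/", speed)
  sh <- function(stem) sub[[paste0("traj_", stem, "_left_shoulder_", axis)]]
  rot <- movement %in% c("rot_left", "rot_right")
  out <- data.frame(
    age = sub$age, group = sub$group, sex = sub$sex, bmi = sub$bmi,
    max_rom = if (rot) sub$angle_max_shoulder_z else sh("maxamp"),
    time_to_max_rom = if (rot) sub$angle_t2max_shoulder_z else sh("t2max"),
    traj_entropy = sh("sampen"),
    traj_intervar = sh("intervar"),
    traj_intravar = sh("intravar"),
    emg_entropy_l_low = sub$emg_entropy_left_lower,
    emg_entropy_r_low = sub$emg_entropy_right_lower,
    emg_centroid_y = sub$emg_centroid_global_y,
    gfr_fa = sub$gfr_fa)
  n_imp <- 0L
  for (j in seq_along(out)) if (anyNA(out[[j]])) {
    n_imp <- n_imp + sum(is.na(out[[j]]))
    out[[j]][is.na(out[[j]])] <- mean(out[[j]], na.rm = TRUE)
  }
  attr(out, "n_imputed") <- n_imp
  attr(out, "axis") <- axis
  out
}

#' Per-movement exploratory factor analysis
#'
#' Ensemble factor count, maximum-likelihood extraction, varimax rotation,
#' and per-loading significance flags against the critical-correlation
#' tiers for the realized sample size.
#'
#' @param data FA input (one row per subject), e.g. from [fa_input()].
#' @param n_factors `NULL` for the ensemble choice.
#' @param seed seed for the parallel-analysis Monte-Carlo.
#' @return an `fa_result`: `n_factors`, rotated `loadings`, `signif`
#'   (character matrix of stars), `critical` table, `n`.
#' @export
run_factor_analysis <- function(data, n_factors = NULL, seed = 1L) {
  x <- as.matrix(data)
  n <- nrow(x)
  if (is.null(n_factors)) n_factors <- as.integer(n_factors_ensemble(x, seed = seed))
  n_factors <- max(1L, min(n_factors, ncol(x) - 1L))
  fit <- fit_fa_ml(x, n_factors)
  L <- varimax_rotate(fit$loadings)
  n_factors <- ncol(L)   # may have been reduced for a stable fit
  crit <- critical_table(n)
  stars <- c("*", "**", "+", "++")
  sig <- matrix("", nrow(L), ncol(L), dimnames = dimnames(L))
  for (k in seq_along(crit))
    sig[abs(L) >= crit[k]] <- stars[k]
  structure(list(n_factors = n_factors, loadings = L, signif = sig,
                 uniquenesses = fit$uniquenesses, critical = crit, n = n),
            class = "fa_result")
}

#' Locate the group-loaded component
#'
#' Selects the rotated component with the largest |loading| on the group
#' variable, flags it significant iff that loading reaches the 0.05
#' critical correlation for the sample size (boundary values count as
#' significant), and lists all co-loading variables that exceed their own
#' significance tiers.
#'
#' @param result an `fa_result` whose input contained a `group` variable.
#' @param group_var name of the group variable.
#' @return list: `component`, `group_loading`, `significant`,
#'   `co_loadings` (data.frame variable/loading/stars).
#' @export
find_group_component <- function(result, group_var = "group") {
  L <- result$loadings
  if (!group_var %in% rownames(L)) stop("no '", group_var, "' variable in the FA")
  gl <- L[group_var, ]
  j <- which.max(abs(gl))
  significant <- abs(gl[j]) >= result$critical[[1]]  # the 0.05 tier
  co <- data.frame(variable = rownames(L), loading = L[, j],
                   stars = result$signif[, j], row.names = NULL)
  co <- co[co$variable != group_var & co$stars != "", , drop = FALSE]
  co <- co[order(-abs(co$loading)), , drop = FALSE]
  list(component = unname(j), group_loading = unname(gl[j]),
       significant = significant, co_loadings = co)
}
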