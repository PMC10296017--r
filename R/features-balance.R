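#' Self-normalize a statokinesigram
#'
#' Centers the planar centre-of-pressure (COP) trace on its mean and
#' divides both axes by the mean resultant distance from the centre, so the
#' output cloud has mean radius 1 (dimensionless units). This removes the
#' large inter-/intra-subject scale differences of raw sway measures.
#'
#' @param cop_x,cop_y paired COP coordinate series (same length, >= 2).
#' @return list with normalized `cop_x`, `cop_y`.
#' @export
normalize_statokinesigram <- function(cop_x, cop_y) {
  if (length(cop_x) != length(cop_y)) stop("cop_x and cop_y lengths differ")
  if (length(cop_x) < 2L) stop("need at least 2 samples")
  x <- cop_x - mean(cop_x); y <- cop_y - mean(cop_y)
  mr <- mean(sqrt(x^2 + y^2))
  if (mr <= 0) stop("degenerate statokinesigram: no sway")
  list(cop_x = x / mr, cop_y = y / mr)
}

#' 95% prediction-ellipse area of a COP trace
#'
#' Area of the ellipse expected to contain 95% of the sway points under a
#' bivariate Gaussian model: `pi * sqrt(l1 * l2) * q` with `l1, l2` the
#' eigenvalues of the sample covariance and `q = qchisq(0.95, 2) = 5.991`.
#' Dynamic repetitions are typically far shorter than the 90 s recommended
#' for stabilometry; a below-standard-duration warning is emitted when a
#' sampling rate is supplied and the trace is shorter than 90 s.
#'
#' @param cop_x,cop_y paired COP series (>= 10 samples).
#' @param fs optional sampling rate (Hz) used only for the duration check.
#' @return scalar area (input units squared).
#' @export
ellipse_area_95 <- function(cop_x, cop_y, fs = NULL) {
  if (length(cop_x) != length(cop_y)) stop("cop_x and cop_y lengths differ")
  if (length(cop_x) < 10L) stop("need at least 10 samples")
  if (!is.null(fs) && length(cop_x) / fs < 90)
    warning(sprintf("trace is %.1f s, below the 90 s stabilometry standard",
                    length(cop_x) / fs))
  S <- stats::cov(cbind(cop_x, cop_y))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) stop("rank-deficient COP covariance")
  pi * sqrt(prod(ev)) * stats::qchisq(0.95, 2)
}

#' Ground-reaction-force ratio
#'
#' Mean over samples of the samplewise left/right vertical force ratio.
#' Samples where the right force is not positive (after any loading
#' threshold applied upstream) are excluded with a warning; if all samples
#' are excluded an error is raised.
#'
#' @param left,right vertical ground-reaction-force series, equal length.
#' @return scalar ratio (1 = balanced stance).
#' @export
gfr_ratio <- function(left, right) {
  if (length(left) != length(right)) stop("left and right lengths differ")
  ok <- right > 0
  if (!any(ok)) stop("no samples with positive right-side loading")
  if (!all(ok))
    warning(sprintf("excluded %d samples with non-positive right GFR", sum(!ok)))
  mean(left[ok] / right[ok])
}

#' Zero-centred GFR ratio used in factor analysis
#'
#' `|ratio| - 1`: balanced stance maps to 0 and deviations are not
#' side-oriented.
#' @param ratio a GFR ratio.
#' @return scalar.
#' @export
gfr_fa_transform <- function(ratio) {
  if (!is.finite(ratio)) stop("ratio must be finite")
  abs(ratio) - 1
}
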