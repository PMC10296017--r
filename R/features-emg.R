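#' Per-electrode RMS map
#'
#' Computes the root-mean-square value of each channel of one repetition and
#' maps it onto the populated positions of the grid layout.
#'
#' @param rep numeric matrix, channels x time; channels in the layout's
#'   row-major electrode order.
#' @param layout a [grid_layout()].
#' @return an `rms_map`: list with `values` (per-channel RMS, >= 0),
#'   `matrix` (n_rows x n_cols, NA at unpopulated positions) and the layout.
#' @export
electrode_rms <- function(rep, layout = grid_layout()) {
  rep <- as.matrix(rep)
  if (ncol(rep) < 1L) stop("at least one sample per channel is required")
  if (nrow(rep) != layout$n_channels)
    stop(sprintf("channel count (%d) does not match layout (%d populated positions)",
                 nrow(rep), layout$n_channels))
  vals <- sqrt(rowMeans(rep^2))
  m <- matrix(NA_real_, layout$n_rows, layout$n_cols)
  pos <- electrode_positions(layout, "index")
  m[cbind(pos$row, pos$col)] <- vals
  structure(list(values = vals, matrix = m, layout = layout),
            class = "rms_map")
}

#' RMS map from explicit values
#'
#' Convenience constructor used by tests and toy examples.
#' @param values per-electrode RMS values in row-major layout order.
#' @param layout a [grid_layout()].
#' @return an `rms_map`.
#' @export
rms_map <- function(values, layout = grid_layout()) {
  if (length(values) != layout$n_channels)
    stop("length(values) must equal the number of populated positions")
  if (any(!is.finite(values)) || any(values < 0))
    stop("RMS values must be finite and non-negative")
  m <- matrix(NA_real_, layout$n_rows, layout$n_cols)
  pos <- electrode_positions(layout, "index")
  m[cbind(pos$row, pos$col)] <- values
  structure(list(values = as.numeric(values), matrix = m, layout = layout),
            class = "rms_map")
}

#' Activity centroid of one electrode grid
#'
#' RMS-weighted barycenter of the grid in electrode-index units: the x
#' coordinate is the weighted mean column index (1..n_cols, medio-lateral)
#' and the y coordinate the weighted mean row index (1..n_rows,
#' cranio-caudal, larger = more cranial). Weights are the per-electrode RMS
#' values normalized to sum one. Callers average per-repetition centroids
#' to obtain the per-movement value.
#'
#' @param map an `rms_map`.
#' @return list with `x`, `y`.
#' @export
grid_centroid <- function(map) {
  stopifnot(inherits(map, "rms_map"))
  tot <- sum(map$values)
  if (tot <= 0) stop("no activity: all-zero RMS map")
  pos <- electrode_positions(map$layout, "index")
  w <- map$values / tot
  list(x = sum(w * pos$col), y = sum(w * pos$row))
}

#' Global activity centroid over several grids
#'
#' Converts each grid centroid to millimetres in the common back frame
#' (using the grid's offset and left/right mirroring), then combines them
#' as a weighted mean with weights equal to each grid's total RMS.
#'
#' @param maps list of `rms_map` objects whose layouts carry offsets.
#' @return list with `x`, `y` in millimetres.
#' @export
global_centroid <- function(maps) {
  stopifnot(length(maps) >= 1L)
  tots <- vapply(maps, function(m) sum(m$values), numeric(1))
  if (all(tots <= 0)) stop("no activity: all grids silent")
  keep <- tots > 0
  cx <- cy <- numeric(sum(keep))
  i <- 0L
  for (m in maps[keep]) {
    i <- i + 1L
    pos <- electrode_positions(m$layout, "mm")
    w <- m$values / sum(m$values)
    cx[i] <- sum(w * pos$x)
    cy[i] <- sum(w * pos$y)
  }
  w <- tots[keep] / sum(tots[keep])
  list(x = sum(w * cx), y = sum(w * cy))
}

#' Spatial entropy of an activity map
#'
#' Shannon entropy (nats) of the RMS-power distribution over electrodes:
#' `p_i = n_i^2 / sum(n_j^2)`, `H = -sum(p_i log p_i)`. High entropy means
#' diffuse activity across the patch, low entropy focal activity; the
#' maximum is `log` of the electrode count. `raw = TRUE` returns the
#' unnormalized signless sum `sum(n_i^2 log n_i^2)` instead, for
#' comparability with conventions that skip the probability normalization.
#'
#' @param map an `rms_map`.
#' @param raw logical; see above.
#' @return entropy in nats (scalar).
#' @export
grid_entropy <- function(map, raw = FALSE) {
  stopifnot(inherits(map, "rms_map"))
  n2 <- map$values^2
  tot <- sum(n2)
  if (tot <= 0) stop("no activity: all-zero RMS map")
  if (raw) {
    nz <- n2 > 0
    return(sum(n2[nz] * log(n2[nz])))
  }
  p <- n2 / tot
  p <- p[p > 0]
  -sum(p * log(p))
}
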