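#' Electrode grid layout for a 13 x 5 HD-EMG patch
#'
#' Describes one adhesive electrode matrix: 13 rows along the cranio-caudal
#' axis, 5 columns along the medio-lateral axis, 8 mm inter-electrode
#' distance. The commercial patch carries 63 electrodes on the 65 grid
#' positions; which two positions are unpopulated is configurable (default:
#' two opposite corners, positions (1,1) and (13,5)).
#'
#' Grid offsets place the patch in a common back frame whose origin `[0,0]`
#' is the junction point of the four patches: left patches have x < 0,
#' right x > 0, lower y < 0, upper y > 0. Within a patch, row index grows
#' cranially (toward the head) and column index grows away from the spine.
#'
#' @param n_rows,n_cols grid dimensions (rows = cranio-caudal).
#' @param populated logical `n_rows x n_cols` matrix marking populated
#'   electrode positions; default leaves corners (1,1) and (13,5) empty.
#' @param inter_electrode_mm electrode pitch in millimetres.
#' @param x_off,y_off offset (mm) of the grid's row-1/column-1 electrode in
#'   the common back frame.
#' @param grid_id one of `"left_lower"`, `"left_upper"`, `"right_lower"`,
#'   `"right_upper"`, or `"single"` for a free-standing patch.
#' @return an object of class `grid_layout`.
#' @export
grid_layout <- function(n_rows = 13L, n_cols = 5L, populated = NULL,
                        inter_electrode_mm = 8, x_off = 0, y_off = 0,
                        grid_id = "single") {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be positive")
  if (is.null(populated)) {
    populated <- matrix(TRUE, n_rows, n_cols)
    if (n_rows == 13L && n_cols == 5L) {
      # default mask: 63 of 65 positions populated, opposite corners empty
      populated[1L, 1L] <- FALSE
      populated[n_rows, n_cols] <- FALSE
    }
  }
  populated <- matrix(as.logical(populated), n_rows, n_cols)
  if (anyNA(populated)) stop("populated mask must be logical with no NA")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, populated = populated,
         n_channels = sum(populated),
         inter_electrode_mm = inter_electrode_mm,
         x_off = x_off, y_off = y_off, grid_id = grid_id),
    class = "grid_layout")
}

#' Four-patch layout set covering the lower back
#'
#' Builds the standard arrangement of four patches (left/right, lower/upper)
#' around the common-frame origin, mirrored left/right so that columns grow
#' away from the spine on both sides.
#'
#' @param inter_electrode_mm electrode pitch in millimetres.
#' @param gap_mm clearance between a patch edge and the frame origin, on
#'   both axes.
#' @return named list of four `grid_layout` objects, in order
#'   `left_lower`, `left_upper`, `right_lower`, `right_upper`.
#' @export
back_grid_set <- function(inter_electrode_mm = 8, gap_mm = 10) {
  d <- inter_electrode_mm
  span_r <- 12 * d  # 13 rows
  span_c <- 4 * d   # 5 cols
  mk <- function(id, xs, ys) {
    grid_layout(inter_electrode_mm = d, x_off = xs, y_off = ys, grid_id = id)
  }
  list(
    left_lower  = mk("left_lower",  -gap_mm - span_c, -gap_mm - span_r),
    left_upper  = mk("left_upper",  -gap_mm - span_c,  gap_mm),
    right_lower = mk("right_lower",  gap_mm,          -gap_mm - span_r),
    right_upper = mk("right_upper",  gap_mm,           gap_mm))
}

#' Electrode positions of a layout
#'
#' @param layout a `grid_layout`.
#' @param frame `"index"` for (col, row) electrode indices, `"mm"` for
#'   positions in the common back frame (left grids mirrored so x is
#'   negative and grows toward the spine).
#' @return data.frame with one row per populated electrode, in row-major
#'   (row, then column) order, columns `row`, `col`, `x`, `y`.
#' @export
electrode_positions <- function(layout, frame = c("index", "mm")) {
  frame <- match.arg(frame)
  stopifnot(inherits(layout, "grid_layout"))
  idx <- which(t(layout$populated), arr.ind = TRUE)  # row-major order
  col <- idx[, 1L]; row <- idx[, 2L]
  if (frame == "index") {
    return(data.frame(row = row, col = col, x = col, y = row))
  }
  d <- layout$inter_electrode_mm
  left <- grepl("^left", layout$grid_id)
  # mirror left grids: column 1 sits nearest the spine on both sides
  x <- if (left) layout$x_off + (layout$n_cols - col) * d
       else layout$x_off + (col - 1) * d
  y <- layout$y_off + (row - 1) * d
  data.frame(row = row, col = col, x = x, y = y)
}
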