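#' Rectangular gridded study-plot geometry
#'
#' Describes one survey plot: a rectangular window subdivided into a regular
#' grid of square cells. The default is the classic cacao-plantation layout:
#' a 12 m x 9 m plot of forty-eight 1.5 m x 1.5 m cells (8 columns x 6 rows).
#' Area and perimeter are derived and carried along because the
#' border-corrected Clark-Evans expectation needs both.
#'
#' @param width Plot width in metres (x extent).
#' @param height Plot height in metres (y extent).
#' @param cell_size Side length of one square grid cell in metres. Must
#'   divide both `width` and `height` exactly.
#'
#' @return An object of class `"plot_geometry"`: a list with elements
#'   `width`, `height`, `cell_size`, `n_cols`, `n_rows`, `n_cells`,
#'   `area` (m^2) and `perimeter` (m).
#' @examples
#' geom <- plot_geometry()
#' geom$n_cells # 48
#' @export
plot_geometry <- function(width = 12, height = 9, cell_size = 1.5) {
  stopifnot(is.numeric(width), is.numeric(height), is.numeric(cell_size),
            length(width) == 1L, length(height) == 1L, length(cell_size) == 1L,
            width > 0, height > 0, cell_size > 0)
  n_cols <- width / cell_size
  n_rows <- height / cell_size
  if (abs(n_cols - round(n_cols)) > 1e-9 || abs(n_rows - round(n_rows)) > 1e-9)
    stop("cell_size must divide both width and height exactly", call. = FALSE)
  n_cols <- as.integer(round(n_cols))
  n_rows <- as.integer(round(n_rows))
  structure(list(
    width = width, height = height, cell_size = cell_size,
    n_cols = n_cols, n_rows = n_rows, n_cells = n_cols * n_rows,
    area = width * height, perimeter = 2 * (width + height)
  ), class = "plot_geometry")
}

#' @export
print.plot_geometry <- function(x, ...) {
  cat(sprintf("Gridded plot: %g m x %g m (%d x %d cells of %g m; %d cells)\n",
              x$width, x$height, x$n_cols, x$n_rows, x$cell_size, x$n_cells))
  cat(sprintf("  area %g m^2, perimeter %g m\n", x$area, x$perimeter))
  invisible(x)
}

#' Centre coordinates of grid cells
#'
#' Maps 0-based cell indices to the planar coordinates of the cell centre.
#' The cell centre is the canonical point location for a capture: positions
#' are only resolved to the cell, and the centre is the unbiased
#' representative point.
#'
#' @param cell_row,cell_col Integer vectors of 0-based row/column indices
#'   (recycled to a common length).
#' @param geometry A [plot_geometry()] object.
#'
#' @return A data frame with numeric columns `x` and `y` (metres).
#' @examples
#' cell_center(0, 0)          # (0.75, 0.75)
#' cell_center(5, 7)          # (11.25, 8.25)
#' @export
cell_center <- function(cell_row, cell_col, geometry = plot_geometry()) {
  n <- max(length(cell_row), length(cell_col))
  cell_row <- rep_len(as.integer(cell_row), n)
  cell_col <- rep_len(as.integer(cell_col), n)
  bad <- cell_row < 0L | cell_row >= geometry$n_rows |
    cell_col < 0L | cell_col >= geometry$n_cols
  if (any(bad))
    stop(sprintf(
      "cell index out of range (row must be in [0, %d], col in [0, %d]): first offender row=%d col=%d",
      geometry$n_rows - 1L, geometry$n_cols - 1L,
      cell_row[which(bad)[1]], cell_col[which(bad)[1]]), call. = FALSE)
  data.frame(x = (cell_col + 0.5) * geometry$cell_size,
             y = (cell_row + 0.5) * geometry$cell_size)
}

#' Grid cell containing a point
#'
#' Inverse of [cell_center()] up to within-cell position: maps continuous
#' coordinates to 0-based cell indices, with points on the far boundary
#' assigned to the last cell.
#'
#' @param x,y Numeric coordinate vectors (metres), inside the window.
#' @param geometry A [plot_geometry()] object.
#' @return A data frame with integer columns `cell_row` and `cell_col`.
#' @export
cell_of_point <- function(x, y, geometry = plot_geometry()) {
  if (any(x < 0 | x > geometry$width | y < 0 | y > geometry$height))
    stop("point outside the plot window", call. = FALSE)
  data.frame(
    cell_row = pmin(as.integer(floor(y / geometry$cell_size)), geometry$n_rows - 1L),
    cell_col = pmin(as.integer(floor(x / geometry$cell_size)), geometry$n_cols - 1L)
  )
}

# distance from each point to the nearest window edge
border_distance <- function(x, y, geometry) {
  pmin(x, geometry$width - x, y, geometry$height - y)
}
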