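#' Create a regular grid
#'
#' @param n_rows,n_cols Grid dimensions (positive integers). Row 1 is the
#'   southern edge of the domain.
#' @param cell_size Cell edge length in km (default 30).
#' @return A [Grid-class] object.
#' @examples
#' g <- makeGrid(10, 10, 30)
#' nCells(g)
#' @export
makeGrid <- function(n_rows, n_cols, cell_size = 30) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1)
    stop("grid dimensions must be positive integers")
  new("Grid", n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_size = as.numeric(cell_size))
}

#' Number of cells of a grid
#' @param grid A [Grid-class].
#' @return Integer cell count.
#' @export
nCells <- function(grid) grid@n_rows * grid@n_cols

#' Cell index from (row, col) and back
#'
#' Cells are numbered in row-major order; `cellAt()` and `rowColAt()` are
#' inverse bijections.
#'
#' @param grid A [Grid-class].
#' @param row,col Row and column indices (vectorised).
#' @return `cellAt()`: integer cell indices. `rowColAt()`: a data.frame with
#'   columns `row` and `col`.
#' @export
cellAt <- function(grid, row, col) {
  stopifnot(all(row >= 1L & row <= grid@n_rows),
            all(col >= 1L & col <= grid@n_cols))
  as.integer((row - 1L) * grid@n_cols + col)
}

#' @param cell Integer cell indices (vectorised).
#' @rdname cellAt
#' @export
rowColAt <- function(grid, cell) {
  stopifnot(all(cell >= 1L & cell <= nCells(grid)))
  cell <- as.integer(cell)
  data.frame(row = (cell - 1L) %/% grid@n_cols + 1L,
             col = (cell - 1L) %% grid@n_cols + 1L)
}

#' Latitude proxy of cells
#'
#' Row-normalised scalar in `[0, 1]`: 0 at the southern edge (row 1), 1 at
#' the northern edge, 0.5 for a single-row grid.
#'
#' @param grid A [Grid-class].
#' @param cell Integer cell indices; defaults to all cells.
#' @return Numeric vector of latitude proxies.
#' @export
latitudeProxy <- function(grid, cell = seq_len(nCells(grid))) {
  row <- rowColAt(grid, cell)$row
  if (grid@n_rows == 1L) rep(0.5, length(row)) else (row - 1) / (grid@n_rows - 1)
}

## Rook neighbours of each cell (list of integer vectors), used by movement.
gridNeighbors <- function(grid) {
  rc <- rowColAt(grid, seq_len(nCells(grid)))
  lapply(seq_len(nCells(grid)), function(i) {
    r <- rc$row[i]; cl <- rc$col[i]
    nb <- rbind(
      if (r > 1L) c(r - 1L, cl),
      if (r < grid@n_rows) c(r + 1L, cl),
      if (cl > 1L) c(r, cl - 1L),
      if (cl < grid@n_cols) c(r, cl + 1L)
    )
    if (is.null(nb)) integer(0) else cellAt(grid, nb[, 1], nb[, 2])
  })
}

#' @describeIn makeGrid Display a grid.
#' @param object A [Grid-class].
#' @export
setMethod("show", "Grid", function(object) {
  cat(sprintf("Grid: %d x %d cells of %g km (%d cells, %g km2 each)\n",
              object@n_rows, object@n_cols, object@cell_size,
              nCells(object), object@cell_size^2))
  invisible(object)
})
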