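#' Georeferenced raster grid
#'
#' Minimal matrix-backed raster container used throughout the package. Values
#' are stored as a numeric matrix with row 1 at the northern edge; the affine
#' placement contract is: cell (r, c) has centre
#' \code{x = xmin + (c - 0.5) * cell_size},
#' \code{y = ymin + (nrow - r + 0.5) * cell_size}.
#'
#' @param values numeric matrix (row 1 = north).
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric length-2, (xmin, ymin) of the grid's lower-left corner.
#' @param nodata value treated as missing; converted to NA on construction.
#' @return an object of class \code{river_grid}.
#' @export
river_grid <- function(values, cell_size, origin = c(0, 0), nodata = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L) stop("`origin` must have length 2")
  if (!is.null(nodata)) values[values == nodata] <- NA_real_
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "river_grid")
}

#' @export
print.river_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<river_grid> %d x %d cells, cell %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], NA cells: %d\n", rng[1], rng[2],
              sum(is.na(v))))
  invisible(x)
}

#' @export
dim.river_grid <- function(x) dim(x$values)

## cell index <-> coordinate helpers (column-major linear index)
grid_rc <- function(grid, idx) {
  nr <- nrow(grid$values)
  cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
}

grid_idx <- function(grid, row, col) (col - 1L) * nrow(grid$values) + row

#' Cell-centre coordinates
#'
#' @param grid a \code{river_grid}.
#' @param idx optional vector of column-major cell indices; default all cells.
#' @return matrix with columns x, y.
#' @export
grid_xy <- function(grid, idx = seq_along(grid$values)) {
  rc <- grid_rc(grid, idx)
  nr <- nrow(grid$values)
  cbind(x = grid$origin[1] + (rc[, "col"] - 0.5) * grid$cell_size,
        y = grid$origin[2] + (nr - rc[, "row"] + 0.5) * grid$cell_size)
}

#' Map coordinates to cell indices
#'
#' @param grid a \code{river_grid}.
#' @param x,y coordinate vectors.
#' @return column-major cell indices; NA for points outside the grid.
#' @export
grid_cell_at <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  col <- floor((x - grid$origin[1]) / cs) + 1L
  row <- nr - floor((y - grid$origin[2]) / cs)
  ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
  out <- rep(NA_integer_, length(x))
  out[ok] <- grid_idx(grid, row[ok], col[ok])
  out
}

stopifnot_same_geometry <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(a$cell_size, b$cell_size)) ||
      !isTRUE(all.equal(a$origin, b$origin)))
    stop("grids are not aligned (dimension, cell size or origin differ)")
  invisible(TRUE)
}

## D8 neighbour scheme. Precedence order (used for deterministic tie-breaks):
## E, SE, S, SW, W, NW, N, NE. Codes 1..8 in that order; 0 marks an outlet.
D8_DR <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
D8_DIST <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

#' Block-mean aggregation of a grid
#'
#' @param grid a \code{river_grid} whose dimensions are divisible by `factor`.
#' @param factor integer aggregation ratio.
#' @return a coarser \code{river_grid}; each coarse cell is the mean of its
#'   `factor` x `factor` fine block (NAs removed).
#' @export
aggregate_grid <- function(grid, factor) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr %% factor != 0L || nc %% factor != 0L)
    stop("aggregation factor must divide the grid dimensions")
  nrc <- nr %/% factor; ncc <- nc %/% factor
  a <- array(v, dim = c(factor, nrc, factor, ncc))
  out <- apply(a, c(2, 4), mean, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  river_grid(out, grid$cell_size * factor, grid$origin)
}

#' Write / read a grid as an ESRI ASCII raster
#'
#' Plain-text interchange format readable by GDAL and most GIS software.
#'
#' @param grid a \code{river_grid}.
#' @param path file path (conventionally `.asc`).
#' @param nodata value written for NA cells.
#' @return `path`, invisibly (writer); a \code{river_grid} (reader).
#' @export
write_asc_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", grid$origin[2]),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %g", nodata))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_asc_grid
#' @export
read_asc_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(tolower(hdr), "\\s+")
  vals <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
  names(vals) <- vapply(kv, `[`, "", 1L)
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  river_grid(m, vals[["cellsize"]],
             c(vals[["xllcorner"]], vals[["yllcorner"]]),
             nodata = vals[["nodata_value"]])
}
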