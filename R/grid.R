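#' Grid geometry of a raster
#'
#' Rows are numbered from the north (row 1 is the northernmost row, matching
#' the top line of an ESRI ASCII Grid body); indices are row-major. `origin`
#' is the (x, y) map coordinate of the top-left (north-west) corner.
#'
#' @param n_rows,n_cols Positive integers.
#' @param cell_size Cell edge length in metres (square cells).
#' @param origin Numeric length-2, (x, y) of the top-left corner.
#' @return An object of class `lu_geometry`.
#' @export
lu_geometry <- function(n_rows, n_cols, cell_size = 90, origin = c(0, 0)) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0, length(origin) == 2)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "lu_geometry")
}

#' Cell area in hectares
#'
#' @param geometry An `lu_geometry` (or an `lu_grid`, whose geometry is used).
#' @return Area of one cell in ha (`cell_size^2 / 10000`); a 90 m cell is
#'   0.81 ha.
#' @export
cell_area_ha <- function(geometry) {
  if (inherits(geometry, "lu_grid")) geometry <- geometry$geometry
  geometry$cell_size^2 / 1e4
}

#' Categorical land-use grid
#'
#' The central container: an integer lattice whose values are class codes of
#' a [lu_schema()]. Nodata cells are stored as `NA` internally; the schema's
#' nodata code is only used at the file boundary.
#'
#' @param values Integer matrix (`NA` = nodata) of schema codes.
#' @param schema An `lu_schema`.
#' @param geometry An `lu_geometry`; defaults to a 90 m grid at origin (0,0)
#'   shaped like `values`.
#' @return An object of class `lu_grid` with elements `values`, `schema`,
#'   `geometry`.
#' @examples
#' g <- lu_grid(matrix(c(1, 1, 3, 3), 2, 2), schema_7class())
#' class_areas(g)
#' @export
lu_grid <- function(values, schema, geometry = NULL) {
  if (!is.matrix(values)) stop("values must be a matrix")
  storage.mode(values) <- "integer"
  if (is.null(geometry))
    geometry <- lu_geometry(nrow(values), ncol(values))
  if (nrow(values) != geometry$n_rows || ncol(values) != geometry$n_cols)
    stop("values shape does not match geometry")
  bad <- !is.na(values) & !(values %in% schema$codes)
  if (any(bad)) {
    i <- which(bad)[1L]
    rc <- arrayInd(i, dim(values))
    stop(sprintf(
      "value %d at cell (row %d, col %d) is not a schema code",
      values[i], rc[1L], rc[2L]))
  }
  structure(list(values = values, schema = schema, geometry = geometry),
            class = "lu_grid")
}

#' @export
print.lu_grid <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<lu_grid> %d x %d cells, %g m, %d classes, %d nodata cells\n",
              g$n_rows, g$n_cols, g$cell_size, length(x$schema$codes),
              sum(is.na(x$values))))
  invisible(x)
}

geometries_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

#' Check that grids/layers share an identical geometry
#'
#' Co-registration in this package means bit-identical geometry: same shape,
#' cell size and origin. No resampling is performed anywhere.
#'
#' @param ... Two or more `lu_grid` / `lu_factor` / `lu_constraint` objects.
#' @return Invisibly `TRUE`; error on mismatch.
#' @export
check_coregistered <- function(...) {
  objs <- list(...)
  geoms <- lapply(objs, function(o) o$geometry)
  for (i in seq_along(geoms)[-1L]) {
    if (!geometries_identical(geoms[[1L]], geoms[[i]]))
      stop("grids are not co-registered (geometry mismatch)")
  }
  invisible(TRUE)
}
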