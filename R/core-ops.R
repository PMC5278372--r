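#' Reclassify a categorical grid
#'
#' Applies a total mapping over the schema codes cell-by-cell. Nodata is
#' preserved. The target schema defaults to the input schema; supply one
#' when the mapping merges classes (e.g. wetland + other unused -> unused,
#' see [schema_6class()]).
#'
#' @param grid An [lu_grid()].
#' @param mapping Named integer vector: `mapping[["old_code"]] = new_code`.
#'   Must cover every schema code.
#' @param schema Target [lu_schema()]; default `grid$schema`.
#' @return A reclassified `lu_grid`.
#' @examples
#' g <- lu_grid(matrix(c(1, 6, 7, 6), 2, 2), schema_7class())
#' m <- schema_6class()
#' class_areas(reclassify(g, m$mapping, m$schema))
#' @export
reclassify <- function(grid, mapping, schema = grid$schema) {
  codes <- grid$schema$codes
  miss <- setdiff(as.character(codes), names(mapping))
  if (length(miss))
    stop("mapping is not total: missing code(s) ", paste(miss, collapse = ", "))
  lut <- stats::setNames(as.integer(mapping[as.character(codes)]),
                         as.character(codes))
  v <- grid$values
  out <- v
  keep <- !is.na(v)
  out[keep] <- lut[as.character(v[keep])]
  lu_grid(out, schema, grid$geometry)
}

#' Per-class areas of a grid, in hectares
#'
#' `area(c) = count(c) * cell_area`; nodata cells are excluded.
#'
#' @param grid An [lu_grid()].
#' @return Named numeric vector of areas (ha), one entry per schema class
#'   (zero for absent classes).
#' @export
class_areas <- function(grid) {
  ca <- cell_area_ha(grid)
  cnt <- class_counts(grid)
  cnt * ca
}

#' @rdname class_areas
#' @return `class_counts()`: named integer vector of cell counts.
#' @export
class_counts <- function(grid) {
  codes <- grid$schema$codes
  tab <- tabulate(match(grid$values, codes), nbins = length(codes))
  stats::setNames(as.integer(tab), names(codes))
}

#' Cross-tabulate two co-registered grids into a transition matrix
#'
#' Entry (i, j) is the area (or cell count) of cells holding class i at time
#' 1 and class j at time 2. Cells that are nodata in either grid are
#' excluded. The diagonal is persistence; row margins are the time-1 class
#' areas and column margins the time-2 class areas of the jointly valid
#' cells.
#'
#' @param grid_t1,grid_t2 Co-registered [lu_grid()]s sharing a schema.
#' @param unit `"ha"` (default) or `"cells"`.
#' @return A numeric matrix of class `lu_transition` with class-name
#'   dimnames and a `unit` attribute.
#' @export
crosstab <- function(grid_t1, grid_t2, unit = c("ha", "cells")) {
  unit <- match.arg(unit)
  check_coregistered(grid_t1, grid_t2)
  if (!schemas_identical(grid_t1$schema, grid_t2$schema))
    stop("grids do not share a schema")
  codes <- grid_t1$schema$codes
  k <- length(codes)
  i <- match(grid_t1$values, codes)
  j <- match(grid_t2$values, codes)
  ok <- !is.na(i) & !is.na(j)
  tab <- tabulate((j[ok] - 1L) * k + i[ok], nbins = k * k)
  m <- matrix(as.numeric(tab), k, k,
              dimnames = list(names(codes), names(codes)))
  if (unit == "ha") m <- m * cell_area_ha(grid_t1)
  transition_matrix(m, unit)
}

#' Construct a transition matrix object
#'
#' @param m Square nonnegative numeric matrix with identical row/column
#'   class-name dimnames (initial year in rows, final year in columns).
#' @param unit `"ha"` or `"cells"`.
#' @return An `lu_transition`.
#' @export
transition_matrix <- function(m, unit = "ha") {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (any(m < 0)) stop("transition matrix entries must be >= 0")
  if (is.null(dimnames(m)) ||
      !identical(rownames(m), colnames(m)))
    stop("transition matrix needs identical row/column class names")
  structure(m, unit = unit, class = c("lu_transition", "matrix", "array"))
}

#' @export
print.lu_transition <- function(x, ...) {
  cat("<lu_transition> unit:", attr(x, "unit"), "\n")
  print(unclass(x)[,])
  invisible(x)
}

#' Change-trajectory analysis of a map series
#'
#' Labels every jointly valid cell with its ordered sequence of class codes
#' across the series, tabulates trajectory frequencies, and reports the
#' unchanged mask and, per class, the fraction of its initial-time cells
#' that kept the same class throughout.
#'
#' @param grids List of >= 2 co-registered [lu_grid()]s sharing a schema,
#'   in time order.
#' @return A list: `trajectory` (integer matrix of trajectory ids, `NA`
#'   where any input is nodata), `levels` (data.frame `id`, `sequence`
#'   like `"1-1-3"`, `count`), `unchanged` (logical matrix), and
#'   `unchanged_fraction` (named vector over classes; `NaN` for classes
#'   absent at time 1).
#' @export
trajectory_codes <- function(grids) {
  if (length(grids) < 2L) stop("need at least 2 grids for a trajectory")
  do.call(check_coregistered, grids)
  sch <- grids[[1L]]$schema
  for (g in grids[-1L])
    if (!schemas_identical(sch, g$schema)) stop("grids do not share a schema")
  vals <- lapply(grids, function(g) g$values)
  valid <- Reduce(`&`, lapply(vals, function(v) !is.na(v)))
  seqs <- do.call(paste, c(lapply(vals, as.vector), list(sep = "-")))
  seqs[!valid] <- NA_character_
  lev <- sort(unique(seqs[!is.na(seqs)]))
  ids <- match(seqs, lev)
  traj <- matrix(ids, nrow(vals[[1L]]), ncol(vals[[1L]]))
  counts <- tabulate(ids, nbins = length(lev))
  unchanged <- valid & Reduce(`&`, lapply(vals[-1L],
                                          function(v) v == vals[[1L]]))
  unchanged[!valid] <- FALSE
  codes <- sch$codes
  t1 <- vals[[1L]]
  frac <- vapply(codes, function(cd) {
    n <- sum(t1 == cd & valid, na.rm = TRUE)
    if (n == 0L) return(NaN)
    sum(unchanged & t1 == cd, na.rm = TRUE) / n
  }, numeric(1L))
  list(trajectory = traj,
       levels = data.frame(id = seq_along(lev), sequence = lev,
                           count = counts),
       unchanged = unchanged,
       unchanged_fraction = frac)
}

# Margin helpers for lu_transition.
initial_totals <- function(m) rowSums(m)
final_totals   <- function(m) colSums(m)
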