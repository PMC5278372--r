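#' Factor and constraint layers
#'
#' A factor is a continuous suitability surface standardised to the 0-255
#' fuzzy-membership range; a constraint is a binary layer where 0 excludes
#' a cell absolutely.
#'
#' @param values Numeric/integer matrix; factors must lie in \[0, 255\],
#'   constraints in \{0, 1\} (`NA` = nodata).
#' @param name Layer name.
#' @param geometry An [lu_geometry()]; defaults to a 90 m grid shaped like
#'   `values`.
#' @return An `lu_factor` / `lu_constraint` object.
#' @export
factor_layer <- function(values, name = "factor", geometry = NULL) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (any(values < 0 | values > 255, na.rm = TRUE))
    stop("factor values must lie in [0, 255]")
  if (is.null(geometry)) geometry <- lu_geometry(nrow(values), ncol(values))
  storage.mode(values) <- "integer"
  structure(list(values = values, name = name, geometry = geometry),
            class = "lu_factor")
}

#' @rdname factor_layer
#' @export
constraint_layer <- function(values, name = "constraint", geometry = NULL) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (is.logical(values)) storage.mode(values) <- "integer"
  if (!all(values %in% c(0L, 1L) | is.na(values)))
    stop("constraint values must be 0 or 1")
  if (is.null(geometry)) geometry <- lu_geometry(nrow(values), ncol(values))
  storage.mode(values) <- "integer"
  structure(list(values = values, name = name, geometry = geometry),
            class = "lu_constraint")
}

#' Score a categorical environmental factor for one class
#'
#' For each category k of the factor (soil type, geomorphic unit, binned
#' elevation, ...), the score is the percentage of the class's union area
#' falling on that category, rescaled linearly from the hundred-mark to the
#' 255-mark system: `score(k) = round(2.55 * percent(k))` with rounding
#' half away from zero. The returned layer assigns every valid cell the
#' score of its factor category; categories the class never occupies score
#' 0.
#'
#' @param class_union_mask Logical matrix: the union of the class's extent
#'   over the observed time points.
#' @param factor_grid Integer matrix (or `lu_grid`) of factor categories,
#'   `NA` = nodata.
#' @param name Layer name for the result.
#' @return A list: `layer` ([factor_layer()]) and `table` (data.frame
#'   `category`, `percent`, `score`; percents sum to 100).
#' @export
categorical_factor_scores <- function(class_union_mask, factor_grid,
                                      name = "factor") {
  fv <- if (inherits(factor_grid, "lu_grid")) factor_grid$values else factor_grid
  if (!identical(dim(class_union_mask), dim(fv)))
    stop("mask and factor grid are not co-registered")
  inside <- class_union_mask & !is.na(fv)
  n_union <- sum(inside)
  if (n_union == 0L) stop("empty class union: no cells to score")
  cats <- sort(unique(fv[!is.na(fv)]))
  pct <- vapply(cats, function(k) 100 * sum(fv[inside] == k) / n_union,
                numeric(1L))
  score <- as.integer(round_half_away(2.55 * pct))
  lut <- stats::setNames(score, as.character(cats))
  out <- matrix(NA_integer_, nrow(fv), ncol(fv))
  keep <- !is.na(fv)
  out[keep] <- lut[as.character(fv[keep])]
  list(layer = factor_layer(out, name),
       table = data.frame(category = cats, percent = pct, score = score))
}

#' Euclidean-distance factor from a feature layer
#'
#' Distance from every cell to the nearest feature cell (settlements,
#' rivers, roads), normalised to \[0, 1\] by the maximum distance over the
#' valid cells and reverse-stretched to 255-0: a feature cell scores 255,
#' the farthest cell scores 0.
#'
#' @param feature_mask Logical matrix of feature cells (non-empty).
#' @param cell_size Cell edge length in metres (scales distances; the score
#'   is invariant to it).
#' @param valid_mask Optional logical matrix of study cells over which the
#'   maximum distance is taken; default all cells.
#' @param name Layer name.
#' @return A [factor_layer()].
#' @export
distance_factor <- function(feature_mask, cell_size = 90, valid_mask = NULL,
                            name = "distance") {
  if (!any(feature_mask)) stop("empty feature set: no cells to measure from")
  d <- as.matrix(EBImage::distmap(1 - feature_mask, metric = "euclidean"))
  d <- d * cell_size
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(d), ncol(d))
  dmax <- max(d[valid_mask])
  sc <- if (dmax > 0) round_half_away(255 * (1 - d / dmax)) else
    matrix(255, nrow(d), ncol(d))
  sc[!valid_mask] <- NA_integer_
  factor_layer(sc, name)
}

#' Spatial-autocorrelation factor for a class
#'
#' Certain land uses favour proximity to where that land use already is.
#' This is the [distance_factor()] taken from the cells of `class` in a
#' reference map: 255 inside existing patches, decaying with distance.
#'
#' @param reference_map An [lu_grid()] (e.g. the earliest observed map).
#' @param class Class name or code.
#' @return A [factor_layer()].
#' @export
autocorrelation_factor <- function(reference_map, class) {
  code <- schema_code(reference_map$schema, class)
  mask <- !is.na(reference_map$values) & reference_map$values == code
  if (!any(mask))
    stop("class '", class, "' is absent from the reference map")
  distance_factor(mask, reference_map$geometry$cell_size,
                  valid_mask = !is.na(reference_map$values),
                  name = paste0("autocorrelation_", class))
}

#' Build the constraint layer for one class
#'
#' A cell is excluded (constraint 0) for class c when any of:
#' \itemize{
#'   \item it is mapped water and c is not water (nothing else occurs on
#'     water bodies);
#'   \item the unchanged-land map fixes a different class there (land that
#'     kept one class across the whole observed period is assumed to have
#'     held it at the reconstruction date too);
#'   \item c is a human-modified class (arable, settlement by default) and
#'     the cell lies outside that class's observed union range.
#' }
#'
#' @param class Class name.
#' @param water_mask Logical matrix of water-body cells.
#' @param unchanged_map Integer matrix (or `lu_grid`) holding a class code
#'   where land use never changed and `NA` elsewhere; may be `NULL`.
#' @param union_masks Named list of logical matrices, one per class with a
#'   union-range restriction; only consulted for `human_classes`.
#' @param schema An [lu_schema()].
#' @param human_classes Classes confined to their union range.
#' @return An [constraint_layer()].
#' @export
build_constraints <- function(class, water_mask, unchanged_map = NULL,
                              union_masks = list(), schema = schema_7class(),
                              human_classes = c("arable", "settlement")) {
  code <- schema_code(schema, class)
  cons <- matrix(1L, nrow(water_mask), ncol(water_mask))
  if (class != "water") cons[water_mask] <- 0L
  if (!is.null(unchanged_map)) {
    uv <- if (inherits(unchanged_map, "lu_grid")) unchanged_map$values else
      unchanged_map
    cons[!is.na(uv) & uv != code] <- 0L
  }
  if (class %in% human_classes && !is.null(union_masks[[class]]))
    cons[!union_masks[[class]]] <- 0L
  constraint_layer(cons, paste0("constraint_", class))
}

#' Weighted linear combination of factors under constraints
#'
#' The multi-criteria evaluation step:
#' `S(cell) = round( sum_i w_i x_i(cell) * prod_j c_j(cell) )`, a convex
#' combination of 0-255 factors zeroed wherever any constraint is 0.
#'
#' @param factors List of [factor_layer()]s.
#' @param weights Numeric weights, one per factor, summing to 1 (see
#'   [weight_vector()]).
#' @param constraints List of [constraint_layer()]s (possibly empty).
#' @param name Layer name.
#' @return A [factor_layer()] with values in \[0, 255\].
#' @export
wlc_suitability <- function(factors, weights, constraints = list(),
                            name = "suitability") {
  if (length(factors) != length(weights))
    stop("got ", length(factors), " factors but ", length(weights), " weights")
  weights <- weight_vector(weights, tol = 1e-3)
  do.call(check_coregistered, c(factors, constraints))
  acc <- matrix(0, factors[[1L]]$geometry$n_rows,
                factors[[1L]]$geometry$n_cols)
  for (i in seq_along(factors))
    acc <- acc + weights[i] * factors[[i]]$values
  for (cl in constraints)
    acc <- acc * cl$values
  factor_layer(round_half_away(acc), name,
               geometry = factors[[1L]]$geometry)
}

#' Bin a continuous surface into categories
#'
#' Continuous factors (elevation, slope) are classed into intervals before
#' categorical scoring with [categorical_factor_scores()].
#'
#' @param values Numeric matrix.
#' @param breaks Increasing break points passed to [cut()]; values outside
#'   the range become `NA`.
#' @return Integer matrix of category indices (1-based).
#' @export
bin_continuous <- function(values, breaks) {
  out <- matrix(as.integer(cut(values, breaks = breaks)),
                nrow(values), ncol(values))
  out
}
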