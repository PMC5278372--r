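#' Category schema for categorical land-use rasters
#'
#' A schema is the legend of a categorical raster: an ordered set of unique
#' positive integer codes, one unique name per code, and a nodata code
#' distinct from all class codes.
#'
#' @param codes Integer vector of positive, unique class codes.
#' @param names Character vector of unique class names, same length.
#' @param nodata Integer nodata code, distinct from every class code.
#'   Defaults to -9999 (the usual ESRI ASCII Grid convention).
#' @return An object of class `lu_schema`: a list with elements `codes`
#'   (named integer vector, names are the class labels) and `nodata`.
#' @examples
#' lu_schema(1:2, c("land", "water"))
#' @export
lu_schema <- function(codes, names, nodata = -9999L) {
  codes <- as.integer(codes)
  if (any(codes <= 0L)) stop("class codes must be positive integers")
  if (anyDuplicated(codes)) stop("class codes must be unique")
  if (anyDuplicated(names)) stop("class names must be unique")
  if (length(codes) != length(names)) stop("codes and names differ in length")
  nodata <- as.integer(nodata)
  if (nodata %in% codes) stop("nodata code collides with a class code")
  structure(list(codes = stats::setNames(codes, as.character(names)),
                 nodata = nodata),
            class = "lu_schema")
}

#' Default 7-class land-use schema
#'
#' The classification used throughout the package: 1 arable, 2 forest,
#' 3 grassland, 4 water, 5 settlement, 6 wetland, 7 other unused land
#' (sand, saline-alkali soils, bare land).
#'
#' @return An `lu_schema` with seven classes.
#' @export
schema_7class <- function() {
  lu_schema(1:7, c("arable", "forest", "grassland", "water", "settlement",
                   "wetland", "other_unused"))
}

#' Merged 6-class schema (wetland + other unused -> unused)
#'
#' For comparisons against sources whose legend does not separate wetland
#' from other unused land, wetland and other-unused are merged into a
#' single "unused" class, keeping code 6.
#'
#' @return A list with `schema` (the 6-class `lu_schema`) and `mapping`
#'   (a named integer vector suitable for [reclassify()], mapping the
#'   7-class codes onto the merged codes).
#' @seealso [reclassify()]
#' @export
schema_6class <- function() {
  sch <- lu_schema(1:6, c("arable", "forest", "grassland", "water",
                          "settlement", "unused"))
  mapping <- stats::setNames(c(1L, 2L, 3L, 4L, 5L, 6L, 6L), as.character(1:7))
  list(schema = sch, mapping = mapping)
}

#' @export
print.lu_schema <- function(x, ...) {
  cat("<lu_schema> ", length(x$codes), " classes, nodata ", x$nodata, "\n",
      sep = "")
  print(x$codes)
  invisible(x)
}

schema_names <- function(schema) names(schema$codes)

schema_code <- function(schema, name) {
  if (is.numeric(name)) {
    code <- as.integer(name)
    if (!code %in% schema$codes) stop("unknown class code ", code)
    return(code)
  }
  if (!name %in% names(schema$codes)) stop("unknown class name '", name, "'")
  unname(schema$codes[[name]])
}

schemas_identical <- function(a, b) {
  identical(unname(a$codes), unname(b$codes)) &&
    identical(names(a$codes), names(b$codes))
}
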