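#' Read a categorical raster from an ESRI ASCII Grid file
#'
#' Reads the plain-text ESRI ASCII Grid dialect (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `NODATA_value`, then the
#' integer body, first line = northernmost row). Every in-range value must
#' be a schema code or the nodata value.
#'
#' @param path File path.
#' @param schema An [lu_schema()] giving the legend the values are checked
#'   against.
#' @return An [lu_grid()].
#' @export
read_raster <- function(path, schema) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  body_start <- 1L
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1L])) {
      hdr[[tolower(tok[1L])]] <- as.numeric(tok[2L])
      body_start <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing ESRI ASCII header keyword(s): ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  nodata <- as.integer(hdr$nodata_value %||% schema$nodata)
  vals <- scan(text = lines[body_start:length(lines)], what = numeric(),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("body has %d values, expected %d", length(vals), nr * nc))
  m <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_integer_
  geom <- lu_geometry(nr, nc, hdr$cellsize,
                      origin = c(hdr$xllcorner,
                                 hdr$yllcorner + nr * hdr$cellsize))
  lu_grid(m, schema, geom)
}

#' Write a categorical raster to an ESRI ASCII Grid file
#'
#' @param grid An [lu_grid()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_raster <- function(grid, path) {
  g <- grid$geometry
  m <- grid$values
  m[is.na(m)] <- grid$schema$nodata
  hdr <- c(
    sprintf("ncols         %d", g$n_cols),
    sprintf("nrows         %d", g$n_rows),
    sprintf("xllcorner     %.10g", g$origin[1L]),
    sprintf("yllcorner     %.10g", g$origin[2L] - g$n_rows * g$cell_size),
    sprintf("cellsize      %.10g", g$cell_size),
    sprintf("NODATA_value  %d", grid$schema$nodata))
  body <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a class-by-class matrix as CSV
#'
#' CSV layout: header row of final-year class names, first column of
#' initial-year class names, numeric body. Used for transition matrices and
#' pairwise-comparison matrices.
#'
#' @param path File path.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

#' @rdname read_matrix_csv
#' @param m Matrix with dimnames.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
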