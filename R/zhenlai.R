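#' Zhenlai County case-study tables
#'
#' The published tables of the Zhenlai County (Jilin, China) 1930s
#' reconstruction, bundled as plain-text example inputs:
#' \describe{
#'   \item{`zhenlai_source_areas()`}{per-class 1930s area estimates from
#'     each source (Markov backcast, historical documents, topographic
#'     maps at three scales) with their AHP source weights. The
#'     other-unused class carries only the published fused figure (its
#'     per-source weights were never published) as a single "given" source
#'     with weight 1.}
#'   \item{`zhenlai_factor_weights()`}{AHP factor weights per class for
#'     the suitability surfaces; each class column sums to 1, blanks mean
#'     the factor is not used for that class.}
#'   \item{`zhenlai_change_matrix()`}{the 1954 -> 1932 six-class change
#'     matrices (ha), reference or simulated; wetland and other unused
#'     land are merged as "unused".}
#'   \item{`zhenlai_accuracy_components()`}{the published three-map
#'     accuracy components (percent of study area).}
#' }
#'
#' @return `zhenlai_source_areas()`: a data.frame for [fuse_sources()].
#' @export
zhenlai_source_areas <- function() {
  utils::read.csv(system.file("extdata", "zhenlai_source_areas.csv",
                              package = "hlurm"))
}

#' @rdname zhenlai_source_areas
#' @return `zhenlai_factor_weights()`: a matrix (factors x classes) with
#'   `NA` where a factor does not apply to a class.
#' @export
zhenlai_factor_weights <- function() {
  df <- utils::read.csv(system.file("extdata", "zhenlai_factor_weights.csv",
                                    package = "hlurm"), row.names = 1L)
  as.matrix(df)
}

#' @rdname zhenlai_source_areas
#' @param which `"reference"` (observed 1954 and 1932 maps) or
#'   `"simulated"` (observed 1954 vs reconstructed 1932).
#' @return `zhenlai_change_matrix()`: an `lu_transition` in ha, rows =
#'   1954 classes, columns = 1932 classes.
#' @export
zhenlai_change_matrix <- function(which = c("reference", "simulated")) {
  which <- match.arg(which)
  m <- read_matrix_csv(system.file(
    "extdata", paste0("zhenlai_", which, "_change.csv"), package = "hlurm"))
  transition_matrix(m, unit = "ha")
}

#' @rdname zhenlai_source_areas
#' @return `zhenlai_accuracy_components()`: a named list `N`, `H`, `M`,
#'   `F` (percent), suitable for [comparison_budgets()].
#' @export
zhenlai_accuracy_components <- function() {
  df <- utils::read.csv(system.file(
    "extdata", "zhenlai_accuracy_components.csv", package = "hlurm"))
  as.list(stats::setNames(df$percent, df$component))
}
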