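#' Fuse multi-source area estimates into one area per class
#'
#' Each land-use class may have area estimates from several sources
#' (historical documents, Markov backcasts, map digitisation at various
#' scales), each with a per-class source weight. The fused area is the
#' weighted sum `fused(c) = sum_s w(c,s) * area(c,s)` over the sources
#' available for that class.
#'
#' @param sources Data frame with columns `class`, `source`, `area_ha`,
#'   `weight`. Within each class the weights must sum to 1 (tolerance
#'   `tol`); a weight attached to a missing (`NA`) area is an error.
#' @param tol Tolerance on each class's weight sum; default 1e-3 to admit
#'   weights published at 3 decimals.
#' @return Named numeric vector of fused areas (ha), in order of first
#'   appearance of each class.
#' @examples
#' fuse_sources(data.frame(class = "water", source = c("a", "b"),
#'                         area_ha = c(10, 20), weight = c(0.5, 0.5)))
#' @export
fuse_sources <- function(sources, tol = 1e-3) {
  need <- c("class", "source", "area_ha", "weight")
  if (!all(need %in% names(sources)))
    stop("sources needs columns ", paste(need, collapse = ", "))
  if (any(!is.na(sources$area_ha) & sources$area_ha < 0))
    stop("areas must be >= 0")
  cls <- unique(sources$class)
  out <- vapply(cls, function(cc) {
    s <- sources[sources$class == cc, ]
    if (any(is.na(s$area_ha)))
      stop("class '", cc, "' has a weight for a missing area")
    if (abs(sum(s$weight) - 1) > tol)
      stop(sprintf("weights for class '%s' sum to %.4f, not 1",
                   cc, sum(s$weight)))
    sum(s$weight * s$area_ha)
  }, numeric(1L))
  stats::setNames(out, cls)
}

#' Rescale class areas to a known study-area total
#'
#' @param areas Named nonnegative numeric vector (ha), not all zero.
#' @param study_total Total study area (ha).
#' @return Named vector scaled by `study_total / sum(areas)`; sums to
#'   `study_total` exactly.
#' @export
normalize_to_total <- function(areas, study_total) {
  if (any(areas < 0)) stop("areas must be >= 0")
  s <- sum(areas)
  if (s <= 0) stop("cannot normalize all-zero areas")
  areas * (study_total / s)
}

#' Transition-matrix edit rule: move a flow to a different destination
#'
#' Expresses a narrative adjustment such as "the wetland that the matrix
#' sends to arable land should go to grassland instead" as a mechanical
#' rule. Moving a flow changes one off-diagonal destination while leaving
#' the source row total (the initial-year class area) untouched.
#'
#' @param from Source (initial-year) class name.
#' @param old_to Current destination class name.
#' @param new_to New destination class name.
#' @param amount `"all"` (default) to move the whole flow, or a
#'   nonnegative ha/cell amount not exceeding the available flow.
#' @return A `move_flow` rule for [edit_transitions()].
#' @export
move_flow <- function(from, old_to, new_to, amount = "all") {
  if (!identical(amount, "all")) {
    amount <- as.numeric(amount)
    if (is.na(amount) || amount < 0) stop("amount must be \"all\" or >= 0")
  }
  structure(list(from = from, old_to = old_to, new_to = new_to,
                 amount = amount), class = "move_flow")
}

#' Apply edit rules to a transition matrix
#'
#' Rules are applied sequentially in list order. Every `move_flow` rule
#' preserves its source row total exactly, so the matrix grand total is
#' invariant under any rule list.
#'
#' @param matrix An `lu_transition` (see [transition_matrix()]).
#' @param rules List of [move_flow()] rules.
#' @return The edited `lu_transition`.
#' @export
edit_transitions <- function(matrix, rules) {
  m <- matrix
  for (r in rules) {
    if (!inherits(r, "move_flow")) stop("rules must be move_flow objects")
    for (nm in c(r$from, r$old_to, r$new_to))
      if (!nm %in% rownames(m)) stop("unknown class '", nm, "' in rule")
    avail <- m[r$from, r$old_to]
    amt <- if (identical(r$amount, "all")) avail else r$amount
    if (amt > avail + 1e-9)
      stop(sprintf("rule moves %.2f from %s->%s but only %.2f is available",
                   amt, r$from, r$old_to, avail))
    m[r$from, r$old_to] <- avail - amt
    m[r$from, r$new_to] <- m[r$from, r$new_to] + amt
  }
  m
}

#' Backcast class quantities from a transition model and known margins
#'
#' Given a transition matrix taken as the model of an interval whose
#' final-year (column) class areas are known, each column j is rescaled by
#' `known_final(j) / column_total(j)` and the backcast initial-year area of
#' class i is the rescaled row total. Only the final margin is known, so a
#' single column-rescaling pass determines the answer uniquely;
#' `sum(backcast) = sum(known_final)` always. If the matrix columns already
#' match the margins the backcast equals the raw row totals.
#'
#' @param model_matrix An `lu_transition`; rows = earlier year, columns =
#'   the year with known areas.
#' @param known_final Named nonnegative vector of final-year class areas;
#'   names must match the matrix classes.
#' @return A list: `quantities` (named backcast areas for the earlier
#'   year), `rescaled` (the margin-matched `lu_transition`).
#' @export
backcast_quantities <- function(model_matrix, known_final) {
  cls <- colnames(model_matrix)
  if (!setequal(names(known_final), cls))
    stop("margin classes do not match matrix classes")
  known_final <- known_final[cls]
  if (any(known_final < 0)) stop("margins must be >= 0")
  ct <- colSums(model_matrix)
  dead <- ct == 0 & known_final > 0
  if (any(dead))
    stop("nonzero target margin for all-zero column(s): ",
         paste(cls[dead], collapse = ", "))
  scale <- ifelse(ct > 0, known_final / ct, 0)
  resc <- sweep(unclass(model_matrix)[,], 2L, scale, `*`)
  resc <- transition_matrix(resc, attr(model_matrix, "unit"))
  list(quantities = rowSums(resc), rescaled = resc)
}

#' Convert per-class areas to integer cell quotas
#'
#' Largest-remainder apportionment of the valid cells among classes in
#' proportion to their target areas. The total must already be consistent:
#' `sum(quantities)` within 1% of `n_valid_cells * cell_area`.
#'
#' @param quantities Named nonnegative areas (ha).
#' @param geometry An [lu_geometry()] (for the cell area) or a cell area in
#'   ha.
#' @param n_valid_cells Number of allocatable (non-nodata) cells.
#' @return Named integer vector summing to `n_valid_cells` exactly.
#' @export
areas_to_cells <- function(quantities, geometry, n_valid_cells) {
  ca <- if (is.numeric(geometry)) geometry else cell_area_ha(geometry)
  tot <- n_valid_cells * ca
  if (abs(sum(quantities) - tot) > 0.01 * tot)
    stop(sprintf("areas sum to %.2f ha but the grid holds %.2f ha (>1%% off)",
                 sum(quantities), tot))
  stats::setNames(largest_remainder(quantities, n_valid_cells),
                  names(quantities))
}
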