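#' Three-map comparison: per-cell accuracy components
#'
#' Overlays the reference map at time 1, the reference map at time 2 and
#' the simulated map of time 2, and classifies every jointly valid cell:
#' \describe{
#'   \item{null success (N)}{observed persistence predicted as persistence}
#'   \item{hit (H)}{observed change predicted as change}
#'   \item{miss (M)}{observed change predicted as persistence}
#'   \item{false alarm (F)}{observed persistence predicted as change}
#' }
#' Observed change is `ref_t1 != ref_t2`; predicted change is
#' `ref_t1 != sim_t2`. In `"binary"` mode a hit only requires both to
#' change; cells that changed to the wrong category (partial hits, PH) are
#' then a subset of H. In `"categorical"` mode (the default) a hit also
#' requires `sim_t2 == ref_t2`, and partial hits are counted among the
#' misses. PH is always reported separately.
#'
#' @param ref_t1,ref_t2,sim_t2 Co-registered [lu_grid()]s with a shared
#'   schema.
#' @param mode `"categorical"` or `"binary"`.
#' @return A list of class `three_map_components`: `grid` (integer matrix,
#'   0 = null success, 1 = hit, 2 = miss, 3 = false alarm, `NA` = nodata),
#'   `partial_hits` (logical matrix) and `counts` (list `N`, `H`, `M`,
#'   `F`, `PH` as percentages of the valid area, plus `mode` and
#'   `n_valid`). `N + H + M + F = 100`.
#' @export
three_map_components <- function(ref_t1, ref_t2, sim_t2,
                                 mode = c("categorical", "binary")) {
  mode <- match.arg(mode)
  check_coregistered(ref_t1, ref_t2, sim_t2)
  if (!schemas_identical(ref_t1$schema, ref_t2$schema) ||
      !schemas_identical(ref_t1$schema, sim_t2$schema))
    stop("the three maps do not share a schema")
  a <- ref_t1$values; b <- ref_t2$values; s <- sim_t2$values
  valid <- !is.na(a) & !is.na(b) & !is.na(s)
  nv <- sum(valid)
  if (nv == 0L) stop("no jointly valid cells")
  obs <- valid & a != b
  pred <- valid & a != s
  ph <- obs & pred & s != b           # changed, predicted change, wrong class
  hit <- if (mode == "binary") obs & pred else obs & pred & s == b
  miss <- if (mode == "binary") obs & !pred else (obs & !pred) | ph
  fa <- valid & !obs & pred
  nul <- valid & !obs & !pred
  comp <- matrix(NA_integer_, nrow(a), ncol(a))
  comp[nul] <- 0L; comp[hit] <- 1L; comp[miss] <- 2L; comp[fa] <- 3L
  pc <- function(m) 100 * sum(m) / nv
  structure(list(
    grid = comp, partial_hits = ph,
    counts = list(N = pc(nul), H = pc(hit), M = pc(miss), F = pc(fa),
                  PH = pc(ph), mode = mode, n_valid = nv)),
    class = "three_map_components")
}

#' Summary budgets from accuracy components
#'
#' From component percentages H, M, F (hits, misses, false alarms)
#' computes: observed change `OC = H + M`, predicted change `PC = H + F`,
#' `total_error = M + F` and its decomposition into quantity error
#' `EQ = |M - F|` and allocation error `EA = 2 min(M, F)` (so
#' `EQ + EA = total_error`); the figure of merit
#' `FOM = H / (H + M + F)` (in percent); and the ratios of hits, misses
#' and false alarms to the observed change, `HOC`, `MOC`, `FOC`
#' (`HOC + MOC = 1`).
#'
#' @param counts A `three_map_components` object, its `counts` element, or
#'   any list/vector with elements `H`, `M`, `F` in percent of study area.
#' @return A list of class `validation_budget` with elements `OC`, `PC`,
#'   `total_error`, `EQ`, `EA`, `FOM` (percent) and `HOC`, `MOC`, `FOC`
#'   (ratios; `NA` with a warning when `OC = 0`).
#' @examples
#' comparison_budgets(list(H = 30.62, M = 26.97, F = 5.95))
#' @export
comparison_budgets <- function(counts) {
  if (inherits(counts, "three_map_components")) counts <- counts$counts
  h <- counts[["H"]]; m <- counts[["M"]]; f <- counts[["F"]]
  if (any(c(h, m, f) < 0)) stop("components must be >= 0")
  oc <- h + m; pcv <- h + f; te <- m + f
  eq <- abs(m - f); ea <- 2 * min(m, f)
  fom <- if (h + m + f > 0) 100 * h / (h + m + f) else 0
  if (oc == 0) {
    warning("observed change is zero; HOC/MOC/FOC undefined")
    hoc <- moc <- foc <- NA_real_
  } else {
    hoc <- h / oc; moc <- m / oc; foc <- f / oc
  }
  structure(list(OC = oc, PC = pcv, total_error = te, EQ = eq, EA = ea,
                 FOM = fom, HOC = hoc, MOC = moc, FOC = foc),
            class = "validation_budget")
}

#' @export
print.validation_budget <- function(x, ...) {
  cat(sprintf(
    "<validation_budget> OC %.2f%%  PC %.2f%%  EQ %.2f  EA %.2f  FOM %.2f%%\n",
    x$OC, x$PC, x$EQ, x$EA, x$FOM))
  cat(sprintf("  HOC %.3f  MOC %.3f  FOC %.3f\n", x$HOC, x$MOC, x$FOC))
  invisible(x)
}

#' Per-class gross gains, losses and total change of a transition matrix
#'
#' `gross_loss(i) = initial_total(i) - persistence(i)` and
#' `gross_gain(j) = final_total(j) - persistence(j)`; the total change
#' equals both the sum of losses and the sum of gains (the off-diagonal
#' mass).
#'
#' @param matrix An `lu_transition` (see [transition_matrix()]).
#' @return A list: `table` (data.frame `class`, `initial_total`,
#'   `final_total`, `persistence`, `gross_loss`, `gross_gain`) and
#'   `total_change`.
#' @export
change_budget <- function(matrix) {
  d <- diag(unclass(matrix)[,])
  it <- initial_totals(matrix); ft <- final_totals(matrix)
  tab <- data.frame(class = rownames(matrix),
                    initial_total = unname(it), final_total = unname(ft),
                    persistence = unname(d),
                    gross_loss = unname(it - d),
                    gross_gain = unname(ft - d))
  list(table = tab, total_change = sum(it - d))
}
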