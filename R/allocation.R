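#' Allocation configuration
#'
#' @param class_order Order in which classes are allocated, most
#'   human-constrained first. Default: settlement, arable, water, wetland,
#'   forest, grassland, other unused.
#' @param neighbor_threshold Minimum number of Moore-8 neighbours already
#'   holding the class for the strict neighbour rule (default 5).
#' @param relaxation Rule-drop order once strict passes stall: drop the
#'   neighbour rule, then the max-probability rule, then the evidence rule.
#' @return An `allocation_config` list.
#' @export
allocation_config <- function(class_order = c("settlement", "arable", "water",
                                              "wetland", "forest", "grassland",
                                              "other_unused"),
                              neighbor_threshold = 5L,
                              relaxation = c("neighbor", "max_prob",
                                             "evidence")) {
  neighbor_threshold <- as.integer(neighbor_threshold)
  if (neighbor_threshold < 0L || neighbor_threshold > 8L)
    stop("neighbor_threshold must be in [0, 8]")
  if (!all(relaxation %in% c("neighbor", "max_prob", "evidence")))
    stop("unknown relaxation rule name")
  structure(list(class_order = class_order,
                 neighbor_threshold = neighbor_threshold,
                 relaxation = relaxation),
            class = "allocation_config")
}

#' Count Moore-8 neighbours of a class at one cell
#'
#' Off-grid and nodata neighbours count as non-matching, so the neighbour
#' rule is effectively stricter at borders.
#'
#' @param map An [lu_grid()] or integer matrix (`NA` = unassigned/nodata).
#' @param class Class name (if `map` is an `lu_grid`) or code.
#' @param cell Integer `c(row, col)`.
#' @return Integer in \[0, 8\].
#' @export
neighbor_count <- function(map, class, cell) {
  v <- if (inherits(map, "lu_grid")) map$values else map
  code <- if (inherits(map, "lu_grid")) schema_code(map$schema, class) else
    as.integer(class)
  r <- cell[1L]; cc <- cell[2L]
  stopifnot(r >= 1, r <= nrow(v), cc >= 1, cc <= ncol(v))
  n <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    rr <- r + dr; ccc <- cc + dc
    if (rr < 1L || rr > nrow(v) || ccc < 1L || ccc > ncol(v)) next
    if (!is.na(v[rr, ccc]) && v[rr, ccc] == code) n <- n + 1L
  }
  n
}

#' Ordered cellular-automata spatial allocation
#'
#' Distributes per-class cell quotas over the grid. Cells fixed by the
#' unchanged-land evidence are pre-assigned and their quotas debited
#' (step 0). Classes are then processed in `config$class_order`; for each
#' class, candidate cells (unassigned, constraint 1) are ranked by
#' descending suitability (ties by row-major index) and accepted in strict
#' passes requiring simultaneously:
#' \enumerate{
#'   \item max-probability: the class's suitability is the strict maximum
#'     over all classes at the cell (ties fail);
#'   \item evidence consistency: where the partial evidence map has a
#'     value, it names this class;
#'   \item neighbourhood: at least `neighbor_threshold` Moore-8 neighbours
#'     already hold the class.
#' }
#' Passes are synchronous: neighbour counts are frozen at the start of each
#' pass, so pre-assigned and previously accepted cells seed the growth of
#' the next pass. When a strict pass accepts nothing and quota remains,
#' rules are dropped one at a time in `config$relaxation` order and passes
#' resume. Quantity control is binding: allocation for a class stops
#' exactly when its quota is met. After the last class, any remaining cells
#' are assigned to the feasible class with the highest remaining quota
#' (ties: higher suitability, then class order).
#'
#' @param stack Named list of per-class suitability [factor_layer()]s
#'   (`NA` = nodata; nodata must agree across layers).
#' @param quotas Named integer vector of cell targets summing to the number
#'   of allocatable cells.
#' @param constraints Named list of [constraint_layer()]s; a missing entry
#'   means unconstrained.
#' @param evidence Optional [lu_grid()] or integer matrix: partial class
#'   assignments (`NA` where silent).
#' @param fixed Optional [lu_grid()] or integer matrix of pre-determined
#'   cells (the unchanged-land constraint); these are never reassigned.
#' @param config An [allocation_config()].
#' @param schema An [lu_schema()] for the output map.
#' @return A list of class `allocation_result`: `map` (an `lu_grid`),
#'   `counts` (realised per-class counts, equal to `quotas`), `pass`
#'   (integer matrix: pass at which each cell was assigned; 0 =
#'   pre-assigned), and `audit` (data.frame `row`, `col`, `class`, `pass`,
#'   `rules`).
#' @export
allocate <- function(stack, quotas, constraints = list(), evidence = NULL,
                     fixed = NULL, config = allocation_config(),
                     schema = schema_7class()) {
  classes <- names(stack)
  if (is.null(classes) || anyDuplicated(classes))
    stop("stack must be a uniquely named list of suitability layers")
  if (!setequal(config$class_order, classes))
    stop("config$class_order must be a permutation of the stack classes")
  if (!setequal(names(quotas), classes)) stop("quotas must name every class")
  do.call(check_coregistered, stack)
  nr <- stack[[1L]]$geometry$n_rows; nc <- stack[[1L]]$geometry$n_cols
  n <- nr * nc
  codes <- vapply(classes, function(cl) schema_code(schema, cl), integer(1L))

  S <- lapply(stack, function(f) { v <- f$values; storage.mode(v) <- "double"; v })
  valid <- Reduce(`&`, lapply(S, function(v) !is.na(v)))
  n_valid <- sum(valid)
  quotas <- round(quotas[classes])
  storage.mode(quotas) <- "integer"
  quotas0 <- quotas
  if (sum(quotas) != n_valid)
    stop(sprintf("quotas sum to %d but the grid has %d allocatable cells",
                 sum(quotas), n_valid))

  cons <- lapply(classes, function(cl) {
    cl_layer <- constraints[[cl]]
    if (is.null(cl_layer)) matrix(1L, nr, nc) else cl_layer$values
  })
  names(cons) <- classes
  ev <- if (is.null(evidence)) NULL else
    if (inherits(evidence, "lu_grid")) evidence$values else evidence

  # row-major linear index, the deterministic tie-break everywhere
  rm_index <- as.vector((row(matrix(0L, nr, nc)) - 1L) * nc +
                        col(matrix(0L, nr, nc)))

  assigned <- matrix(NA_integer_, nr, nc)
  pass_at <- matrix(NA_integer_, nr, nc)
  audit <- list()
  pass_id <- 0L

  # Step 0: pre-assigned (unchanged-land) cells
  if (!is.null(fixed)) {
    fv <- if (inherits(fixed, "lu_grid")) fixed$values else fixed
    fx <- !is.na(fv) & valid
    if (any(fx)) {
      assigned[fx] <- fv[fx]
      pass_at[fx] <- 0L
      for (cl in classes) {
        nfix <- sum(fv[fx] == codes[[cl]])
        quotas[cl] <- quotas[cl] - nfix
        if (quotas[cl] < 0L)
          stop(sprintf(
            "class '%s': %d cells are fixed but the quota is only %d",
            cl, nfix, quotas0[cl]))
      }
    }
  }

  rule_names <- c(max_prob = "max_prob", evidence = "evidence",
                  neighbor = "neighbor")

  for (cl in config$class_order) {
    quota <- quotas[[cl]]
    code <- codes[[cl]]
    if (quota == 0L) next
    s_cl <- S[[cl]]
    others <- S[setdiff(classes, cl)]
    best_other <- if (length(others)) Reduce(pmax, others) else
      matrix(-Inf, nr, nc)
    ruleA <- !is.na(s_cl) & s_cl > best_other
    ruleB <- if (is.null(ev)) matrix(TRUE, nr, nc) else
      is.na(ev) | ev == code
    feas_base <- valid & cons[[cl]] == 1L
    ord <- order(-as.vector(s_cl), rm_index, na.last = TRUE)

    active <- c("max_prob", "evidence", "neighbor")
    stage <- 0L
    repeat {
      # passes under the current rule set
      repeat {
        if (quota == 0L) break
        cand <- feas_base & is.na(assigned)
        if ("max_prob" %in% active) cand <- cand & ruleA
        if ("evidence" %in% active) cand <- cand & ruleB
        if ("neighbor" %in% active) {
          ncount <- neighbor_sum_matrix(!is.na(assigned) & assigned == code)
          cand <- cand & ncount >= config$neighbor_threshold
        }
        cv <- as.vector(cand)
        sel <- ord[cv[ord]]
        if (length(sel) == 0L) break
        sel <- sel[seq_len(min(quota, length(sel)))]
        if ("neighbor" %in% active || length(sel) > 0L) {
          pass_id <- pass_id + 1L
          assigned[sel] <- code
          pass_at[sel] <- pass_id
          quota <- quota - length(sel)
          audit[[length(audit) + 1L]] <- list(idx = sel, class = cl,
                                              pass = pass_id,
                                              rules = paste(active,
                                                            collapse = "+"))
        }
        if (!"neighbor" %in% active) break  # static rules: one pass suffices
      }
      if (quota == 0L) break
      stage <- stage + 1L
      if (stage > length(config$relaxation)) break
      active <- setdiff(active, config$relaxation[stage])
    }
    if (quota > 0L) {
      # no feasible cells remain for this class even with all rules dropped
      stop(sprintf(
        "class '%s' has a remaining quota of %d but no feasible cells",
        cl, quota))
    }
    quotas[cl] <- 0L
  }

  # Mop-up for any still-unassigned valid cells (possible only when the
  # constraint layers steered earlier classes away from them).
  rem <- which(is.na(assigned) & valid)
  if (length(rem)) {
    rem <- rem[order(rm_index[rem])]
    for (idx in rem) {
      feas <- vapply(classes, function(cl2)
        quotas[[cl2]] > 0L && cons[[cl2]][idx] == 1L, logical(1L))
      if (!any(feas))
        stop("unassignable cell: every class with remaining quota is ",
             "constrained out")
      cand_cl <- classes[feas]
      qv <- quotas[cand_cl]
      sv <- vapply(cand_cl, function(cl2) S[[cl2]][idx], numeric(1L))
      pick <- cand_cl[order(-qv, -sv,
                            match(cand_cl, config$class_order))][1L]
      pass_id <- pass_id + 1L
      assigned[idx] <- codes[[pick]]
      pass_at[idx] <- pass_id
      quotas[pick] <- quotas[pick] - 1L
      audit[[length(audit) + 1L]] <- list(idx = idx, class = pick,
                                          pass = pass_id, rules = "mop_up")
    }
  }

  counts <- vapply(classes, function(cl2)
    sum(assigned == codes[[cl2]], na.rm = TRUE), integer(1L))
  stopifnot(identical(unname(counts), unname(as.integer(quotas0[classes]))))

  audit_df <- if (length(audit)) {
    do.call(rbind, lapply(audit, function(a) {
      r <- (a$idx - 1L) %% nr + 1L
      cc <- (a$idx - 1L) %/% nr + 1L
      data.frame(row = r, col = cc, class = a$class, pass = a$pass,
                 rules = a$rules)
    }))
  } else data.frame(row = integer(), col = integer(), class = character(),
                    pass = integer(), rules = character())

  structure(list(
    map = lu_grid(assigned, schema, stack[[1L]]$geometry),
    counts = stats::setNames(counts, classes),
    pass = pass_at,
    audit = audit_df), class = "allocation_result")
}

#' @export
print.allocation_result <- function(x, ...) {
  cat("<allocation_result>\n")
  print(x$counts)
  invisible(x)
}
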