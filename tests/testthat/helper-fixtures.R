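# Shared fixture builders and independent oracles.

# Two-class toy schema.
schema_ab <- function() lu_schema(1:2, c("A", "B"))

grid_ab <- function(values, cell_size = 100) {
  lu_grid(values, schema_ab(),
          lu_geometry(nrow(values), ncol(values), cell_size))
}

# Brute-force Euclidean distance transform: O(cells x features), the
# independent oracle for distance_factor().
bf_distance <- function(feature_mask) {
  ft <- which(feature_mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(feature_mask), ncol(feature_mask))
  for (r in seq_len(nrow(out))) for (cc in seq_len(ncol(out)))
    out[r, cc] <- sqrt(min((ft[, 1] - r)^2 + (ft[, 2] - cc)^2))
  out
}

# Random positive reciprocal pairwise matrix.
random_reciprocal <- function(n, noise = 0.3) {
  m <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- exp(rnorm(1, sd = noise) + rnorm(1))
    m[j, i] <- 1 / m[i, j]
  }
  m
}

# Dominant eigenvector by repeated squaring + row-sum normalisation, the
# independent oracle for ahp_weights().
eig_by_squaring <- function(m, n_square = 30) {
  for (i in seq_len(n_square)) {
    m <- m %*% m
    m <- m / max(m)
  }
  rs <- rowSums(m)
  rs / sum(rs)
}

# Random allocation problem on an n x n grid over the 7-class schema:
# suitability layers, constraints consistent with a sparse fixed
# (unchanged-land) map, a partial evidence map, and feasible quotas.
random_allocation_problem <- function(n = 100, seed = 1) {
  withr::with_seed(seed, {
    sch <- schema_7class()
    cls <- names(sch$codes)
    k <- length(cls)
    stack <- lapply(cls, function(cl)
      factor_layer(matrix(sample(0:255, n * n, replace = TRUE), n, n),
                   name = cl))
    names(stack) <- cls
    # sparse fixed map (~8% of cells)
    fixed <- matrix(NA_integer_, n, n)
    idx <- sample(n * n, round(0.08 * n * n))
    fixed[idx] <- sample(sch$codes, length(idx), replace = TRUE)
    # constraints: other classes excluded on fixed cells; two classes also
    # carry random exclusions elsewhere (grassland stays unconstrained so
    # every cell keeps a feasible class)
    cons <- lapply(cls, function(cl) {
      m <- matrix(1L, n, n)
      m[!is.na(fixed) & fixed != sch$codes[[cl]]] <- 0L
      if (cl %in% c("water", "settlement")) {
        drop <- sample(which(is.na(fixed)), round(0.02 * n * n))
        m[drop] <- 0L
      }
      constraint_layer(m, cl)
    })
    names(cons) <- cls
    # evidence on ~10% of cells
    ev <- matrix(NA_integer_, n, n)
    eidx <- sample(n * n, round(0.1 * n * n))
    ev[eidx] <- sample(sch$codes, length(eidx), replace = TRUE)
    # quotas: fixed counts plus a random split of the remainder
    nfix <- vapply(cls, function(cl)
      sum(fixed == sch$codes[[cl]], na.rm = TRUE), integer(1))
    rest <- n * n - sum(nfix)
    quotas <- nfix + hlurm:::largest_remainder(runif(k, 0.2, 1), rest)
    names(quotas) <- cls
    list(stack = stack, constraints = cons, evidence = ev, fixed = fixed,
         quotas = quotas, schema = sch)
  })
}
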