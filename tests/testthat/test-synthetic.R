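test_that("the generator is fully determined by its seed", {
  cfg <- synth_config(n_rows = 60, n_cols = 60, seed = 42)
  g1 <- generate_landscape(cfg)
  g2 <- generate_landscape(cfg)
  expect_identical(g1$values, g2$values)
  f1 <- generate_factors(g1, cfg)
  f2 <- generate_factors(g2, cfg)
  expect_identical(f1$factors, f2$factors)
  expect_identical(f1$evidence$values, f2$evidence$values)
  g3 <- generate_landscape(synth_config(n_rows = 60, n_cols = 60, seed = 43))
  expect_false(identical(g1$values, g3$values))
})

test_that("realised class proportions match the targets", {
  cfg <- synth_config(n_rows = 200, n_cols = 200, seed = 7)
  g <- generate_landscape(cfg)
  real <- class_counts(g) / (200 * 200)
  expect_true(all(abs(real - cfg$proportions) <= 0.02))
  # rank carving makes them exact up to integer rounding
  expect_true(all(abs(real - cfg$proportions) <= 1 / (200 * 200)))
  # degenerate single-class request
  p1 <- c(arable = 1, forest = 0, grassland = 0, water = 0,
          settlement = 0, wetland = 0, other_unused = 0)
  g1 <- generate_landscape(synth_config(50, 50, proportions = p1, seed = 1))
  expect_true(all(g1$values == 1L))
  expect_error(synth_config(50, 50, proportions = p1 * 2), "sum")
})

test_that("smoothing raises same-class neighbour agreement", {
  agreement <- function(g) {
    v <- g$values
    tot <- 0; same <- 0
    for (code in g$schema$codes) {
      m <- v == code
      same <- same + sum(hlurm:::neighbor_sum_matrix(m)[m])
    }
    same / sum(hlurm:::neighbor_sum_matrix(matrix(TRUE, nrow(v), ncol(v))))
  }
  a0 <- a5 <- numeric(10)
  for (s in 1:10) {
    a0[s] <- agreement(generate_landscape(
      synth_config(80, 80, smooth_radius = 0, seed = s)))
    a5[s] <- agreement(generate_landscape(
      synth_config(80, 80, smooth_radius = 5, seed = s)))
  }
  expect_true(mean(a5) > mean(a0))
  expect_true(all(a5 > a0))
})

test_that("generated factors carry information about the classes", {
  cfg <- synth_config(n_rows = 80, n_cols = 80, seed = 3)
  g <- generate_landscape(cfg)
  fx <- generate_factors(g, cfg)
  mi <- function(x, y) {
    tab <- table(x, y) / length(x)
    px <- rowSums(tab); py <- colSums(tab)
    keep <- tab > 0
    sum(tab[keep] * log(tab[keep] / outer(px, py)[keep]))
  }
  for (fn in names(fx$factors))
    expect_gt(mi(as.vector(g$values), as.vector(fx$factors[[fn]])), 0.05)
  # feature masks are non-empty and lines span the grid
  expect_true(any(fx$features$settlements))
  expect_true(any(fx$features$rivers[, 1]) && any(fx$features$rivers[, 80]))
  # evidence agrees with the landscape wherever present
  ev <- fx$evidence$values
  expect_true(all(ev[!is.na(ev)] == g$values[!is.na(ev)]))
  # zero coverage -> empty evidence
  cfg0 <- synth_config(n_rows = 80, n_cols = 80, seed = 3,
                       evidence_coverage = 0)
  expect_true(all(is.na(generate_factors(g, cfg0)$evidence$values)))
})

test_that("forward simulation follows the transition probabilities", {
  sch <- schema_ab()
  allA <- lu_grid(matrix(1L, 500, 500), sch, lu_geometry(500, 500, 100))
  P <- matrix(c(0.7, 0, 0.3, 1), 2, 2, dimnames = list(c("A", "B"),
                                                       c("A", "B")))
  t2 <- simulate_forward_change(allA, P, seed = 7)
  frac_b <- mean(t2$values == 2L)
  expect_equal(frac_b, 0.30, tolerance = 0.01 / 0.30)
  # identity matrix: nothing moves
  I2 <- diag(2); dimnames(I2) <- dimnames(P)
  tI <- simulate_forward_change(allA, I2, seed = 7)
  expect_identical(tI$values, allA$values)
  # a present class with an all-zero row is rejected
  bad <- matrix(c(0, 0, 0, 1), 2, 2, dimnames = dimnames(P))
  expect_error(simulate_forward_change(allA, bad, seed = 1),
               "non-stochastic")
})

test_that("crosstab of simulated change recovers the transition matrix", {
  k <- 7
  P <- matrix(0.03, k, k); diag(P) <- 1 - 0.03 * (k - 1)
  cls <- names(schema_7class()$codes)
  dimnames(P) <- list(cls, cls)
  cfg <- synth_config(500, 500,
                      proportions = setNames(rep(1 / k, k), cls), seed = 11)
  t1 <- generate_landscape(cfg)
  t2 <- simulate_forward_change(t1, P, seed = 12)
  m <- crosstab(t1, t2, unit = "cells")
  Phat <- unclass(m)[,] / rowSums(m)
  expect_true(max(abs(Phat - P)) <= 0.02)
})

test_that("backcasting from simulated intervals recovers the earlier areas", {
  # doubly stochastic model -> uniform composition is stationary, so the
  # later interval's crosstab is a valid model of the earlier one
  k <- 7
  P <- matrix(0.03, k, k); diag(P) <- 1 - 0.03 * (k - 1)
  cls <- names(schema_7class()$codes)
  dimnames(P) <- list(cls, cls)
  for (seed in 1:5) {
    cfg <- synth_config(500, 500,
                        proportions = setNames(rep(1 / k, k), cls),
                        seed = seed)
    t0 <- generate_landscape(cfg)
    t1 <- simulate_forward_change(t0, P, seed = seed + 100)
    t2 <- simulate_forward_change(t1, P, seed = seed + 200)
    model <- crosstab(t1, t2)             # later interval as model
    # backcast with the model's own margins is exact
    exact <- backcast_quantities(model, final_totals(model))
    expect_equal(exact$quantities, class_areas(t1)[cls], tolerance = 1e-12)
    # model of the earlier interval: columns rescaled to the known t1 areas
    b <- backcast_quantities(model, class_areas(t1))
    a0 <- class_areas(t0)[cls]
    expect_true(all(abs(b$quantities - a0) / a0 <= 0.02))
    # an edit that reroutes a small flow stays within the same band
    edited <- edit_transitions(model, list(
      move_flow("wetland", "water", "grassland")))
    expect_equal(sum(edited), sum(model))
    b2 <- backcast_quantities(edited, class_areas(t1))
    expect_true(all(abs(b2$quantities - a0) / a0 <= 0.05))
  }
})
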