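test_that("three-map components match a hand-enumerated 2x2 toy", {
  ref1 <- grid_ab(matrix(c(1L, 2L, 1L, 2L), 2, 2))   # rows: A A / B B
  ref2 <- grid_ab(matrix(c(1L, 2L, 2L, 2L), 2, 2))   # rows: A B / B B
  sim2 <- grid_ab(matrix(2L, 2, 2))                  # all B
  for (mode in c("categorical", "binary")) {
    cmp <- three_map_components(ref1, ref2, sim2, mode)
    expect_equal(cmp$counts$N, 50)                   # 2 of 4 cells
    expect_equal(cmp$counts$H, 25)
    expect_equal(cmp$counts$M, 0)
    expect_equal(cmp$counts$F, 25)
    expect_equal(cmp$counts$PH, 0)
  }
  cmp <- three_map_components(ref1, ref2, sim2)
  expect_identical(cmp$grid, matrix(c(3L, 0L, 1L, 0L), 2, 2))
})

test_that("perfect prediction gives FOM 100 and the null model FOM 0", {
  withr::with_seed(51, {
    ref1 <- grid_ab(matrix(sample(1:2, 100, TRUE), 10, 10))
    ref2 <- grid_ab(matrix(sample(1:2, 100, TRUE), 10, 10))
    perfect <- three_map_components(ref1, ref2, ref2)
    expect_equal(perfect$counts$M, 0)
    expect_equal(perfect$counts$F, 0)
    b <- comparison_budgets(perfect)
    expect_equal(b$FOM, 100)
    expect_equal(perfect$counts$H, b$OC)
    null <- three_map_components(ref1, ref2, ref1)   # predicts persistence
    expect_equal(null$counts$H, 0)
    expect_equal(null$counts$F, 0)
    expect_equal(null$counts$M, comparison_budgets(null)$OC)
    expect_equal(comparison_budgets(null)$FOM, 0)
  })
})

test_that("partial hits move between H and M with the mode", {
  sch <- lu_schema(1:3, c("A", "B", "C"))
  g <- function(v) lu_grid(matrix(v, 1, 1), sch)
  # observed A->B, predicted A->C: changed, predicted change, wrong class
  bin <- three_map_components(g(1L), g(2L), g(3L), "binary")
  expect_equal(bin$counts$H, 100); expect_equal(bin$counts$PH, 100)
  cat <- three_map_components(g(1L), g(2L), g(3L), "categorical")
  expect_equal(cat$counts$H, 0); expect_equal(cat$counts$M, 100)
  expect_equal(cat$counts$PH, 100)
})

test_that("swapping reference and simulation swaps misses and false alarms", {
  withr::with_seed(52, {
    ref1 <- grid_ab(matrix(sample(1:2, 64, TRUE), 8, 8))
    ref2 <- grid_ab(matrix(sample(1:2, 64, TRUE), 8, 8))
    sim2 <- grid_ab(matrix(sample(1:2, 64, TRUE), 8, 8))
    a <- three_map_components(ref1, ref2, sim2, "binary")$counts
    b <- three_map_components(ref1, sim2, ref2, "binary")$counts
    expect_equal(a$M, b$F)
    expect_equal(a$F, b$M)
    expect_equal(a$H, b$H)
  })
})

test_that("budget identities hold for random component vectors", {
  withr::with_seed(53, {
    for (rep in 1:50) {
      x <- runif(3, 0, 40)
      cnt <- list(H = x[1], M = x[2], F = x[3])
      b <- comparison_budgets(cnt)
      expect_equal(b$OC, cnt$H + cnt$M)
      expect_equal(b$PC, cnt$H + cnt$F)
      expect_equal(b$total_error, cnt$M + cnt$F)
      expect_equal(b$EQ + b$EA, b$total_error)
      expect_equal(b$EQ, abs(cnt$M - cnt$F))
      expect_equal(b$HOC + b$MOC, 1)
      expect_equal(b$FOM, 100 * cnt$H / (cnt$H + cnt$M + cnt$F))
    }
  })
  expect_warning(comparison_budgets(list(H = 0, M = 0, F = 5)), "undefined")
  # M = F: the whole error is allocation error
  b <- comparison_budgets(list(H = 10, M = 7, F = 7))
  expect_equal(b$EQ, 0)
  expect_equal(b$EA, b$total_error)
})

test_that("published accuracy components yield the published budgets", {
  b <- comparison_budgets(zhenlai_accuracy_components())
  expect_equal(b$FOM, 48.19, tolerance = 0.01 / 48.19)
  expect_equal(b$EQ, 21.02, tolerance = 0.01 / 21.02)
  expect_equal(b$OC, 57.59, tolerance = 0.01 / 57.59)
  expect_equal(b$HOC, 0.532, tolerance = 0.001 / 0.532)
  expect_equal(b$FOC, 0.103, tolerance = 0.001 / 0.103)
})

test_that("change budgets recover gains, losses and total change", {
  cls <- c("A", "B")
  m <- transition_matrix(matrix(c(1, 0, 1, 2), 2, 2,
                                dimnames = list(cls, cls)))
  cb <- change_budget(m)
  expect_equal(cb$table$gross_loss, c(1, 0))
  expect_equal(cb$table$gross_gain, c(0, 1))
  expect_equal(cb$total_change, 1)
  # diagonal matrix: no change
  dm <- matrix(c(3, 0, 0, 4), 2, 2, dimnames = list(cls, cls))
  cb2 <- change_budget(transition_matrix(dm))
  expect_true(all(cb2$table$gross_loss == 0))
  expect_equal(cb2$total_change, 0)
})

test_that("change budgets from a crosstab equal its off-diagonal mass", {
  withr::with_seed(54, {
    t1 <- grid_ab(matrix(sample(1:2, 100, TRUE), 10, 10))
    t2 <- grid_ab(matrix(sample(1:2, 100, TRUE), 10, 10))
    m <- crosstab(t1, t2)
    cb <- change_budget(m)
    off <- sum(m) - sum(diag(unclass(m)[,]))
    expect_equal(cb$total_change, off)
    expect_equal(sum(cb$table$gross_gain), off)
  })
})
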