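test_that("ASCII grid round trip reproduces values, geometry and nodata", {
  sch <- schema_7class()
  v <- matrix(c(1L, 2L, 3L, 4L, 5L, 6L, 7L, NA, 1L), 3, 3)
  g <- lu_grid(v, sch, lu_geometry(3, 3, cell_size = 90, origin = c(500, 900)))
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(g, path)
  g2 <- read_raster(path, sch)
  expect_identical(g2$values, g$values)
  expect_true(hlurm:::geometries_identical(g$geometry, g2$geometry))
  # nodata is written as the schema's nodata code
  expect_match(paste(readLines(path), collapse = "\n"), "-9999")
})

test_that("nodata mask is set exactly at NODATA_value cells", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 90", "NODATA_value -9999",
               "1 -9999 2", "-9999 3 4"), path)
  g <- read_raster(path, schema_7class())
  expect_identical(is.na(g$values),
                   matrix(c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE), 2, 3))
})

test_that("out-of-schema codes are rejected, naming the value and cell", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 90", "NODATA_value -9999", "1 9"), path)
  expect_error(read_raster(path, schema_7class()), "9")
  expect_error(lu_grid(matrix(9L, 1, 1), schema_7class()),
               "value 9 at cell \\(row 1, col 1\\)")
})

test_that("reclassify applies total mappings and rejects partial ones", {
  sch <- schema_7class()
  v <- matrix(c(6L, 6L, 6L, 6L, 1L, NA), 2, 3)
  g <- lu_grid(v, sch)
  ident <- setNames(1:7, as.character(1:7))
  expect_identical(reclassify(g, ident)$values, v)
  # 4 wetland cells -> unused
  m6 <- schema_6class()
  g2 <- reclassify(g, m6$mapping, m6$schema)
  cnt <- class_counts(g2)
  expect_equal(unname(cnt["unused"]), 4L)
  expect_false("wetland" %in% names(cnt))
  expect_true(is.na(g2$values[2, 3]))                  # nodata preserved
  expect_error(reclassify(g, ident[-3]), "not total")
})

test_that("composed reclassify equals reclassify of the composed mapping", {
  sch <- schema_7class()
  withr::with_seed(11, {
    for (rep in 1:5) {
      g <- lu_grid(matrix(sample(1:7, 30, TRUE), 5, 6), sch)
      m1 <- setNames(sample(1:7, 7, TRUE), as.character(1:7))
      m2 <- setNames(sample(1:7, 7, TRUE), as.character(1:7))
      comp <- setNames(m2[as.character(m1)], as.character(1:7))
      expect_identical(reclassify(reclassify(g, m1), m2)$values,
                       reclassify(g, comp)$values)
    }
  })
})

test_that("class areas scale counts by the cell area", {
  sch <- schema_7class()
  g <- lu_grid(matrix(3L, 10, 10), sch)   # 90 m cells -> 0.81 ha
  a <- class_areas(g)
  expect_equal(unname(a["grassland"]), 81)
  expect_equal(unname(a["forest"]), 0)
  expect_equal(sum(a), sum(!is.na(g$values)) * 0.81)
})

test_that("crosstab matches a hand count and conserves margins", {
  # 2x2 toy, cell area 1 ha (100 m cells)
  t1 <- grid_ab(matrix(c(1L, 2L, 1L, 2L), 2, 2))     # rows: A A / B B
  t2 <- grid_ab(matrix(c(1L, 2L, 2L, 2L), 2, 2))     # rows: A B / B B
  m <- crosstab(t1, t2)
  expect_equal(m["A", "A"], 1)
  expect_equal(m["A", "B"], 1)
  expect_equal(m["B", "B"], 2)
  expect_equal(m["B", "A"], 0)
  expect_equal(sum(m), 4)
  expect_equal(hlurm:::initial_totals(m), class_areas(t1))
  expect_equal(hlurm:::final_totals(m), class_areas(t2))
})

test_that("crosstab of a grid with itself is diagonal; nodata excluded", {
  withr::with_seed(4, {
    v <- matrix(sample(c(1:7, NA), 64, TRUE), 8, 8)
    g <- lu_grid(v, schema_7class())
    m <- crosstab(g, g)
    expect_equal(sum(m) , sum(!is.na(v)) * 0.81)
    off <- m; diag(off) <- 0
    expect_equal(sum(off), 0)
  })
  g1 <- grid_ab(matrix(1L, 2, 2))
  g2 <- grid_ab(matrix(1L, 3, 2))
  expect_error(crosstab(g1, g2), "co-registered")
})

test_that("trajectories label ordered sequences and unchanged fractions", {
  g1 <- grid_ab(matrix(c(1L, 2L), 2, 1))             # A / B
  g2 <- grid_ab(matrix(c(1L, 1L), 2, 1))             # A / A
  tr <- trajectory_codes(list(g1, g2))
  expect_setequal(tr$levels$sequence, c("1-1", "2-1"))
  expect_equal(tr$levels$count, c(1L, 1L))
  expect_equal(unname(tr$unchanged_fraction["A"]), 1)
  expect_equal(unname(tr$unchanged_fraction["B"]), 0)
  # identical series: one trajectory per present class, fraction 1
  tr2 <- trajectory_codes(list(g1, g1, g1))
  expect_equal(nrow(tr2$levels), 2L)
  expect_true(all(tr2$unchanged_fraction[c("A", "B")] == 1))
  expect_error(trajectory_codes(list(g1)), "at least 2")
})

test_that("distinct trajectories are bounded and agree with crosstab persistence", {
  withr::with_seed(9, {
    grids <- lapply(1:3, function(i)
      grid_ab(matrix(sample(1:2, 36, TRUE), 6, 6)))
    tr <- trajectory_codes(grids)
    expect_lte(nrow(tr$levels), 2^3)
    # unchanged mask = cells persistent in every pairwise crosstab
    pers <- Reduce(`&`, lapply(grids[-1], function(g)
      g$values == grids[[1]]$values))
    expect_identical(tr$unchanged, pers)
  })
})
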