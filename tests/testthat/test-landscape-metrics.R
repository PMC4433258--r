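grid_from <- function(m, ...) land_cover_grid(m, forest_codes = 1L, ...)

test_that("forest cover percentage counts forest over valid pixels", {
  expect_equal(compute_pfc(grid_from(matrix(1L, 4, 4))), 100)
  expect_equal(compute_pfc(grid_from(matrix(0L, 3, 5))), 0)

  m <- matrix(0L, 5, 5)
  m[c(1, 7, 13, 19, 25)] <- 1L
  expect_equal(compute_pfc(grid_from(m)), 20)

  # nodata pixels leave both numerator and denominator
  m2 <- matrix(c(1L, 1L, 0L, -9L), 2, 2)
  g2 <- land_cover_grid(m2, forest_codes = 1L, nodata_code = -9)
  expect_equal(compute_pfc(g2), 100 * 2 / 3)

  all_na <- land_cover_grid(matrix(-9L, 2, 2), forest_codes = 1L,
                            nodata_code = -9)
  expect_error(compute_pfc(all_na), "no valid pixels")
  expect_error(compute_rlps(all_na), "no valid pixels")
})

test_that("largest patch share follows connected components", {
  blob <- matrix(0L, 4, 4); blob[2:3, 2:3] <- 1L
  expect_equal(compute_rlps(grid_from(blob)), 100)

  two <- matrix(0L, 5, 5); two[1, 1:2] <- 1L; two[5, 4:5] <- 1L
  expect_equal(compute_rlps(grid_from(two)), 50)
  expect_equal(compute_rlps(grid_from(two), connectivity = 4), 50)

  # patches of 3 and 2 pixels under either connectivity
  m <- matrix(0L, 5, 5)
  m[1, 1] <- 1L; m[1, 2] <- 1L; m[2, 2] <- 1L; m[4, 4] <- 1L; m[5, 4] <- 1L
  expect_equal(compute_rlps(grid_from(m), 8), 60)
  expect_equal(compute_rlps(grid_from(m), 4), 60)
  expect_equal(compute_pfc(grid_from(m)), 20)

  # forest-free window: undefined, not 0 or 100
  expect_true(is.na(compute_rlps(grid_from(matrix(0L, 3, 3)))))
})

test_that("connectivity choice separates diagonal-only patches", {
  diagm <- matrix(0L, 2, 2); diagm[1, 1] <- 1L; diagm[2, 2] <- 1L
  expect_equal(compute_rlps(grid_from(diagm), 8), 100)
  expect_equal(compute_rlps(grid_from(diagm), 4), 50)
})

test_that("patch labelling matches a recursive flood-fill oracle", {
  set.seed(42)
  for (trial in 1:40) {
    nr <- sample(4:40, 1); nc <- sample(4:40, 1)
    mask <- random_mask(nr, nc, runif(1, 0.2, 0.7), seed = 1000 + trial)
    g <- grid_from(matrix(as.integer(mask), nr, nc))
    for (conn in c(4, 8)) {
      expect_equal(compute_rlps(g, conn), oracle_rlps(mask, conn),
                   info = sprintf("trial %d conn %d", trial, conn))
    }
  }
})

test_that("relabelling non-forest codes changes nothing", {
  set.seed(7)
  m <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
  g1 <- land_cover_grid(m, forest_codes = c(1, 2))
  m2 <- m; m2[m == 0] <- 7L; m2[m == 3] <- 9L
  g2 <- land_cover_grid(m2, forest_codes = c(1, 2))
  expect_equal(compute_pfc(g1), compute_pfc(g2))
  expect_equal(compute_rlps(g1), compute_rlps(g2))
})

test_that("growing the largest patch never shrinks it", {
  set.seed(11)
  for (trial in 1:20) {
    mask <- random_mask(8, 8, 0.4, seed = 2000 + trial)
    if (!any(mask)) next
    lab <- label_patches(mask, 8)
    sizes <- tabulate(lab[lab > 0])
    big <- which.max(sizes)
    # add a free pixel bordering the largest patch
    cand <- which(!mask)
    added <- FALSE
    for (s in cand) {
      r <- ((s - 1) %% 8) + 1; cc <- ((s - 1) %/% 8) + 1
      nbr <- expand.grid(r = r + (-1:1), c = cc + (-1:1))
      nbr <- nbr[nbr$r >= 1 & nbr$r <= 8 & nbr$c >= 1 & nbr$c <= 8, ]
      if (any(lab[cbind(nbr$r, nbr$c)] == big)) {
        mask2 <- mask; mask2[s] <- TRUE
        lab2 <- label_patches(mask2, 8)
        expect_gte(max(tabulate(lab2[lab2 > 0])), sizes[big])
        added <- TRUE
        break
      }
    }
    if (!added) succeed()
  }
})

test_that("rlps can fall below pfc (it is relative to forest, not the cell)", {
  # 4-connectivity checkerboard: every forest pixel isolated
  m <- matrix(0L, 5, 5)
  m[seq(1, 25, by = 2)] <- 1L
  g <- grid_from(m)
  expect_equal(compute_pfc(g), 52)
  expect_equal(compute_rlps(g, 4), 100 / 13)
  expect_lt(compute_rlps(g, 4), compute_pfc(g))
})

test_that("metrics_table tiles the raster and matches per-window recomputation", {
  g <- grid_from(matrix(1L, 20, 20))
  tab <- metrics_table(g, cell_size = 10)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$pfc == 100))
  expect_true(all(tab$rlps == 100))
  expect_equal(tab$cell_id, sort(tab$cell_id))

  spec <- landscape_spec(grid_shape = c(3, 3), pixels_per_cell = 8,
                         target_cover = 40, aggregation = 2, seed = 9)
  sg <- generate_raster(spec)
  tab2 <- metrics_table(sg, cell_size = 8)
  expect_equal(nrow(tab2), 9)
  k <- 0
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1
    win <- sg$values[((i - 1) * 8 + 1):(i * 8), ((j - 1) * 8 + 1):(j * 8)]
    expect_equal(tab2$pfc[k], 100 * sum(win) / 64)
    expect_equal(tab2$rlps[k], oracle_rlps(win == 1, 8))
  }

  expect_error(metrics_table(g, cell_size = 7), "misaligned")
})

test_that("ascii grid round trip preserves codes, nodata and cell size", {
  set.seed(3)
  m <- matrix(sample(c(0L, 1L, -9L), 30, replace = TRUE, c(.4, .4, .2)), 5, 6)
  g <- land_cover_grid(m, pixel_size = 100, forest_codes = 1L,
                       nodata_code = -9)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, path)
  g2 <- read_ascii_grid(path, forest_codes = 1L)
  expect_equal(g2$values, m + 0)  # numeric matrix back
  expect_equal(g2$pixel_size, 100)
  expect_equal(g2$nodata_code, -9)
  expect_equal(compute_pfc(g2), compute_pfc(g))
  expect_equal(compute_rlps(g2), compute_rlps(g))
})

test_that("land-cover grid rejects inconsistent construction", {
  expect_error(land_cover_grid(matrix(1, 0, 3)), "non-empty")
  expect_error(land_cover_grid(matrix(1, 2, 2), forest_codes = integer(0)),
               "non-empty")
  expect_error(land_cover_grid(matrix(1, 2, 2), forest_codes = 1,
                               nodata_code = 1), "disjoint")
})
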