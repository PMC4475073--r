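test_that("hexagon cells have the exact requested area and edge length", {
  grid <- hex_tessellation(c(0, 40000, 0, 40000), cell_area_ha = 5000)
  expect_equal(grid$s, sqrt(2 * 5e7 / (3 * sqrt(3))))  # ~4386.9 m
  areas <- vapply(grid$cells$id, function(id)
    shoelace_area(hex_vertices(grid, id)), numeric(1))
  expect_equal(areas / 1e4, rep(5000, nrow(grid$cells)), tolerance = 1e-9)
  # equal within 1e-6 relative tolerance across cells
  expect_lt(diff(range(areas)) / mean(areas), 1e-6)
  expect_error(hex_tessellation(c(0, 1000, 0, 1000), cell_area_ha = -1),
               "positive")
  expect_warning(hex_tessellation(c(0, 1000, 0, 1000), cell_area_ha = 5000),
                 "exceeds")
})

test_that("the tessellation tiles the extent: pixels map to exactly one cell", {
  grid <- hex_tessellation(c(0, 20000, 0, 20000), cell_area_ha = 2000)
  hab <- land_raster(matrix(1, 100, 100), res = 200)
  kern <- dispersal_kernel(0.10, 2000)
  patches <- label_patches(hab)
  g <- local_connectivity(grid, patches, land_raster(matrix(1, 100, 100),
                                                     res = 200), kern)
  # every habitat pixel lands in exactly one cell: counts conserve pixels
  expect_identical(sum(g$habitat_pixels), 10000L)
})

test_that("interior cells have exactly six edge-sharing neighbors", {
  for (ext in list(c(0, 60000, 0, 60000), c(0, 35000, 0, 80000))) {
    grid <- hex_tessellation(ext, cell_area_ha = 5000)
    deg <- table(factor(c(grid$adjacency$i, grid$adjacency$j),
                        levels = grid$cells$id))
    expect_true(all(deg[as.character(grid$cells$id[grid$cells$interior])] == 6))
    # adjacency refers only to known cells, no self pairs, i < j
    expect_true(all(grid$adjacency$i < grid$adjacency$j))
  }
})

test_that("local connectivity: empty cells 0, lone patch a^2, pair by hand", {
  grid <- hex_tessellation(c(0, 20000, 0, 20000), cell_area_ha = 5000)
  ctr <- grid$cells[grid$cells$interior, ][1, ]
  nr <- 400; res <- 50
  m <- matrix(0, nr, nr)
  # a 2x2 patch and a 1x3 patch near the chosen cell's center,
  # separated by 10 empty pixel columns (edge-to-edge 550 m)
  row0 <- nr - round(ctr$cy / res); col0 <- round(ctr$cx / res)
  m[row0 + (0:1), col0 + (0:1)] <- 1
  m[row0, col0 + 12 + (0:2)] <- 1
  hab <- land_raster(m, res = res)
  sv <- matrix(0, nr, nr)
  sv[row0 + (0:1), col0 + (0:1)] <- 0.5       # attribute 2
  sv[row0, col0 + 12 + (0:2)] <- 1            # attribute 3
  kern <- dispersal_kernel(0.10, 2000)
  patches <- label_patches(hab)
  g <- local_connectivity(grid, patches, land_raster(sv, res = res), kern)
  vals <- g$values$current
  expect_equal(sum(vals > 0), 1L)
  p <- predict(kern, 550)
  expect_equal(max(vals), 4 + 9 + 2 * (2 * 3 * p))
  # all other cells (no habitat) are zero
  expect_true(all(vals[-which.max(vals)] == 0))

  # lone patch: value is attribute squared
  m2 <- matrix(0, nr, nr); m2[row0, col0] <- 1
  g2 <- local_connectivity(grid, label_patches(land_raster(m2, res = res)),
                           land_raster(matrix(0.8, nr, nr), res = res), kern)
  expect_equal(max(g2$values$current), 0.8^2)
})

test_that("a cell containing the whole landscape recovers the global PC numerator", {
  grid <- hex_tessellation(c(0, 20000, 0, 20000), cell_area_ha = 5000)
  ctr <- grid$cells[grid$cells$interior, ][1, ]
  nr <- 400; res <- 50
  set.seed(21)
  m <- matrix(0, nr, nr)
  row0 <- nr - round(ctr$cy / res); col0 <- round(ctr$cx / res)
  # random blob of habitat within +-10 pixels (500 m) of the cell center
  blk <- matrix(rbinom(21 * 21, 1, 0.4), 21, 21)
  m[row0 + (-10:10), col0 + (-10:10)] <- blk
  hab <- land_raster(m, res = res)
  sv <- land_raster(matrix(runif(nr * nr), nr, nr), res = res)
  kern <- dispersal_kernel(0.10, 2000)
  patches <- label_patches(hab)
  g <- local_connectivity(grid, patches, sv, kern)
  expect_equal(sum(g$values$current > 0), 1L)
  global <- compute_pc(graph_from_patches(patch_attributes(patches, sv),
                                          interpatch_distances(patches),
                                          kern),
                       numerator_only = TRUE)$numerator
  expect_equal(max(g$values$current), global, tolerance = 1e-12)
})

test_that("regional graph links adjacent cells and preserves zero-habitat nodes", {
  grid <- hex_tessellation(c(0, 30000, 0, 30000), cell_area_ha = 5000)
  hab <- land_raster(matrix(0, 60, 60), res = 500)  # no habitat at all
  hab$values[30, 30] <- 1
  kern <- dispersal_kernel(0.10, 2000)
  g <- local_connectivity(grid, label_patches(hab),
                          land_raster(matrix(1, 60, 60), res = 500), kern)
  rg <- regional_graph(g, "current")
  expect_equal(length(rg$ids), nrow(grid$cells))   # zero cells kept as nodes
  expect_equal(rg$mode, "binary")
  expect_equal(nrow(rg$links), nrow(grid$adjacency))
  expect_equal(rg$A_L,
               nrow(grid$cells) * grid$cell_area_ha * 1e4 / 500^2)
  expect_error(regional_graph(g, "2099"), "no local connectivity")
})

test_that("regional importance: symmetry, middle-of-chain dominance, scaling invariance", {
  # fabricate a 3-cell row grid to isolate the graph logic
  fake <- structure(list(
    cells = data.frame(id = 1:3, q = 0:2, r = 0, cx = 0, cy = 0,
                       interior = TRUE),
    adjacency = data.frame(i = c(1, 2), j = c(2, 3)),
    values = list(t = c(1, 1, 1)), cell_area_ha = 5000, res = 50,
    s = 1, extent = c(0, 1, 0, 1)), class = "focal_grid")
  imp <- regional_importance(fake, "t")
  expect_equal(imp$t, 100 * c(8, 11, 8) / 17)
  expect_gt(imp$t[2], imp$t[1])

  # two adjacent equal cells: equal importance
  fake2 <- fake
  fake2$cells <- fake$cells[1:2, ]
  fake2$adjacency <- data.frame(i = 1, j = 2)
  fake2$values <- list(t = c(3, 3))
  imp2 <- regional_importance(fake2, "t")
  expect_equal(imp2$t[1], imp2$t[2])

  # dIIC invariant under uniform scaling of the cell attributes
  fake3 <- fake
  fake3$values <- list(t = c(2, 5, 1))
  scaled <- fake3
  scaled$values <- list(t = 7 * c(2, 5, 1))
  expect_equal(regional_importance(fake3, "t")$t,
               regional_importance(scaled, "t")$t, tolerance = 1e-12)

  # all-zero attributes: zeros with a warning
  fake0 <- fake
  fake0$values <- list(t = c(0, 0, 0))
  expect_warning(imp0 <- regional_importance(fake0, "t"), "zero")
  expect_equal(imp0$t, c(0, 0, 0))

  # long CSV export
  f <- withr::local_tempfile(fileext = ".csv")
  write_importance(imp, f)
  long <- read.csv(f)
  expect_named(long, c("cell_id", "period", "delta_iic_pct"))
  expect_equal(nrow(long), 3L)
})

test_that("dispersal-distance sensitivity reports rank correlations", {
  scn <- tiny_scenario(seed = 31, fraction = 0.35, aggregation = 0.5,
                       extent = c(0, 16000, 0, 16000), res = 100)
  hab <- generate_habitat(scn)
  suit <- generate_suitability(scn, 1)
  patches <- label_patches(hab)
  grid <- hex_tessellation(raster_extent(hab), cell_area_ha = 2000)
  sens <- sensitivity_to_dispersal(grid, patches, suit,
                                   distances = c(1000, 2000, 3000))
  expect_false(sens$degenerate)
  expect_true(isSymmetric(sens$rho))
  expect_equal(diag(sens$rho), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(is.finite(sens$rho)))

  # identical distance repeated: correlation exactly 1
  sens_same <- sensitivity_to_dispersal(grid, patches, suit,
                                        distances = c(2000, 2000))
  expect_equal(sens_same$rho[1, 2], 1)

  # constant ranks (no habitat anywhere): undefined, flagged
  bare <- land_raster(matrix(0, 160, 160), res = 100)
  sens_deg <- suppressWarnings(sensitivity_to_dispersal(
    grid, label_patches(bare),
    land_raster(matrix(1, 160, 160), res = 100), c(1000, 2000)))
  expect_true(sens_deg$degenerate)
  expect_true(all(is.na(sens_deg$rho)))
})
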