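test_that("power_diagram realises equal targets on a periodic domain", {
  set.seed(2)
  seeds <- best_candidate_seeds(36, 30, 30, periodic = TRUE)
  pd <- power_diagram(seeds, rep(25, 36), 30, 30, nx = 128, ny = 128,
                      periodic = TRUE)
  expect_setequal(unique(as.vector(pd$labels)), 1:36)
  expect_lt(max(abs(pd$areas - 25)) / 25, 0.05)
  expect_equal(sum(pd$areas), 30 * 30)
})

test_that("power_diagram areas track heterogeneous targets", {
  set.seed(4)
  seeds <- best_candidate_seeds(40, 40, 40, periodic = TRUE)
  targets <- pmax(0.3, 1 + 0.3 * rnorm(40)) * 40
  pd <- power_diagram(seeds, targets, 40, 40, nx = 180, ny = 180)
  scaled <- targets / sum(targets) * 1600
  expect_gt(cor(pd$areas, scaled), 0.98)
  expect_lt(pd$resid, 0.01)
})

test_that("warm-started weights converge faster than cold starts", {
  set.seed(9)
  seeds <- best_candidate_seeds(30, 30, 30, periodic = TRUE)
  targets <- pmax(0.3, 1 + 0.3 * rnorm(30)) * 30
  cold <- power_diagram(seeds, targets, 30, 30, nx = 120, ny = 120)
  warm <- power_diagram(seeds, targets, 30, 30, nx = 120, ny = 120,
                        weights = cold$weights)
  expect_lte(warm$iterations, cold$iterations)
  expect_identical(warm$labels, cold$labels)
})

test_that("power_diagram validates its inputs", {
  seeds <- cbind(c(5, 15), c(5, 15))
  expect_error(power_diagram(seeds, c(-1, 10), 20, 20),
               "targets")
  expect_error(power_diagram(seeds, c(10, 10, 10), 20, 20))
  expect_error(power_diagram(seeds[, 1, drop = FALSE], c(10, 10), 20, 20))
})

test_that("untuned diagram with equal weights is a Voronoi partition", {
  seeds <- rbind(c(5, 5), c(15, 5), c(5, 15), c(15, 15))
  pd <- power_diagram(seeds, width = 20, height = 20, nx = 80, ny = 80,
                      periodic = FALSE, tune = FALSE)
  expect_equal(as.numeric(pd$areas), rep(100, 4))
})

test_that("power_diagram_cells gives exact areas and adjacency", {
  # 2 x 2 equidistant seeds, bounded: four exact quadrants; diagonal
  # pairs share only a corner point, hence are not neighbours
  seeds <- rbind(c(5, 5), c(15, 5), c(5, 15), c(15, 15))
  cells <- power_diagram_cells(seeds, width = 20, height = 20,
                               periodic = FALSE)
  expect_equal(cells$areas, rep(100, 4))
  expect_true(all(cells$on_boundary))
  expect_setequal(cells$neighbours[[1]], c(2L, 3L))
  expect_setequal(cells$neighbours[[4]], c(2L, 3L))
  for (i in 1:4)
    expect_equal(oracle_polygon_area(cells$polygons[[i]]), cells$areas[i])
})

test_that("power_diagram_cells adjacency is symmetric on a torus", {
  set.seed(21)
  seeds <- best_candidate_seeds(30, 30, 30, periodic = TRUE)
  cells <- power_diagram_cells(seeds, width = 30, height = 30,
                               periodic = TRUE)
  expect_equal(sum(cells$areas), 900, tolerance = 1e-6)
  expect_false(any(cells$on_boundary))
  for (i in seq_len(30))
    for (j in cells$neighbours[[i]])
      expect_true(i %in% cells$neighbours[[j]])
  # Euler: mean neighbour number of a toroidal tessellation is 6
  expect_equal(mean(lengths(cells$neighbours)), 6, tolerance = 0.01)
})

test_that("clean_label_image reassigns stray fragments", {
  m <- matrix(1L, 10, 10)
  m[, 6:10] <- 2L
  m[1, 1] <- 2L  # fragment of label 2 inside label 1
  cleaned <- clean_label_image(m, periodic = FALSE)
  expect_equal(cleaned[1, 1], 1L)
  expect_equal(label_component_counts(cleaned, FALSE)[-1], c(1L, 1L))
})

test_that("best_candidate_seeds spreads points", {
  s <- best_candidate_seeds(50, 20, 20, periodic = FALSE)
  expect_equal(dim(s), c(50, 2))
  expect_true(all(s >= 0 & s <= 20))
  dmin <- min(dist(s))
  expect_gt(dmin, 0.5)  # blue noise: far above uniform-random minima
})

test_that("hex_lattice_seeds builds an offset-row lattice", {
  s <- hex_lattice_seeds(4, 4, 8, 8)
  expect_equal(nrow(s), 16)
  expect_error(hex_lattice_seeds(4, 5, 8, 8), "even")
})
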