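# voxelised solid ellipsoid with semi-axes (a, b, c) at centre ctr
voxel_ellipsoid <- function(arr, label, ctr, semi, voxel) {
  d <- dim(arr)
  x <- ((1:d[1]) - 0.5) * voxel[1]
  y <- ((1:d[2]) - 0.5) * voxel[2]
  z <- ((1:d[3]) - 0.5) * voxel[3]
  u2 <- outer(outer(((x - ctr[1]) / semi[1])^2,
                    ((y - ctr[2]) / semi[2])^2, "+"),
              ((z - ctr[3]) / semi[3])^2, "+")
  arr[u2 <= 1] <- label
  arr
}

test_that("nuclear_stats recovers ellipsoid morphometrics", {
  vox <- c(0.25, 0.25, 0.25)
  arr <- array(0L, c(60, 60, 100))
  arr <- voxel_ellipsoid(arr, 1L, c(7.5, 7.5, 6), c(2, 3, 5), vox)
  st <- nuclear_stats(arr, vox)
  expect_equal(st$volume_um3, 4 / 3 * pi * 2 * 3 * 5, tolerance = 0.02)
  expect_equal(st$semi_a, 5, tolerance = 0.02)
  expect_equal(st$semi_b, 3, tolerance = 0.02)
  expect_equal(st$semi_c, 2, tolerance = 0.02)
  expect_equal(st$ellipticity, 1 - 2 / 5, tolerance = 0.02)
  expect_equal(st$centre_z, 6 / 25, tolerance = 0.01)
})

test_that("a sphere has ellipticity near zero", {
  vox <- c(0.25, 0.25, 0.25)
  arr <- array(0L, c(60, 60, 60))
  arr <- voxel_ellipsoid(arr, 3L, c(7.5, 7.5, 7.5), c(4, 4, 4), vox)
  st <- nuclear_stats(arr, vox)
  expect_equal(st$cell_id, "3")
  expect_lt(st$ellipticity, 0.01)
})

test_that("nuclear_stats rejects split labels and empty grids", {
  arr <- array(0L, c(10, 10, 10))
  arr[1:2, 1:2, 1:2] <- 1L
  arr[8:9, 8:9, 8:9] <- 1L
  expect_error(nuclear_stats(arr, c(1, 1, 1)), "disconnected")
  expect_error(nuclear_stats(array(0L, c(4, 4, 4)), c(1, 1, 1)),
               "no nuclei")
})

test_that("nuclear_stats_from_tissue mirrors the analytic nuclei", {
  tis <- fixture_small_tissue()
  nm <- nuclear_stats_from_tissue(tis)
  expect_equal(nm$volume_um3, tis$nuclei$volume_um3)
  expect_equal(nm$centre_z, tis$nuclei$centre_z)
  # prolate 2:1 nuclei: ellipticity 0.5 for every nucleus
  expect_equal(nm$ellipticity, rep(0.5, nrow(nm)))
  expect_true(all(nm$semi_a >= nm$semi_b & nm$semi_b >= nm$semi_c))
})

test_that("voxelised tissue nuclei agree with the analytic models", {
  tis <- fixture_small_tissue()
  stack <- tis$nucleus_stack
  arr <- array(0L, c(ncol(stack[[1]]), nrow(stack[[1]]), length(stack)))
  for (l in seq_along(stack)) arr[, , l] <- t(stack[[l]])
  vz <- tis$config$tissue_height / length(stack)
  st <- nuclear_stats(arr, c(tis$pixel_size, tis$pixel_size, vz))
  m <- match(st$cell_id, tis$nuclei$cell_id)
  # rasterised, cell-clipped nuclei: volumes within 40%, positions close
  expect_gt(cor(st$volume_um3, tis$nuclei$volume_um3[m]), 0.7)
  expect_lt(mean(abs(st$centre_z - tis$nuclei$centre_z[m])), 0.06)
})

test_that("cell_nucleus_correlation is exact on constructed columns", {
  cols <- lapply(1:6, function(i)
    cell_column(paste0("c", i), 0:4, seq(0.1, 0.9, 0.2),
                area = rep(10 * i, 5),
                neighbours = rep(list(c("x", "y", "z")), 5),
                nuclear_area = c(0, 5 * i, 5 * i, 5 * i, 0),
                height = 10))
  nuclei <- data.frame(cell_id = paste0("c", 1:6),
                       volume_um3 = 10 * (1:6) * 10 * 0.5)
  corr <- cell_nucleus_correlation(cols, nuclei)
  expect_equal(corr$r_volume, 1)
  expect_equal(corr$r_area, 1)
  expect_equal(corr$n_cells, 6)
  expect_equal(corr$n_area_pairs, 18)
  expect_error(cell_nucleus_correlation(cols[1:2], nuclei), "at least 3")
})

test_that("equivalent_diameters match the closed forms", {
  d <- equivalent_diameters(600, 25, 330)
  expect_equal(d$d_cell_cylinder, 2 * sqrt(600 / (25 * pi)))
  expect_equal(d$d_nucleus_sphere, (6 * 330 / pi)^(1 / 3))
  expect_error(equivalent_diameters(-1, 25, 330), "positive")
})

test_that("ellipticity_position_test detects rounder apical nuclei", {
  nuc <- data.frame(
    centre_z = c(rep(0.1, 10), 0.25, rep(0.5, 10)),
    ellipticity = c(rnorm(10, 0.2, 0.01), 0.2, rnorm(10, 0.6, 0.01)))
  set.seed(31)
  nuc$ellipticity <- c(rnorm(10, 0.2, 0.01), 0.2, rnorm(10, 0.6, 0.01))
  res <- ellipticity_position_test(nuc)
  expect_equal(res$n_apical, 11)  # boundary 0.25 counts as apical
  expect_equal(res$n_middle, 10)
  expect_lt(res$p_one_sided, 1e-6)
  expect_lt(res$t, 0)
  # reversed pattern is not significant
  rev <- ellipticity_position_test(within(nuc, ellipticity <- rev(ellipticity)))
  expect_gt(rev$p_one_sided, 0.99)
  expect_error(ellipticity_position_test(nuc[1:4, ]), "at least 3")
})
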