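test_that("simulation_config applies and validates defaults", {
  cf <- simulation_config()
  expect_equal(cf$n_cells, 140L)
  expect_equal(cf$n_layers, 30L)
  expect_equal(cf$tissue_height, 25)
  expect_equal(cf$domain_width, sqrt(140 * 24))
  expect_equal(cf$nuclear_volume_fraction, 0.55)
  expect_true(cf$periodic)
  expect_error(simulation_config(n_cells = 5), "n_cells < 7")
  expect_error(simulation_config(nuclear_volume_fraction = 1.2))
  expect_error(simulation_config(n_layers = 2))
  expect_error(simulation_config(base_area_cv = -0.1))
  expect_error(simulation_config(seed_points = matrix(0, 3, 2)))
})

test_that("infeasible nuclear packings are rejected early", {
  cf <- simulation_config(n_cells = 10, nuclear_aspect = 20)
  expect_error(generate_tissue(cf), "infeasible packing")
})

test_that("generate_tissue output is structurally consistent", {
  tis <- fixture_small_tissue()
  cf <- tis$config
  expect_s3_class(tis, "synthetic_tissue")
  expect_length(tis$layers, cf$n_layers)
  expect_length(tis$columns, cf$n_cells)
  expect_length(tis$label_stack, cf$n_layers)
  expect_equal(nrow(tis$nuclei), cf$n_cells)
  # each layer partitions the full domain
  for (ly in tis$layers) {
    expect_s3_class(ly, "polygonal_layer")
    expect_equal(sum(ly$area), cf$domain_width * cf$domain_height,
                 tolerance = 1e-9)
    expect_length(ly$cell_id, cf$n_cells)
    expect_true(all(ly$interior))  # periodic domain
  }
  # columns are strictly ordered and carry their layer's data
  for (cl in tis$columns) {
    expect_false(is.unsorted(cl$z, strictly = TRUE))
    expect_true(all(cl$area > 0))
    expect_equal(cl$height, cf$tissue_height)
    l5 <- tis$layers[[5]]
    expect_equal(cl$area[5], l5$area[match(cl$cell_id, l5$cell_id)])
    expect_setequal(cl$neighbours[[5]], l5$neighbours[[cl$cell_id]])
  }
  # nuclear volume is conserved exactly by construction
  expect_equal(mean(tis$nuclei$volume_um3),
               cf$nuclear_volume_fraction * cf$domain_width *
                 cf$domain_height * cf$tissue_height / cf$n_cells)
})

test_that("generate_tissue is deterministic in its seed", {
  cf <- simulation_config(n_cells = 12, n_layers = 4, seed = 33,
                          pixels_per_cell = 100)
  a <- generate_tissue(cf)
  b <- generate_tissue(cf)
  expect_identical(a$label_stack, b$label_stack)
  expect_identical(a$nuclei, b$nuclei)
  c2 <- generate_tissue(simulation_config(n_cells = 12, n_layers = 4,
                                          seed = 34,
                                          pixels_per_cell = 100))
  expect_false(identical(a$label_stack, c2$label_stack))
})

test_that("iknm position distributions are honoured", {
  cf <- simulation_config(n_cells = 12, n_layers = 4, seed = 3,
                          pixels_per_cell = 100,
                          iknm_positions = list(dist = "fixed",
                                                value = 0.5))
  tis <- generate_tissue(cf)
  expect_equal(tis$nuclei$centre_z, rep(0.5, 12))
  expect_error(simulation_config(n_cells = 12,
                                 iknm_positions = list(dist = "bogus")) |>
                 generate_tissue(), "unknown iknm")
})

test_that("nuclear bulges drive apical-basal area modulation", {
  tis <- fixture_small_tissue()
  # per cell, the largest cross-section should sit near the nuclear centre
  peak_z <- vapply(tis$columns, function(cl) cl$z[which.max(cl$area)],
                   numeric(1))
  ctr <- tis$nuclei$centre_z
  expect_lt(median(abs(peak_z - ctr)), 0.2)
  # and T1 events exist at all (area redistribution changes adjacency)
  expect_gt(nrow(detect_t1_all(tis$columns)), 0)
})

test_that("generate_hex_layer is an exact degenerate lattice", {
  hex <- generate_hex_layer(n_cols = 6, n_rows = 6, px = 10)
  expect_length(hex$cell_id, 36)
  expect_equal(length(unique(hex$area)), 1L)
  expect_true(all(lengths(hex$neighbours) == 6))
  img <- attr(hex, "label_image")
  expect_true(is.matrix(img))
  expect_setequal(as.vector(unique(as.vector(img))), 1:36)
  expect_error(generate_hex_layer(n_rows = 5), "even")
})

test_that("generate_random_layer carries exact polygons", {
  ly <- fixture_random_layer()
  expect_length(ly$cell_id, 400)
  expect_gt(sum(ly$interior), 200)
  expect_setequal(names(ly$polygons), ly$cell_id)
  # polygon shoelace areas are the reported areas
  for (id in ly$cell_id[c(1, 50, 200, 400)])
    expect_equal(oracle_polygon_area(ly$polygons[[id]]),
                 ly$area[match(id, ly$cell_id)])
  # polygons tile the domain
  expect_equal(sum(ly$area), 400 * 24, tolerance = 1e-6)
  # neighbour counts of an exact tessellation average close to 6
  st <- layer_stats(ly)
  expect_gt(st$n_bar, 5.5)
  expect_lt(st$n_bar, 6.5)
  expect_equal(st$area_cv, 0.3, tolerance = 0.1)
})
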