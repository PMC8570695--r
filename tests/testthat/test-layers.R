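# a 2 x 2 block label image: four 5x5-pixel cells
block_image <- function() {
  m <- matrix(0L, 10, 10)
  m[1:5, 1:5] <- 1L
  m[1:5, 6:10] <- 2L
  m[6:10, 1:5] <- 3L
  m[6:10, 6:10] <- 4L
  m
}

test_that("polygonal_layer validates adjacency structure", {
  nb <- list(a = "b", b = "a")
  ly <- polygonal_layer(c("a", "b"), c(1, 2), nb, c(TRUE, TRUE))
  expect_s3_class(ly, "polygonal_layer")
  expect_error(polygonal_layer(c("a", "b"), c(1, 2),
                               list(a = "b", b = character(0)),
                               c(TRUE, TRUE)),
               "asymmetric")
  expect_error(polygonal_layer("a", 1, list(a = "a"), TRUE),
               "self-neighbour")
  expect_error(polygonal_layer("a", 1, list(b = character(0)), TRUE),
               "named by cell_id")
  expect_error(polygonal_layer("a", -1, list(a = character(0)), TRUE))
  expect_error(polygonal_layer("a", 1, list(a = character(0)), TRUE,
                               z = 1.5))
})

test_that("build_layer extracts areas and rook adjacency", {
  ly <- build_layer(block_image(), pixel_size = 2)
  expect_equal(ly$area, rep(100, 4))  # 25 pixels x 4 um^2
  expect_setequal(ly$neighbours[["1"]], c("2", "3"))
  expect_setequal(ly$neighbours[["4"]], c("2", "3"))
  expect_false(any(ly$interior))  # all touch the border
})

test_that("min_contact suppresses single-pixel contacts", {
  m <- block_image()
  # give cells 1 and 4 exactly one contact pixel pair through cell 2
  m[5, 6] <- 4L
  m <- m  # 1 touches 4 at (5,5)-(5,6) once only
  ly1 <- build_layer(m, 1, min_contact = 1L)
  ly2 <- build_layer(m, 1, min_contact = 2L)
  expect_true("4" %in% ly1$neighbours[["1"]])
  expect_false("4" %in% ly2$neighbours[["1"]])
})

test_that("build_layer rejects split labels and bad images", {
  m <- block_image()
  m[1, 1] <- 4L  # label 4 now has a far-away fragment
  expect_error(build_layer(m, 1), "disconnected")
  expect_error(build_layer(matrix(0L, 4, 4), 1), "no cells")
  expect_error(build_layer(matrix(0.5, 4, 4), 1), "non-negative integers")
})

test_that("periodic images have no border cells", {
  ly <- build_layer(block_image(), 1, periodic = TRUE)
  expect_true(all(ly$interior))
  # wrap-around adjacency: on the torus opposite blocks also touch
  expect_setequal(ly$neighbours[["1"]], c("2", "3"))
})

test_that("interior_rings = 2 excludes neighbours of border cells", {
  # 4 x 4 block grid, 3-pixel blocks
  m <- matrix(0L, 12, 12)
  for (r in 0:3) for (c in 0:3)
    m[r * 3 + 1:3, c * 3 + 1:3] <- r * 4L + c + 1L
  ly1 <- build_layer(m, 1, interior_rings = 1L)
  ly2 <- build_layer(m, 1, interior_rings = 2L)
  # ring 1: the four centre cells are interior
  expect_setequal(ly1$cell_id[ly1$interior], c("6", "7", "10", "11"))
  # ring 2: every cell is adjacent to a border cell here
  expect_false(any(ly2$interior))
})

test_that("layer_stats is exact on the hexagonal lattice", {
  hex <- generate_hex_layer(n_cols = 8, n_rows = 8)
  st <- layer_stats(hex)
  expect_identical(st$n_bar, 6)
  expect_identical(st$area_cv, 0)
  expect_identical(st$hex_fraction, 1)
  expect_equal(st$aw_table$m_n, 6)
  expect_equal(st$lewis_table$lewis_ratio, 1)
  expect_equal(st$n_interior, 64)
})

test_that("layer_stats excludes border and degenerate cells", {
  nb <- list(a = c("b", "c", "d"), b = c("a", "c", "d"),
             c = c("a", "b", "d"), d = c("a", "b", "c"), e = character(0))
  ly <- polygonal_layer(letters[1:5], c(1, 1, 1, 1, 9), nb,
                        c(TRUE, TRUE, TRUE, TRUE, TRUE))
  st <- layer_stats(ly)  # e has n = 0 < 3 and must be dropped
  expect_equal(st$n_interior, 4)
  expect_equal(st$n_bar, 3)
  expect_equal(st$area_cv, 0)
  ly2 <- polygonal_layer(letters[1:5], c(1, 1, 1, 1, 9), nb,
                         c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(layer_stats(ly2)$n_interior, 2)
  ly3 <- polygonal_layer("e", 1, list(e = character(0)), TRUE)
  expect_error(layer_stats(ly3), "no interior cells")
})

test_that("polygon_internal_angles handles both orientations and reflex corners", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_internal_angles(sq), rep(90, 4))
  expect_equal(polygon_internal_angles(sq[4:1, ]), rep(90, 4))
  th <- (0:5) * pi / 3
  hexagon <- cbind(cos(th), sin(th))
  expect_equal(polygon_internal_angles(hexagon), rep(120, 6))
  # L-shape: one reflex corner of 270 degrees
  ell <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2))
  ang <- polygon_internal_angles(ell)
  expect_equal(sort(ang), c(rep(90, 5), 270))
  expect_equal(sum(ang), (6 - 2) * 180)
  expect_error(polygon_internal_angles(rbind(c(0, 0), c(1, 1))))
})

test_that("side_and_angle_tables matches regular-polygon references", {
  th <- (0:5) * pi / 3
  polys <- list(a = cbind(cos(th), sin(th)),
                b = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  ly <- polygonal_layer(c("a", "b"), c(2.6, 1),
                        list(a = "b", b = "a"), c(TRUE, TRUE),
                        polygons = polys)
  tabs <- side_and_angle_tables(ly)
  expect_equal(tabs$angle_table$mean_angle, regular_angle(c(4, 6)))
  expect_equal(tabs$angle_table$n, c(4, 6))
  # hexagon edge 1, square edge 1, global mean edge 1
  expect_equal(tabs$side_table$side_ratio, c(1, 1))
  ly2 <- polygonal_layer(c("a", "b"), c(2.6, 1),
                         list(a = "b", b = "a"), c(TRUE, TRUE),
                         polygons = polys["a"])
  expect_error(side_and_angle_tables(ly2), "missing for cell")
})
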