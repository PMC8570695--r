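test_that("cell_column validates its ordering invariants", {
  expect_error(cell_column("a", c(0, 2, 1), c(0.1, 0.5, 0.9),
                           rep(1, 3), rep(list("x"), 3)),
               "strictly ordered")
  expect_error(cell_column("a", 0:2, c(0.1, 0.1, 0.9),
                           rep(1, 3), rep(list("x"), 3)),
               "strictly ordered")
  expect_error(cell_column("a", 0:1, c(0.2, 0.8), c(1, -1),
                           rep(list("x"), 2)))
})

test_that("detect_t1 reports gains, losses and positions exactly", {
  nbrs <- list(c("a", "b", "c"), c("a", "b", "c"), c("a", "b", "d"),
               c("a", "b", "d", "e"))
  cl <- cell_column("x", 0:3, c(0.125, 0.375, 0.625, 0.875),
                    c(10, 11, 12, 13), nbrs, height = 20)
  ev <- detect_t1(cl)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$interface_index, c(2, 3))
  expect_equal(ev$rel_position, c(0.5, 0.75))
  expect_equal(ev$delta_n, c(0, 1))
  expect_equal(ev$gained, c("d", "e"))
  expect_equal(ev$lost, c("c", ""))
  expect_equal(ev$delta_area, c(1, 1))
  # scutoid-type exchange (delta_n = 0) is an event
  expect_true(any(ev$delta_n == 0))
})

test_that("columns without changes yield an empty event frame", {
  cl <- column_with_transitions("q", 0)
  ev <- detect_t1(cl)
  expect_equal(nrow(ev), 0)
  expect_named(ev, c("cell_id", "interface_index", "rel_position",
                     "delta_n", "gained", "lost", "delta_area",
                     "delta_nuclear_area"))
  expect_error(detect_t1(cell_column("a", 0, 0.5, 1, list("x"))),
               "two entries")
})

test_that("detect_t1_all combines events across columns", {
  cols <- list(column_with_transitions("a", 2),
               column_with_transitions("b", 0),
               column_with_transitions("c", 3))
  ev <- detect_t1_all(cols)
  expect_equal(nrow(ev), 5)
  expect_setequal(unique(ev$cell_id), c("a", "c"))
  expect_equal(nrow(detect_t1_all(list())), 0)
})

test_that("transition_stats computes exact count statistics", {
  cols <- lapply(seq_len(25), function(i)
    column_with_transitions(paste0("c", i), (i - 1) %% 5))
  st <- transition_stats(cols)
  counts <- (0:24) %% 5
  expect_equal(unname(st$counts_per_cell), counts)
  expect_equal(st$mean, mean(counts))
  expect_equal(st$variance, var(counts))
  expect_equal(st$dispersion_index, var(counts) / mean(counts))
  expect_equal(st$n_events, sum(counts))
  expect_equal(st$n_cells, 25)
  # 95% CI is symmetric about the mean with the normal half-width
  pos <- unlist(lapply(cols, function(cl) detect_t1(cl)$rel_position))
  half <- qnorm(0.975) * sd(pos) / sqrt(length(pos))
  expect_equal(st$rel_position_ci, st$mean_rel_position + c(-half, half))
})

test_that("inter-transition distances scale with cell height", {
  cl <- column_with_transitions("a", 3, n_layers = 10, height = 30)
  ev <- detect_t1(cl)
  st <- transition_stats(list(cl))
  expect_equal(st$inter_transition_distances, diff(ev$rel_position) * 30)
  st2 <- transition_stats(list(cl), interior_only = FALSE)
  expect_equal(length(st2$inter_transition_distances),
               length(st$inter_transition_distances) + 2)
  expect_equal(sum(st2$inter_transition_distances), 30)
})

test_that("poisson_gof behaves like a calibrated chi-squared test", {
  expect_error(poisson_gof(rep(2, 10)), "at least 20")
  expect_error(poisson_gof(rep(0, 50)), "fewer than 3 bins")
  set.seed(8)
  p <- poisson_gof(rpois(500, 3))
  expect_gt(p$p_value, 0.01)
  expect_equal(p$p_value, pchisq(p$chi2, p$dof, lower.tail = FALSE))
  # strongly overdispersed counts are rejected
  bad <- c(rep(0, 250), rep(6, 250))
  expect_lt(poisson_gof(bad)$p_value, 1e-10)
})

test_that("generate_poisson_columns is seeded and bounded", {
  a <- generate_poisson_columns(20, 2, seed = 5)
  b <- generate_poisson_columns(20, 2, seed = 5)
  expect_identical(detect_t1_all(a), detect_t1_all(b))
  expect_error(generate_poisson_columns(10, -1), "non-negative")
  none <- generate_poisson_columns(10, 0, seed = 1)
  expect_equal(nrow(detect_t1_all(none)), 0)
  # at most one exchange per interface
  many <- generate_poisson_columns(50, 40, n_layers = 5, seed = 2)
  counts <- vapply(many, function(cl) nrow(detect_t1(cl)), integer(1))
  expect_true(all(counts <= 4))
})

test_that("column_interfaces enumerates all interfaces", {
  cols <- list(column_with_transitions("a", 2, n_layers = 6),
               column_with_transitions("b", 0, n_layers = 6))
  ii <- column_interfaces(cols)
  expect_equal(nrow(ii), 10)
  expect_equal(sum(ii$changed), 2)
  ev <- detect_t1_all(cols)
  expect_setequal(paste(ev$cell_id, ev$interface_index),
                  paste(ii$cell_id, ii$interface_index)[ii$changed])
})

test_that("area_change_profile bins events by area change", {
  ev <- data.frame(cell_id = "a", interface_index = 1:4,
                   rel_position = c(0.2, 0.4, 0.6, 0.8),
                   delta_n = c(1, -1, 1, 0),
                   gained = "", lost = "",
                   delta_area = c(-3, -1, 2, 4),
                   delta_nuclear_area = NA_real_)
  pr <- area_change_profile(ev, breaks = c(-5, 0, 5))
  expect_equal(pr$n_events, c(2, 2))
  expect_equal(pr$frac_gain, c(0.5, 0.5))
  expect_equal(pr$frac_lose, c(0.5, 0))
  expect_false(any(pr$empty))
  pr2 <- area_change_profile(ev, breaks = c(-20, -10, 0, 5))
  expect_true(pr2$empty[1])
  expect_true(is.na(pr2$frac_gain[1]))
  expect_error(area_change_profile(ev, c(-5, 0, 5), source = "nucleus"),
               "delta_nuclear_area")
})

test_that("area_change_profile rates use interface opportunities", {
  cols <- list(column_with_transitions("a", 2, n_layers = 6))
  ev <- detect_t1_all(cols)
  ii <- column_interfaces(cols)
  pr <- area_change_profile(ev, breaks = c(-1, 1), interfaces = ii)
  expect_equal(pr$n_interfaces, 5)
  expect_equal(pr$rate_gain, 0)  # helper swaps keep n constant
})

test_that("position_histogram is a normalised histogram", {
  ev <- data.frame(rel_position = c(0.05, 0.05, 0.55, 0.95))
  h <- position_histogram(ev, n_bins = 10)
  expect_equal(sum(h$count), 4)
  expect_equal(sum(h$fraction), 1)
  expect_equal(h$count[1], 2)
  expect_equal(h$count[10], 1)
  expect_error(position_histogram(ev[0, , drop = FALSE]), "no events")
})

test_that("seeded generators restore the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_poisson_columns(5, 1, seed = 99))
  expect_identical(.Random.seed, before)
  invisible(generate_hex_layer())
  expect_identical(.Random.seed, before)
})
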