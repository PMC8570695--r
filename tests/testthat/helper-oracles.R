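# Independent brute-force oracles and shared fixtures for the test suite.

# Brute-force region adjacency from raw pixel pairs: enumerate every
# 4-connected pixel pair in R, count contacts per unordered label pair,
# keep pairs with >= min_contact contacts not involving background.
# Deliberately written without the package's C++ path.
oracle_adjacency <- function(m, periodic, min_contact = 2L) {
  nr <- nrow(m); nc <- ncol(m)
  prs <- rbind(cbind(as.vector(m[-nr, ]), as.vector(m[-1, ])),
               cbind(as.vector(m[, -nc]), as.vector(m[, -1])))
  if (periodic)
    prs <- rbind(prs, cbind(m[nr, ], m[1, ]), cbind(m[, nc], m[, 1]))
  prs <- prs[prs[, 1] != prs[, 2], , drop = FALSE]
  key <- paste(pmin(prs[, 1], prs[, 2]), pmax(prs[, 1], prs[, 2]))
  tab <- table(key)
  keep <- strsplit(names(tab)[tab >= min_contact], " ", fixed = TRUE)
  labs <- sort(unique(as.vector(m)))
  labs <- labs[labs > 0]
  out <- stats::setNames(
    replicate(length(labs), character(0), simplify = FALSE),
    as.character(labs))
  for (p in keep) {
    if (p[1] == "0") next
    out[[p[1]]] <- c(out[[p[1]]], p[2])
    out[[p[2]]] <- c(out[[p[2]]], p[1])
  }
  lapply(out, sort)
}

# shoelace area, an independent check of polygon areas
oracle_polygon_area <- function(v) {
  k <- nrow(v)
  abs(sum(v[, 1] * v[c(2:k, 1), 2] - v[c(2:k, 1), 1] * v[, 2])) / 2
}

# points on an ellipse with semi-axes a, b rotated by phi, centred at ctr
ellipse_points <- function(theta, a, b, phi = 0, ctr = c(0, 0)) {
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  sweep(cbind(a * cos(theta), b * sin(theta)) %*% t(R), 2, ctr, "+")
}

# deterministic cell column with k neighbour exchanges at prescribed
# interfaces (no RNG); n_layers sections on [0, 1]
column_with_transitions <- function(id, k, n_layers = 10L, height = 25) {
  stopifnot(k <= n_layers - 1)
  ifs <- if (k > 0) round(seq(1, n_layers - 1, length.out = k)) else integer(0)
  stopifnot(!anyDuplicated(ifs))
  cur <- paste0("n", 1:6)
  nxt <- 7L
  nbrs <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    if (l > 1 && (l - 1) %in% ifs) {
      cur <- c(cur[-1], paste0("n", nxt))
      nxt <- nxt + 1L
    }
    nbrs[[l]] <- cur
  }
  cell_column(id, 0:(n_layers - 1), (seq_len(n_layers) - 0.5) / n_layers,
              rep(20, n_layers), nbrs, height = height)
}

# 59 columns carrying 169 transitions in total (51 x 3 + 8 x 2)
tip_columns <- function() {
  ks <- c(rep(3, 51), rep(2, 8))
  lapply(seq_along(ks), function(i)
    column_with_transitions(paste0("c", i), ks[i]))
}

# memoised expensive fixtures, shared across test files
.fixture_env <- new.env(parent = emptyenv())

fixture_random_layer <- function() {
  if (is.null(.fixture_env$layer))
    .fixture_env$layer <- generate_random_layer(seed = 11)
  .fixture_env$layer
}

fixture_tissue <- function() {
  if (is.null(.fixture_env$tissue))
    .fixture_env$tissue <- generate_tissue(simulation_config(seed = 7))
  .fixture_env$tissue
}

fixture_small_tissue <- function() {
  if (is.null(.fixture_env$small))
    .fixture_env$small <- generate_tissue(
      simulation_config(n_cells = 30, n_layers = 8, seed = 2,
                        pixels_per_cell = 150))
  .fixture_env$small
}
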