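#' Configuration for the synthetic pseudostratified epithelium
#'
#' Collects the generator parameters. Defaults emulate a distal embryonic
#' lung tube: ~140 cell columns spanning a 25 um pseudostratified layer,
#' nuclei occupying on average 55% of the cell volume, prolate nuclei
#' (2:1), and a baseline cross-sectional area spread of 0.3 on top of
#' which the travelling nuclear bulge generates the apical-basal area
#' profile.
#'
#' @param n_cells number of cell columns (>= 7 on a periodic domain).
#' @param n_layers number of cross-sections along the apical-basal axis
#'   (>= 3); layer index 0 is apical.
#' @param tissue_height apical-basal thickness, um.
#' @param domain_width,domain_height lateral extent, um; default sized so
#'   the mean cell cross-section is 24 um^2.
#' @param periodic logical; toroidal lateral domain.
#' @param nuclear_volume_fraction target mean nucleus/cell volume ratio,
#'   in (0, 1).
#' @param nuclear_aspect principal-axis elongation of nuclei (apical-basal
#'   semi-axis over lateral), > 0.
#' @param iknm_positions distribution spec for the relative nuclear centre
#'   z: `list(dist = "apical_biased")` (default: uniform on
#'   `[0.15, 0.85]` with 20% of nuclei placed in the apical quarter,
#'   echoing apical mitoses), `list(dist = "uniform", min =, max =)`, or
#'   `list(dist = "fixed", value =)`.
#' @param base_area_cv cell-to-cell baseline area spread (>= 0).
#' @param seed integer; every random draw of the generator derives from
#'   it.
#' @param seed_points optional n_cells x 2 matrix of lateral seed
#'   coordinates (e.g. [hex_lattice_seeds()]); random blue-noise
#'   placement when NULL.
#' @param pixels_per_cell raster resolution of the tessellation.
#' @param jitter_sd per-layer standard deviation of the correlated seed
#'   random walk, um; defaults to 3% of the mean cell diameter.
#' @param min_contact adjacency threshold in boundary pixel pairs.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 140L, n_layers = 30L,
                              tissue_height = 25,
                              domain_width = NULL, domain_height = NULL,
                              periodic = TRUE,
                              nuclear_volume_fraction = 0.55,
                              nuclear_aspect = 2,
                              iknm_positions = list(dist = "apical_biased"),
                              base_area_cv = 0.3, seed = 1L,
                              seed_points = NULL,
                              pixels_per_cell = 250,
                              jitter_sd = NULL, min_contact = 2L) {
  if (is.null(domain_width)) domain_width <- sqrt(n_cells * 24)
  if (is.null(domain_height)) domain_height <- sqrt(n_cells * 24)
  stopifnot(n_layers >= 3, tissue_height > 0, domain_width > 0,
            domain_height > 0, nuclear_volume_fraction > 0,
            nuclear_volume_fraction < 1, nuclear_aspect > 0,
            base_area_cv >= 0, pixels_per_cell >= 20)
  if (periodic && n_cells < 7)
    stop("n_cells < 7 on a periodic domain: tessellation adjacency undefined")
  if (!periodic && n_cells < 1) stop("n_cells must be positive")
  if (is.null(jitter_sd))
    jitter_sd <- 0.03 * sqrt(domain_width * domain_height / n_cells)
  if (!is.null(seed_points)) {
    seed_points <- as.matrix(seed_points)
    stopifnot(nrow(seed_points) == n_cells, ncol(seed_points) == 2)
  }
  structure(list(n_cells = as.integer(n_cells),
                 n_layers = as.integer(n_layers),
                 tissue_height = tissue_height,
                 domain_width = domain_width,
                 domain_height = domain_height,
                 periodic = periodic,
                 nuclear_volume_fraction = nuclear_volume_fraction,
                 nuclear_aspect = nuclear_aspect,
                 iknm_positions = iknm_positions,
                 base_area_cv = base_area_cv,
                 seed = as.integer(seed),
                 seed_points = seed_points,
                 pixels_per_cell = pixels_per_cell,
                 jitter_sd = jitter_sd,
                 min_contact = as.integer(min_contact)),
            class = "simulation_config")
}

sample_iknm <- function(spec, n) {
  dist <- if (is.null(spec$dist)) "apical_biased" else spec$dist
  switch(dist,
    apical_biased = {
      apical <- runif(n) < 0.2
      z <- runif(n, 0.15, 0.85)
      z[apical] <- runif(sum(apical), 0, 0.25)
      z
    },
    uniform = runif(n, spec$min, spec$max),
    fixed = rep(spec$value, n),
    stop("unknown iknm_positions dist: ", dist))
}

#' Generate a synthetic pseudostratified epithelium
#'
#' Builds a full synthetic tissue: per-cell target cross-sectional area
#' profiles (a cell-specific baseline plus the elliptic cross-section of
#' its nucleus at each section height, rescaled per layer to the domain
#' area), realised per layer by a weighted power-diagram tessellation of
#' slowly drifting seed points whose weights are tuned to the targets.
#' Lateral neighbour exchanges (T1L events) then arise purely from area
#' redistribution as the nuclear bulge travels along the apical-basal
#' axis, which is the mechanism the downstream statistics assume. The
#' output is bit-reproducible for a fixed config (including seed).
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_tissue`: list with `layers` (list
#'   of [polygonal_layer()], index 0 apical), `columns` (list of
#'   [cell_column()]), `nuclei` (data.frame: cell_id, centre_z,
#'   volume_um3, semi_xy, semi_z), `label_stack` and `nucleus_stack`
#'   (lists of integer matrices), `pixel_size`, `seeds`, `config`.
#' @export
generate_tissue <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  W <- cf$domain_width; H <- cf$domain_height
  Ht <- cf$tissue_height
  n <- cf$n_cells
  A0 <- W * H / n

  with_seed(cf$seed, {
    seeds <- if (!is.null(cf$seed_points)) cf$seed_points else
      best_candidate_seeds(n, W, H, periodic = cf$periodic)

    b <- pmax(0.2, 1 + cf$base_area_cv * rnorm(n))

    v_cell <- A0 * Ht * b / mean(b)
    v_nuc <- cf$nuclear_volume_fraction * v_cell
    r_xy <- (3 * v_nuc / (4 * pi * cf$nuclear_aspect))^(1 / 3)
    semi_z <- cf$nuclear_aspect * r_xy
    if (any(2 * semi_z > Ht))
      stop("infeasible packing: nuclear semi-axis exceeds half the tissue height")
    centre_z <- sample_iknm(cf$iknm_positions, n)
    centre_z <- pmin(pmax(centre_z, semi_z / Ht), 1 - semi_z / Ht)

    # nuclear cross-section of cell i at section height zeta (um)
    nuc_cross <- function(zeta) {
      u <- (zeta - centre_z * Ht) / semi_z
      ifelse(abs(u) < 1, pi * r_xy^2 * (1 - u^2), 0)
    }

    h <- sqrt(A0 / cf$pixels_per_cell)
    nx <- max(16L, round(W / h)); ny <- max(16L, round(H / h))
    pixel_size <- sqrt((W / nx) * (H / ny))

    # correlated per-layer seed drift (columnar continuity)
    steps <- array(rnorm(cf$n_layers * n * 2, sd = cf$jitter_sd),
                   dim = c(cf$n_layers, n, 2))
    steps[1, , ] <- 0

    zs <- (seq_len(cf$n_layers) - 0.5) / cf$n_layers
    layers <- vector("list", cf$n_layers)
    label_stack <- vector("list", cf$n_layers)
    nucleus_stack <- vector("list", cf$n_layers)
    areas <- matrix(NA_real_, cf$n_layers, n)
    nuclear_area <- matrix(0, cf$n_layers, n)
    w <- numeric(n)
    jit <- matrix(0, n, 2)

    for (l in seq_len(cf$n_layers)) {
      jit <- jit + steps[l, , ]
      s_l <- seeds + jit
      if (cf$periodic) {
        s_l[, 1] <- s_l[, 1] %% W
        s_l[, 2] <- s_l[, 2] %% H
      } else {
        s_l[, 1] <- pmin(pmax(s_l[, 1], 0), W)
        s_l[, 2] <- pmin(pmax(s_l[, 2], 0), H)
      }
      cross <- nuc_cross(zs[l] * Ht)
      raw <- (1 - cf$nuclear_volume_fraction) * A0 * b + cross
      target <- raw / sum(raw) * W * H
      if (any(target > 0.4 * W * H))
        stop(sprintf(
          "infeasible packing at layer %d: a target area exceeds 40%% of the domain",
          l - 1))
      pd <- tryCatch(
        power_diagram(s_l, target, W, H, nx = nx, ny = ny,
                      periodic = cf$periodic, weights = w,
                      relax = if (l == 1 && is.null(cf$seed_points)) 2L
                              else 0L),
        error = function(e)
          stop(sprintf("layer %d: %s", l - 1, conditionMessage(e))))
      if (l == 1 && is.null(cf$seed_points)) {
        # adopt the relaxed apical layout as the column anchor
        seeds <- pd$seeds
        s_l <- seeds
      }
      w <- pd$weights
      areas[l, ] <- pd$areas
      nuclear_area[l, ] <- pmin(cross, pd$areas)
      label_stack[[l]] <- pd$labels
      nucleus_stack[[l]] <- rasterise_nuclei(pd$labels, s_l, cross, W, H,
                                             cf$periodic)
      layers[[l]] <- build_layer(pd$labels, pixel_size, z = zs[l],
                                 layer_index = l - 1L,
                                 periodic = cf$periodic,
                                 min_contact = cf$min_contact)
    }

    nucleus_stack <- clean_nucleus_stack(nucleus_stack)

    columns <- lapply(seq_len(n), function(i) {
      id <- as.character(i)
      nbrs <- lapply(layers, function(ly) ly$neighbours[[id]])
      cell_column(id, 0:(cf$n_layers - 1L), zs, areas[, i], nbrs,
                  nuclear_area = nuclear_area[, i], height = Ht)
    })

    nuclei <- data.frame(cell_id = as.character(seq_len(n)),
                         centre_z = centre_z,
                         volume_um3 = v_nuc,
                         semi_xy = r_xy, semi_z = semi_z)

    structure(list(layers = layers, columns = columns, nuclei = nuclei,
                   label_stack = label_stack,
                   nucleus_stack = nucleus_stack,
                   pixel_size = pixel_size, seeds = seeds, config = cf),
              class = "synthetic_tissue")
  })
}

# keep, per nucleus, only its largest 6-connected voxel component:
# clipping the nuclear disk by a drifting cell boundary can strand small
# fragments that would make the voxel nucleus disconnected
clean_nucleus_stack <- function(stack) {
  arr <- array(0L, c(nrow(stack[[1]]), ncol(stack[[1]]), length(stack)))
  for (l in seq_along(stack)) arr[, , l] <- stack[[l]]
  cm <- component_map3d(arr)
  idx <- which(arr > 0)
  if (length(idx) > 0) {
    cl <- cm[idx]
    lb <- arr[idx]
    sz <- tabulate(cl)
    best <- tapply(cl, lb, function(comps) comps[which.max(sz[comps])])
    arr[idx[cl != best[as.character(lb)]]] <- 0L
  }
  lapply(seq_len(dim(arr)[3]), function(l) arr[, , l])
}

# nucleus label mask: pixels of a cell within its nuclear cross-section
# radius around the cell's seed position at this layer
rasterise_nuclei <- function(labels, seeds, cross, W, H, periodic) {
  out <- matrix(0L, nrow(labels), ncol(labels))
  present <- which(cross > 0)
  if (length(present) == 0) return(out)
  hx <- W / ncol(labels); hy <- H / nrow(labels)
  xc <- (seq_len(ncol(labels)) - 0.5) * hx
  yc <- (seq_len(nrow(labels)) - 0.5) * hy
  for (i in present) {
    rho <- sqrt(cross[i] / pi)
    dx <- abs(xc - seeds[i, 1])
    dy <- abs(yc - seeds[i, 2])
    if (periodic) {
      dx <- pmin(dx, W - dx)
      dy <- pmin(dy, H - dy)
    }
    mask <- outer(dy^2, dx^2, "+") <= rho^2
    mask <- mask & labels == i
    out[mask] <- i
  }
  out
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf(
    "<synthetic_tissue> %d cells x %d layers, %.1f x %.1f x %.1f um%s\n",
    x$config$n_cells, x$config$n_layers, x$config$domain_width,
    x$config$domain_height, x$config$tissue_height,
    if (x$config$periodic) " (periodic)" else ""))
  invisible(x)
}

#' Exact regular hexagonal layer
#'
#' A periodic label image tessellated into identical hexagonal cells
#' (offset-row lattice), constructed by tiling one analytically assigned
#' fundamental block, so all cell areas are exactly equal and every cell
#' has exactly six neighbours. The degenerate reference case of the
#' lattice statistics: n_bar = 6, hexagon fraction 1, area CV = 0.
#'
#' @param n_cols,n_rows lattice dimensions; `n_rows` must be even.
#' @param px pixels per column spacing (row spacing is
#'   `round(px * sqrt(3) / 2)`).
#' @param pixel_size pixel edge length, um.
#' @param z,layer_index passed to [build_layer()].
#' @return a [polygonal_layer()] (periodic). The label image is in
#'   `attr(, "label_image")`.
#' @export
generate_hex_layer <- function(n_cols = 10L, n_rows = 10L, px = 12L,
                               pixel_size = 1, z = 0, layer_index = 0L) {
  if (n_rows %% 2 != 0) stop("n_rows must be even")
  stopifnot(n_cols >= 3, n_rows >= 4, px >= 6)
  py <- round(px * sqrt(3) / 2)

  # assign one fundamental block (px x 2*py) against the local seed
  # neighbourhood; identical for every block by translation
  cand <- expand.grid(r = -2:3, c = -2:2)
  seed_x <- cand$c * px + px / 2 + (cand$r %% 2) * px / 2
  seed_y <- cand$r * py + py / 2
  block_winner_r <- matrix(0L, 2 * py, px)
  block_winner_c <- matrix(0L, 2 * py, px)
  # irrational sub-pixel sampling offset: no pixel is ever exactly
  # equidistant from two seeds, so assignment is tie-free and every cell
  # is an exact translate of the same pixel set
  ox <- 0.5 + sqrt(2) / 97
  oy <- 0.5 + sqrt(3) / 89
  for (iy in seq_len(2 * py)) {
    for (ix in seq_len(px)) {
      d2 <- (ix - ox - seed_x)^2 + (iy - oy - seed_y)^2
      wn <- which.min(d2)  # deterministic tie-break: first candidate
      block_winner_r[iy, ix] <- cand$r[wn]
      block_winner_c[iy, ix] <- cand$c[wn]
    }
  }

  ngx <- n_cols * px
  ngy <- n_rows * py
  gx <- matrix(rep(0:(ngx - 1), each = ngy), ngy, ngx)
  gy <- matrix(rep(0:(ngy - 1), times = ngx), ngy, ngx)
  bx <- gx %% px + 1L
  by <- gy %% (2L * py) + 1L
  idx <- cbind(as.vector(by), as.vector(bx))
  row_g <- ((gy %/% (2L * py)) * 2L + block_winner_r[idx]) %% n_rows
  col_g <- (gx %/% px + block_winner_c[idx]) %% n_cols
  labels <- matrix(as.integer(row_g * n_cols + col_g + 1L), ngy, ngx)

  layer <- build_layer(labels, pixel_size, z = z,
                       layer_index = layer_index, periodic = TRUE,
                       min_contact = 2L)
  attr(layer, "label_image") <- labels
  layer
}

#' Random bounded polygonal layer
#'
#' A single non-periodic tessellated layer with a prescribed
#' cell-to-cell area spread: blue-noise seeds, truncated-normal target
#' areas with the given CV, power-diagram realisation. Convenience
#' wrapper used for law-compliance checks on lattices with many interior
#' cells.
#'
#' @param n_cells number of cells.
#' @param area_cv target coefficient of variation of cell areas.
#' @param mean_area mean cell area, um^2.
#' @param seed integer seed.
#' @param pixels_per_cell raster resolution of the weight fit.
#' @return a [polygonal_layer()] (non-periodic, border cells flagged)
#'   with exact polygon outlines in `$polygons`; the raster label image
#'   is in `attr(, "label_image")`.
#' @export
generate_random_layer <- function(n_cells = 400L, area_cv = 0.3,
                                  mean_area = 24, seed = 1L,
                                  pixels_per_cell = 400) {
  side <- sqrt(n_cells * mean_area)
  with_seed(seed, {
    seeds <- best_candidate_seeds(n_cells, side, side, periodic = FALSE)
    targets <- pmax(0.2, 1 + area_cv * rnorm(n_cells)) * mean_area
    h <- sqrt(mean_area / pixels_per_cell)
    nx <- round(side / h)
    pd <- power_diagram(seeds, targets, side, side, nx = nx, ny = nx,
                        periodic = FALSE, relax = 2L)
    # exact polygonal cells from the fitted diagram: areas, adjacency
    # and vertex outlines free of raster discretisation artifacts
    cells <- power_diagram_cells(pd$seeds, pd$weights, side, side,
                                 periodic = FALSE)
    if (any(cells$areas <= 0))
      stop("degenerate (empty) power-diagram cell in random layer")
    ids <- as.character(seq_len(n_cells))
    # two rings: neighbour-of-neighbour statistics near the cropped edge
    # would otherwise average over cells with truncated neighbourhoods
    interior <- !cells$on_boundary
    ring1 <- which(cells$on_boundary)
    interior[vapply(cells$neighbours,
                    function(nb) any(nb %in% ring1), logical(1))] <- FALSE
    layer <- polygonal_layer(
      ids, cells$areas,
      stats::setNames(lapply(cells$neighbours, as.character), ids),
      interior,
      polygons = stats::setNames(cells$polygons, ids))
    attr(layer, "label_image") <- pd$labels
    layer
  })
}
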