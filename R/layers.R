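#' Polygonal layer: one cross-section of an epithelium
#'
#' Container for a single tissue cross-section: per-cell area, neighbour
#' sets, interior flags and (optionally) polygon outlines. Usually built
#' from a label image by [build_layer()] or produced by
#' [generate_tissue()].
#'
#' @param cell_id integer or character cell identifiers.
#' @param area numeric cell cross-sectional areas, um^2 (all > 0).
#' @param neighbours named list of neighbour id vectors; must be symmetric
#'   and free of self-neighbours.
#' @param interior logical; cells away from the section border whose
#'   statistics are trusted. Border cells stay in the adjacency so they
#'   still contribute to their interior neighbours' neighbourhood means.
#' @param layer_index integer position in the stack (0 = apical).
#' @param z relative apical-basal position in `[0, 1]` (0 = apical).
#' @param polygons optional named list of ordered vertex matrices (k x 2).
#' @return object of class `polygonal_layer`.
#' @export
polygonal_layer <- function(cell_id, area, neighbours, interior,
                            layer_index = 0L, z = 0,
                            polygons = NULL) {
  cell_id <- as.character(cell_id)
  stopifnot(length(area) == length(cell_id),
            length(interior) == length(cell_id),
            all(area > 0), z >= 0, z <= 1)
  if (is.null(names(neighbours)) || !setequal(names(neighbours), cell_id))
    stop("neighbours must be a list named by cell_id")
  neighbours <- lapply(neighbours, as.character)
  for (id in cell_id) {
    if (id %in% neighbours[[id]]) stop("self-neighbour for cell ", id)
    for (nb in neighbours[[id]]) {
      if (nb %in% cell_id && !(id %in% neighbours[[nb]]))
        stop("asymmetric adjacency between ", id, " and ", nb)
    }
  }
  structure(list(layer_index = as.integer(layer_index), z = z,
                 cell_id = cell_id, area = as.numeric(area),
                 neighbours = neighbours[cell_id],
                 interior = as.logical(interior),
                 polygons = polygons),
            class = "polygonal_layer")
}

#' @export
print.polygonal_layer <- function(x, ...) {
  cat(sprintf("<polygonal_layer> index %d, z = %.3f: %d cells (%d interior)\n",
              x$layer_index, x$z, length(x$cell_id), sum(x$interior)))
  invisible(x)
}

#' Build a polygonal layer from an integer label image
#'
#' Extracts cell areas and the region adjacency graph from a labelled
#' cross-section. Two cells are considered neighbours iff they share at
#' least `min_contact` boundary pixel pairs under 4-connectivity, which
#' suppresses spurious contacts at four-way raster junctions (a proper
#' tricellular junction has three-way vertices). Label 0 is background.
#' On non-periodic images, cells touching the image border are flagged
#' non-interior; they are kept in the adjacency but excluded from layer
#' statistics.
#'
#' @param label_image integer matrix; 0 = background, cells 1..N.
#' @param pixel_size pixel edge length, um.
#' @param z relative apical-basal position of the section.
#' @param layer_index integer stack index (0 = apical).
#' @param periodic logical; treat the image as toroidal (no border cells).
#' @param min_contact minimum shared boundary pixel pairs for adjacency.
#' @param interior_rings how many cell rings from the image border to
#'   flag non-interior (non-periodic only). The default 1 excludes only
#'   cells touching the border. With 2, cells adjacent to border cells
#'   are excluded as well, so every neighbour of an interior cell has a
#'   complete (untruncated) neighbourhood -- relevant for
#'   neighbour-of-neighbour statistics near a cropped image edge.
#' @return [polygonal_layer()] object.
#' @export
build_layer <- function(label_image, pixel_size, z = 0, layer_index = 0L,
                        periodic = FALSE, min_contact = 2L,
                        interior_rings = 1L) {
  stopifnot(is.matrix(label_image), pixel_size > 0)
  m <- label_image
  if (any(m %% 1 != 0) || any(m < 0))
    stop("label image must contain non-negative integers")
  storage.mode(m) <- "integer"
  labs <- sort(unique(as.vector(m)))
  labs <- labs[labs > 0]
  if (length(labs) == 0) stop("label image contains no cells")

  comp <- label_component_counts(m, periodic)
  bad <- labs[comp[labs + 1L] > 1L]
  if (length(bad) > 0)
    stop("label(s) with multiple disconnected components: ",
         paste(bad, collapse = ", "))

  counts <- tabulate(m, nbins = max(labs))
  area <- counts[labs] * pixel_size^2

  cc <- contact_counts(m, periodic)
  cc <- cc[cc$a > 0 & cc$count >= min_contact, , drop = FALSE]
  ids <- as.character(labs)
  neighbours <- stats::setNames(
    replicate(length(labs), character(0), simplify = FALSE), ids)
  for (k in seq_len(nrow(cc))) {
    a <- as.character(cc$a[k]); b <- as.character(cc$b[k])
    neighbours[[a]] <- c(neighbours[[a]], b)
    neighbours[[b]] <- c(neighbours[[b]], a)
  }

  if (periodic) {
    interior <- rep(TRUE, length(labs))
  } else {
    border_labs <- unique(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
    interior <- !(labs %in% border_labs)
    ring <- 1L
    while (ring < interior_rings) {
      excluded <- as.character(labs[!interior])
      touches <- vapply(as.character(labs), function(id)
        any(neighbours[[id]] %in% excluded), logical(1))
      interior <- interior & !touches
      ring <- ring + 1L
    }
  }
  polygonal_layer(ids, area, neighbours, interior,
                  layer_index = layer_index, z = z)
}

#' Per-layer polygonal lattice statistics
#'
#' Computes, over interior cells with at least three neighbours (cells
#' with n < 3 are excluded as segmentation artefacts): the neighbour-number
#' frequency distribution and its mean (Euler's topological mean is 6 on a
#' contiguous lattice with three-way vertices), the area coefficient of
#' variation (sample sd / mean), the observed Aboav-Weaire table m(n) --
#' the mean neighbour number of the neighbours of n-sided cells, where
#' border neighbours still contribute their own n -- the Lewis table of
#' normalised class areas, and the hexagon fraction. Classes with fewer
#' than three cells are reported but flagged `low_count`.
#'
#' @param layer a [polygonal_layer()].
#' @return object of class `layer_stats`: list with `freq` (named
#'   fractions), `n_bar`, `area_cv`, `hex_fraction`, `aw_table`
#'   (data.frame n, m_n, sem, count, low_count), `lewis_table`
#'   (data.frame n, lewis_ratio, sem, count, low_count), `n_interior`.
#' @export
layer_stats <- function(layer) {
  stopifnot(inherits(layer, "polygonal_layer"))
  n_all <- vapply(layer$neighbours, length, integer(1))
  keep <- layer$interior & n_all >= 3
  if (!any(keep)) stop("no interior cells with n >= 3 in layer")
  n <- n_all[keep]
  area <- layer$area[keep]
  ids <- layer$cell_id[keep]

  freq <- table(n) / length(n)
  n_bar <- mean(n)
  mean_area <- mean(area)
  area_cv <- if (length(area) > 1) sd(area) / mean_area else 0
  hex_fraction <- as.numeric(sum(n == 6)) / length(n)

  # neighbour-of-neighbour means: m(n) = mean over n-sided interior cells
  # of (sum of neighbours' n_i) / n; border neighbours keep their n_i
  nn_mean <- vapply(ids, function(id) {
    nb <- layer$neighbours[[id]]
    mean(n_all[match(nb, layer$cell_id)])
  }, numeric(1))

  classes <- sort(unique(n))
  aw_table <- do.call(rbind, lapply(classes, function(k) {
    v <- nn_mean[n == k]
    data.frame(n = k, m_n = mean(v),
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               count = length(v), low_count = length(v) < 3)
  }))
  lewis_table <- do.call(rbind, lapply(classes, function(k) {
    v <- area[n == k] / mean_area
    data.frame(n = k, lewis_ratio = mean(v),
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               count = length(v), low_count = length(v) < 3)
  }))

  structure(list(freq = stats::setNames(as.numeric(freq), names(freq)),
                 n_bar = n_bar, area_cv = area_cv,
                 hex_fraction = hex_fraction,
                 aw_table = aw_table, lewis_table = lewis_table,
                 n_interior = length(n),
                 layer_index = layer$layer_index, z = layer$z),
            class = "layer_stats")
}

#' @export
print.layer_stats <- function(x, ...) {
  cat(sprintf(
    "<layer_stats> %d interior cells: n_bar = %.3f, area CV = %.3f, hexagons %.1f%%\n",
    x$n_interior, x$n_bar, x$area_cv, 100 * x$hex_fraction))
  invisible(x)
}

#' Internal angles of a polygon
#'
#' Interior angles (degrees) at each vertex of a simple polygon given as
#' an ordered vertex matrix; handles either orientation and non-convex
#' corners via signed turn angles. The angles of an n-gon sum to
#' (n - 2) * 180 degrees.
#'
#' @param vertices k x 2 numeric matrix of ordered vertices.
#' @return numeric vector of k interior angles in degrees.
#' @export
polygon_internal_angles <- function(vertices) {
  v <- as.matrix(vertices)
  k <- nrow(v)
  stopifnot(k >= 3, ncol(v) == 2)
  # signed area fixes orientation so interior angles come out positive
  xs <- v[, 1]; ys <- v[, 2]
  a2 <- sum(xs * ys[c(2:k, 1)] - xs[c(2:k, 1)] * ys)
  if (a2 < 0) v <- v[k:1, , drop = FALSE]
  nxt <- c(2:k, 1)
  prv <- c(k, 1:(k - 1))
  e_in <- v - v[prv, , drop = FALSE]
  e_out <- v[nxt, , drop = FALSE] - v
  turn <- atan2(e_in[, 1] * e_out[, 2] - e_in[, 2] * e_out[, 1],
                rowSums(e_in * e_out))
  (pi - turn) * 180 / pi
}

#' Per-class side-length and internal-angle tables
#'
#' For layers that carry polygon outlines: mean internal angle per
#' polygon class (to compare with the regular-polygon angle
#' (n-2)/n * 180) and mean edge length per class normalised by the global
#' mean edge length. Interior cells only.
#'
#' @param layer a [polygonal_layer()] with `polygons` set for its
#'   interior cells.
#' @return list with `side_table` (data.frame n, side_ratio, sem, count)
#'   and `angle_table` (data.frame n, mean_angle, sem, count).
#' @export
side_and_angle_tables <- function(layer) {
  stopifnot(inherits(layer, "polygonal_layer"))
  ids <- layer$cell_id[layer$interior]
  missing <- ids[!ids %in% names(layer$polygons)]
  if (length(missing) > 0)
    stop("polygon vertices missing for cell(s): ",
         paste(missing, collapse = ", "))
  per_cell <- lapply(ids, function(id) {
    v <- as.matrix(layer$polygons[[id]])
    k <- nrow(v)
    edges <- sqrt(rowSums((v[c(2:k, 1), , drop = FALSE] - v)^2))
    list(n = k, angles = polygon_internal_angles(v), edges = edges)
  })
  ns <- vapply(per_cell, `[[`, numeric(1), "n")
  global_mean_edge <- mean(unlist(lapply(per_cell, `[[`, "edges")))
  classes <- sort(unique(ns))
  tab <- function(values_per_cell) {
    do.call(rbind, lapply(classes, function(k) {
      v <- vapply(per_cell[ns == k], values_per_cell, numeric(1))
      data.frame(n = k, value = mean(v),
                 sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
                 count = length(v))
    }))
  }
  side_table <- tab(function(p) mean(p$edges) / global_mean_edge)
  names(side_table)[2] <- "side_ratio"
  angle_table <- tab(function(p) mean(p$angles))
  names(angle_table)[2] <- "mean_angle"
  list(side_table = side_table, angle_table = angle_table)
}
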