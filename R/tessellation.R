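#' Rasterised 2D power-diagram tessellation with area control
#'
#' Assigns every pixel of a rectangular (optionally toroidal) domain to the
#' seed minimising the power distance \eqn{d^2 - w}. Per-seed weights are
#' tuned by a damped fixed-point iteration so that realised cell areas
#' approximate the requested target areas. This is the tessellation engine
#' behind [generate_tissue()]: it approximates a lateral-surface-minimising
#' packing with prescribed cross-sectional areas without a full mechanical
#' model.
#'
#' @param seeds numeric matrix (n x 2) of seed coordinates in microns.
#' @param targets numeric vector of target cell areas (um^2); rescaled
#'   internally so they sum to the domain area.
#' @param width,height domain extent in microns.
#' @param nx,ny raster resolution in pixels.
#' @param periodic logical; wrap distances around both axes (toroidal
#'   domain).
#' @param weights optional starting weights (um^2), e.g. from the previous
#'   layer of a stack; defaults to zero.
#' @param tune logical; if `FALSE` the diagram is evaluated once with the
#'   given weights and no area fitting is attempted.
#' @param clean logical; reassign stray raster fragments (pixels of a
#'   cell disconnected from its main body under 4-connectivity, an
#'   artifact of rasterisation at thin boundaries) to the dominant
#'   adjacent cell, so every label is one connected region.
#' @param relax number of Lloyd (centroidal) relaxation sweeps: after
#'   each sweep the seeds move to their cells' centroids and the weights
#'   are refitted. Relaxation drives the tessellation towards the
#'   minimal-perimeter (lateral-surface-minimising) packing that
#'   epithelial layers approximate, and strongly reduces near-degenerate
#'   vertices.
#' @param eta damping factor of the weight update.
#' @param tol convergence tolerance: mean absolute area error relative to
#'   the mean target area.
#' @param maxit maximum number of fixed-point iterations.
#'
#' @return list with `labels` (ny x nx integer matrix, cells labelled
#'   1..n), `weights`, `areas` (realised areas, um^2), `pixel_size`
#'   (c(dx, dy), um), `iterations` and `resid` (final relative mean
#'   absolute area error).
#' @export
power_diagram <- function(seeds, targets = NULL, width, height,
                          nx = 256L, ny = 256L, periodic = TRUE,
                          weights = NULL, tune = !is.null(targets),
                          clean = TRUE, relax = 0L, eta = 0.7,
                          tol = 0.01, maxit = 200L) {
  seeds <- as.matrix(seeds)
  stopifnot(ncol(seeds) == 2, width > 0, height > 0, nx >= 4, ny >= 4)
  if (relax > 0) {
    for (sweep in seq_len(relax)) {
      pd <- power_diagram(seeds, targets, width, height, nx = nx, ny = ny,
                          periodic = periodic, weights = weights,
                          tune = tune, clean = FALSE, relax = 0L,
                          eta = eta, tol = tol, maxit = maxit)
      cent <- label_centroids(pd$labels, width, height, periodic,
                              nrow(seeds))
      bad <- is.na(cent[, 1]) | is.na(cent[, 2])
      cent[bad, ] <- seeds[bad, ]
      seeds <- cent
      weights <- pd$weights
    }
  }
  n <- nrow(seeds)
  if (is.null(weights)) weights <- numeric(n)
  if (is.null(targets)) targets <- rep(width * height / n, n)
  stopifnot(length(targets) == n, length(weights) == n, all(targets > 0))

  hx <- width / nx
  hy <- height / ny
  xc <- (seq_len(nx) - 0.5) * hx
  yc <- (seq_len(ny) - 0.5) * hy
  dxm <- abs(outer(xc, seeds[, 1], "-"))
  dym <- abs(outer(yc, seeds[, 2], "-"))
  if (periodic) {
    dxm <- pmin(dxm, width - dxm)
    dym <- pmin(dym, height - dym)
  }
  pixel_area <- hx * hy
  target_px <- targets / sum(targets) * (nx * ny)

  fit <- pd_fit(dxm^2, dym^2, weights, target_px, pixel_area,
                eta = if (tune) eta else 0,
                tol = if (tune) tol else Inf,
                maxit = if (tune) maxit else 1L)
  stage_eta <- eta / 3
  while (tune && fit$resid >= tol && stage_eta > eta / 30) {
    fit <- pd_fit(dxm^2, dym^2, fit$weights, target_px, pixel_area,
                  eta = stage_eta, tol = tol, maxit = maxit)
    stage_eta <- stage_eta / 3
  }
  if (tune && fit$resid >= tol) {
    stop(sprintf(
      "power-diagram weight tuning did not converge: relative mean absolute area error %.4f (tolerance %.4f)",
      fit$resid, tol))
  }
  labels <- fit$labels
  if (clean) labels <- clean_label_image(labels, periodic)
  counts <- tabulate(labels, nbins = n)
  list(labels = labels,
       weights = as.numeric(fit$weights),
       seeds = seeds,
       areas = counts * pixel_area,
       pixel_size = c(hx, hy),
       iterations = fit$iterations,
       resid = fit$resid)
}

# per-label centroids of a label image; circular means on a torus
label_centroids <- function(labels, width, height, periodic, n) {
  nr <- nrow(labels); nc <- ncol(labels)
  xc <- (col(labels) - 0.5) * width / nc
  yc <- (row(labels) - 0.5) * height / nr
  lab <- as.vector(labels)
  cent <- matrix(NA_real_, n, 2)
  for (ax in 1:2) {
    v <- as.vector(if (ax == 1) xc else yc)
    ext <- if (ax == 1) width else height
    if (periodic) {
      ang <- v / ext * 2 * pi
      cs <- tapply(cos(ang), lab, mean)
      sn <- tapply(sin(ang), lab, mean)
      val <- (atan2(sn, cs) %% (2 * pi)) / (2 * pi) * ext
    } else {
      val <- tapply(v, lab, mean)
    }
    cent[as.integer(names(val)), ax] <- val
  }
  cent
}

#' Reassign disconnected label fragments
#'
#' Rasterisation of a tessellation can strand a few pixels of a cell
#' diagonally from its main body. This keeps, per label, the largest
#' 4-connected component and reassigns the pixels of any minor fragment
#' to the label most represented among the fragment's outside
#' neighbours. Iterates until every label is a single component.
#'
#' @param labels integer label matrix.
#' @param periodic logical; toroidal connectivity.
#' @param max_passes safety limit on reassignment sweeps.
#' @return cleaned integer label matrix.
#' @export
clean_label_image <- function(labels, periodic = TRUE, max_passes = 10L) {
  m <- labels
  storage.mode(m) <- "integer"
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(mat, dr, dc) {
    ri <- seq_len(nr) + dr; ci <- seq_len(nc) + dc
    if (periodic) {
      ri <- ((ri - 1) %% nr) + 1
      ci <- ((ci - 1) %% nc) + 1
    } else {
      ri <- pmin(pmax(ri, 1), nr)
      ci <- pmin(pmax(ci, 1), nc)
    }
    mat[ri, ci, drop = FALSE]
  }
  for (pass in seq_len(max_passes)) {
    cm <- component_map(m, periodic)
    k <- max(cm)
    first_pix <- match(seq_len(k), as.vector(cm))
    comp_label <- as.vector(m)[first_pix]
    sizes <- tabulate(cm, nbins = k)
    minor <- logical(k)
    for (l in unique(comp_label)) {
      comps <- which(comp_label == l)
      if (length(comps) > 1)
        minor[comps[-which.max(sizes[comps])]] <- TRUE
    }
    if (!any(minor)) break
    nb <- list(shift(m, 1, 0), shift(m, -1, 0), shift(m, 0, 1),
               shift(m, 0, -1))
    for (comp in which(minor)) {
      pix <- which(cm == comp)
      own <- comp_label[comp]
      cand <- unlist(lapply(nb, function(x) x[pix]))
      cand <- cand[cand != own]
      if (length(cand) == 0) next
      m[pix] <- as.integer(names(which.max(table(cand))))
    }
  }
  m
}

#' Exact polygonal cells of a power diagram
#'
#' Computes the exact cell polygons of a 2D power diagram by sequential
#' half-plane clipping: cell i is the intersection of the half-planes
#' \eqn{2 (s_j - s_i) \cdot x \le |s_j|^2 - |s_i|^2 + w_i - w_j} over
#' all competitors j (using each competitor's nearest periodic image on
#' a torus). Gives exact areas (shoelace), exact adjacency (cells whose
#' bisector contributes an edge of positive length) and ordered vertex
#' lists, free of raster artifacts.
#'
#' @param seeds n x 2 seed matrix, um.
#' @param weights per-seed power weights, um^2 (e.g. fitted by
#'   [power_diagram()]).
#' @param width,height domain extent, um.
#' @param periodic logical; toroidal domain.
#' @param eps edge-length tolerance (um) below which a sliver edge is
#'   not counted as adjacency.
#' @return list with `polygons` (list of vertex matrices), `areas`,
#'   `neighbours` (list of integer vectors), `on_boundary` (logical;
#'   polygon touches the domain rectangle, always FALSE on a torus).
#' @export
power_diagram_cells <- function(seeds, weights = NULL, width, height,
                                periodic = TRUE, eps = 1e-9) {
  seeds <- as.matrix(seeds)
  n <- nrow(seeds)
  if (is.null(weights)) weights <- numeric(n)
  stopifnot(length(weights) == n)
  diam <- sqrt(width * height / n)
  cutoff <- 6 * diam

  polygons <- vector("list", n)
  areas <- numeric(n)
  nb <- vector("list", n)
  on_boundary <- logical(n)

  for (i in seq_len(n)) {
    si <- seeds[i, ]
    # start from a generous square around the seed (torus) or the
    # domain rectangle (bounded)
    if (periodic) {
      R <- cutoff
      V <- rbind(si + c(-R, -R), si + c(R, -R), si + c(R, R),
                 si + c(-R, R))
      S <- rep(0L, 4)
    } else {
      V <- rbind(c(0, 0), c(width, 0), c(width, height), c(0, height))
      S <- rep(0L, 4)
    }
    dx <- seeds[, 1] - si[1]
    dy <- seeds[, 2] - si[2]
    if (periodic) {
      dx <- dx - width * round(dx / width)
      dy <- dy - height * round(dy / height)
    }
    d2 <- dx^2 + dy^2
    cand <- order(d2)
    cand <- cand[cand != i & d2[cand] < cutoff^2]
    for (j in cand) {
      sj <- si + c(dx[j], dy[j])
      a <- 2 * (sj - si)
      b <- sum(sj^2) - sum(si^2) + weights[i] - weights[j]
      clipped <- clip_halfplane(V, S, a, b, j)
      V <- clipped$V; S <- clipped$S
      if (nrow(V) < 3) break
    }
    if (nrow(V) < 3) {
      polygons[[i]] <- matrix(numeric(0), 0, 2)
      next
    }
    polygons[[i]] <- V
    xs <- V[, 1]; ys <- V[, 2]
    k <- nrow(V)
    areas[i] <- abs(sum(xs * ys[c(2:k, 1)] - xs[c(2:k, 1)] * ys)) / 2
    el <- sqrt(rowSums((V[c(2:k, 1), , drop = FALSE] - V)^2))
    nb[[i]] <- unique(S[el > eps & S > 0])
    on_boundary[i] <- any(S[el > eps] == 0L)
  }
  # symmetrise: keep a pair only if both cells saw the shared edge
  for (i in seq_len(n))
    nb[[i]] <- nb[[i]][vapply(nb[[i]], function(j) i %in% nb[[j]],
                              logical(1))]
  list(polygons = polygons, areas = areas, neighbours = nb,
       on_boundary = on_boundary)
}

# Sutherland-Hodgman clip of polygon V (edge k runs V[k] -> V[k+1],
# with source id S[k]) against half-plane a . x <= b; new edges on the
# clip line carry source `src`
clip_halfplane <- function(V, S, a, b, src) {
  k <- nrow(V)
  if (k == 0) return(list(V = V, S = S))
  f <- as.numeric(V %*% a) - b
  inside <- f <= 0
  if (all(inside)) return(list(V = V, S = S))
  if (!any(inside)) return(list(V = V[0, , drop = FALSE], S = integer(0)))
  outV <- matrix(NA_real_, 2 * k, 2)
  outS <- integer(2 * k)
  m <- 0L
  for (e in seq_len(k)) {
    e2 <- if (e == k) 1L else e + 1L
    p1 <- V[e, ]; p2 <- V[e2, ]
    in1 <- inside[e]; in2 <- inside[e2]
    if (in1) {
      m <- m + 1L; outV[m, ] <- p1; outS[m] <- S[e]
    }
    if (in1 != in2) {
      t <- f[e] / (f[e] - f[e2])
      m <- m + 1L
      outV[m, ] <- p1 + t * (p2 - p1)
      # leaving the half-plane: the new edge runs along the clip line
      outS[m] <- if (in1) src else S[e]
    }
  }
  list(V = outV[seq_len(m), , drop = FALSE], S = outS[seq_len(m)])
}

#' Seed points by best-candidate (blue-noise) sampling
#'
#' Draws `n` points in the rectangle, each chosen as the best of `k`
#' uniform candidates by maximal minimum distance to the points placed so
#' far. Gives evenly spread seeds without the clumping of plain uniform
#' sampling, mimicking the packed arrangement of epithelial cell columns.
#'
#' @param n number of points.
#' @param width,height domain extent.
#' @param periodic logical; use toroidal distances.
#' @param k candidates per point.
#' @return n x 2 numeric matrix.
#' @export
best_candidate_seeds <- function(n, width, height, periodic = TRUE, k = 12L) {
  stopifnot(n >= 1)
  pts <- matrix(NA_real_, n, 2)
  pts[1, ] <- c(runif(1, 0, width), runif(1, 0, height))
  if (n == 1) return(pts)
  for (i in 2:n) {
    cand <- cbind(runif(k, 0, width), runif(k, 0, height))
    placed <- pts[seq_len(i - 1), , drop = FALSE]
    dmin <- vapply(seq_len(k), function(j) {
      dx <- abs(placed[, 1] - cand[j, 1])
      dy <- abs(placed[, 2] - cand[j, 2])
      if (periodic) {
        dx <- pmin(dx, width - dx)
        dy <- pmin(dy, height - dy)
      }
      min(dx^2 + dy^2)
    }, numeric(1))
    pts[i, ] <- cand[which.max(dmin), ]
  }
  pts
}

#' Triangular (offset-row) seed lattice
#'
#' Seed points for a regular hexagonal tessellation on a periodic domain:
#' `n_rows` rows of `n_cols` seeds, alternate rows offset by half a column
#' spacing. `n_rows` must be even for toroidal continuity.
#'
#' @param n_cols,n_rows lattice dimensions.
#' @param width,height domain extent.
#' @return (n_cols*n_rows) x 2 matrix of seed coordinates.
#' @export
hex_lattice_seeds <- function(n_cols, n_rows, width, height) {
  if (n_rows %% 2 != 0)
    stop("n_rows must be even for a periodic triangular lattice")
  dx <- width / n_cols
  dy <- height / n_rows
  out <- matrix(NA_real_, n_cols * n_rows, 2)
  i <- 1L
  for (r in seq_len(n_rows)) {
    off <- if (r %% 2 == 0) dx / 2 else 0
    for (c in seq_len(n_cols)) {
      out[i, ] <- c((c - 0.5) * dx + off, (r - 0.5) * dy)
      i <- i + 1L
    }
  }
  out
}
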