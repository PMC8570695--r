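#' Nuclear morphometrics from a 3D label grid
#'
#' Per-nucleus volume, principal semi-axes, ellipticity and relative
#' apical-basal centre position from an integer-labelled voxel grid.
#' Principal semi-axes come from the voxel second-moment (inertia)
#' tensor: for a solid ellipsoid the covariance eigenvalues are
#' \eqn{a_i^2 / 5}, so the semi-axes are \eqn{\sqrt{5 \lambda_i}}.
#' Ellipticity is defined as 1 - (shortest / longest principal
#' semi-axis), so a sphere scores 0 and elongated nuclei score higher;
#' this definition is isolated here so it can be swapped if a different
#' convention is needed.
#'
#' @param nucleus_labels 3D integer array `[x, y, z]`; z runs apical to
#'   basal; 0 = background, nuclei labelled by cell id.
#' @param voxel_size length-3 voxel edge lengths, um.
#' @param tissue_height tissue thickness, um; defaults to the grid
#'   extent along z.
#' @return data.frame: cell_id, volume_um3, centre_z (relative, 0 =
#'   apical), semi_a, semi_b, semi_c (descending, um), ellipticity.
#' @export
nuclear_stats <- function(nucleus_labels, voxel_size,
                          tissue_height = NULL) {
  stopifnot(length(dim(nucleus_labels)) == 3, length(voxel_size) == 3,
            all(voxel_size > 0))
  arr <- nucleus_labels
  storage.mode(arr) <- "integer"
  if (is.null(tissue_height))
    tissue_height <- dim(arr)[3] * voxel_size[3]

  comp <- label_component_counts3d(arr)
  labs <- sort(unique(as.vector(arr)))
  labs <- labs[labs > 0]
  if (length(labs) == 0) stop("no nuclei in label grid")
  bad <- labs[comp[labs + 1L] > 1L]
  if (length(bad) > 0)
    stop("nucleus label(s) split across disconnected components: ",
         paste(bad, collapse = ", "))

  idx <- which(arr > 0)
  lab <- arr[idx]
  d <- dim(arr)
  ix <- ((idx - 1) %% d[1]) + 1
  iy <- (((idx - 1) %/% d[1]) %% d[2]) + 1
  iz <- ((idx - 1) %/% (d[1] * d[2])) + 1
  coords <- cbind((ix - 0.5) * voxel_size[1],
                  (iy - 0.5) * voxel_size[2],
                  (iz - 0.5) * voxel_size[3])
  vvol <- prod(voxel_size)

  do.call(rbind, lapply(labs, function(l) {
    sel <- lab == l
    pts <- coords[sel, , drop = FALSE]
    vol <- nrow(pts) * vvol
    ctr <- colMeans(pts)
    cv <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
    # voxel self-extent keeps single-voxel degenerate cases finite
    cv <- cv + diag(voxel_size^2 / 12)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    semi <- sqrt(5 * pmax(ev, 0))
    data.frame(cell_id = as.character(l), volume_um3 = vol,
               centre_z = ctr[3] / tissue_height,
               semi_a = semi[1], semi_b = semi[2], semi_c = semi[3],
               ellipticity = 1 - semi[3] / semi[1])
  }))
}

#' Nuclear morphometry table from generator output
#'
#' Adapter building the same table as [nuclear_stats()] from the
#' analytic nucleus models of a [generate_tissue()] result.
#'
#' @param tissue a `synthetic_tissue`.
#' @return data.frame as in [nuclear_stats()].
#' @export
nuclear_stats_from_tissue <- function(tissue) {
  nuc <- tissue$nuclei
  data.frame(cell_id = nuc$cell_id, volume_um3 = nuc$volume_um3,
             centre_z = nuc$centre_z,
             semi_a = pmax(nuc$semi_z, nuc$semi_xy),
             semi_b = nuc$semi_xy,
             semi_c = pmin(nuc$semi_z, nuc$semi_xy),
             ellipticity = 1 - pmin(nuc$semi_z, nuc$semi_xy) /
               pmax(nuc$semi_z, nuc$semi_xy))
}

#' Cell-nucleus volume and cross-sectional area correlations
#'
#' Pearson correlation between cell and nuclear volumes across cells,
#' and between cell and nuclear cross-sectional areas across all
#' (cell, layer) pairs where the nucleus intersects the section plane.
#' Cell volumes are integrated from the per-section areas.
#'
#' @param columns list of [cell_column()] carrying `nuclear_area`.
#' @param nuclei data.frame with cell_id and volume_um3 (e.g. from
#'   [nuclear_stats()]).
#' @return list with `r_volume`, `r_area`, `n_cells`, `n_area_pairs`.
#' @export
cell_nucleus_correlation <- function(columns, nuclei) {
  ids <- vapply(columns, function(cl) cl$cell_id, character(1))
  m <- match(ids, as.character(nuclei$cell_id))
  keep <- !is.na(m)
  if (sum(keep) < 3) stop("need at least 3 matched cell/nucleus pairs")
  cell_vol <- vapply(columns[keep], function(cl) {
    h <- if (is.na(cl$height)) 1 else cl$height
    # midpoint-rule slab widths between consecutive section positions
    w <- diff(c(0, (cl$z[-1] + cl$z[-length(cl$z)]) / 2, 1))
    sum(cl$area * w) * h
  }, numeric(1))
  nuc_vol <- nuclei$volume_um3[m[keep]]
  r_volume <- cor(cell_vol, nuc_vol)

  pairs <- do.call(rbind, lapply(columns[keep], function(cl) {
    if (is.null(cl$nuclear_area)) return(NULL)
    present <- !is.na(cl$nuclear_area) & cl$nuclear_area > 0
    if (!any(present)) return(NULL)
    cbind(cl$area[present], cl$nuclear_area[present])
  }))
  if (is.null(pairs) || nrow(pairs) < 3)
    stop("fewer than 3 (cell, layer) pairs with a nucleus present")
  list(r_volume = r_volume, r_area = cor(pairs[, 1], pairs[, 2]),
       n_cells = sum(keep), n_area_pairs = nrow(pairs))
}

#' Equivalent sphere and cylinder diameters
#'
#' Diameter a nucleus would have as a perfect sphere of its measured
#' volume, and the diameter a cell would have as a perfect cylinder of
#' its measured volume and height. When the spherical nuclear diameter
#' exceeds the cylindrical cell diameter, nuclei must deform to fit.
#'
#' @param cell_volume cell volume, um^3.
#' @param cell_height cell height, um.
#' @param nuclear_volume nuclear volume, um^3.
#' @return list with `d_cell_cylinder` and `d_nucleus_sphere` (um).
#' @export
equivalent_diameters <- function(cell_volume, cell_height, nuclear_volume) {
  if (any(c(cell_volume, cell_height, nuclear_volume) <= 0))
    stop("volumes and height must be positive")
  list(d_cell_cylinder = 2 * sqrt(cell_volume / (pi * cell_height)),
       d_nucleus_sphere = (6 * nuclear_volume / pi)^(1 / 3))
}

#' One-sided Welch test: apical nuclei are less elliptic
#'
#' Two-sample Welch t-test with Satterthwaite degrees of freedom,
#' one-sided for the hypothesis that nuclei centred in the apical
#' quarter of the tissue (centre_z in `[0, 0.25]`, boundary included)
#' have lower ellipticity than nuclei in the middle half
#' (centre_z in `(0.25, 0.75]`).
#'
#' @param nuclei data.frame with centre_z and ellipticity.
#' @return list with `t`, `dof`, `p_one_sided`, `n_apical`, `n_middle`.
#' @export
ellipticity_position_test <- function(nuclei) {
  apical <- nuclei$ellipticity[nuclei$centre_z <= 0.25]
  middle <- nuclei$ellipticity[nuclei$centre_z > 0.25 &
                                 nuclei$centre_z <= 0.75]
  if (length(apical) < 3 || length(middle) < 3)
    stop("need at least 3 nuclei in each position group")
  m1 <- mean(apical); m2 <- mean(middle)
  v1 <- var(apical) / length(apical)
  v2 <- var(middle) / length(middle)
  se <- sqrt(v1 + v2)
  if (se == 0) {
    t <- 0
    dof <- length(apical) + length(middle) - 2
  } else {
    t <- (m1 - m2) / se
    dof <- (v1 + v2)^2 /
      (v1^2 / (length(apical) - 1) + v2^2 / (length(middle) - 1))
  }
  list(t = t, dof = dof, p_one_sided = pt(t, dof),
       n_apical = length(apical), n_middle = length(middle))
}
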