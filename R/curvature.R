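#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to 2D points by the stable direct algebraic
#' least-squares method (conic fit with the ellipse-specific constraint
#' \eqn{4AC - B^2 = 1}), then extracts geometric parameters. The reported
#' residual is the RMS of the Sampson (gradient-normalised algebraic)
#' distance, in the units of the input.
#'
#' @param points n x 2 numeric matrix, n >= 6, not collinear.
#' @return object of class `ellipse_fit`: list with `centre`, `a` (major
#'   semi-axis), `b` (minor semi-axis), `orientation` (radians, of the
#'   major axis), `rms_residual`.
#' @export
fit_ellipse <- function(points) {
  P <- as.matrix(points)
  stopifnot(ncol(P) == 2)
  if (nrow(P) < 6) stop("need at least 6 points")
  x <- P[, 1]; y <- P[, 2]
  mx <- mean(x); my <- mean(y)
  sc <- max(sd(x), sd(y))
  if (!is.finite(sc) || sc == 0) stop("degenerate point set")
  xs <- (x - mx) / sc; ys <- (y - my) / sc

  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  qS3 <- tryCatch(solve(S3, t(S2)), error = function(e)
    stop("degenerate (collinear?) point configuration"))
  M <- S1 - S2 %*% qS3
  # constraint matrix inverse applied: C^-1 M with C = [[0,0,2],[0,-1,0],[2,0,0]]
  Mc <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(Mc)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 1e-12)
  if (length(ok) == 0) stop("best-fitting conic is not an ellipse")
  a1 <- evec[, ok[1]]
  a2 <- -as.numeric(qS3 %*% a1)
  coef <- c(a1, a2)  # A x^2 + B xy + C y^2 + D x + E y + F = 0 (scaled frame)

  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("best-fitting conic is not an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + (B^2 - 4 * A * C) * F)
  s <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(num * (A + C + s)) / den * sc
  ax2 <- -sqrt(num * (A + C - s)) / den * sc
  if (!all(is.finite(c(ax1, ax2))) || ax1 <= 0 || ax2 <= 0)
    stop("best-fitting conic is not an ellipse")
  theta <- 0.5 * atan2(-B, C - A)
  if (ax1 < ax2) {
    tmp <- ax1; ax1 <- ax2; ax2 <- tmp
    theta <- theta + pi / 2
  }
  theta <- ((theta + pi / 2) %% pi) - pi / 2
  centre <- c(cx * sc + mx, cy * sc + my)

  # Sampson residual in original units
  g <- cbind(2 * A * xs + B * ys + D, B * xs + 2 * C * ys + E)
  alg <- A * xs^2 + B * xs * ys + C * ys^2 + D * xs + E * ys + F
  res <- abs(alg) / sqrt(rowSums(g^2))
  structure(list(centre = centre, a = ax1, b = ax2, orientation = theta,
                 rms_residual = sqrt(mean(res^2)) * sc),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit> centre (%.3f, %.3f), a = %.4f, b = %.4f, theta = %.3f rad, rms %.2e\n",
    x$centre[1], x$centre[2], x$a, x$b, x$orientation, x$rms_residual))
  invisible(x)
}

#' Tube geometry from apical and basal ellipse semi-axes
#'
#' Semi-axes of the apical and basal boundary ellipses of a (nearly
#' elliptic, often collapsed) epithelial tube, typically averaged over
#' many sections perpendicular to the tube axis. Defines the local
#' radius-of-curvature model [local_radius()] near the minor vertex of
#' the ellipse, where the analysed cells sit.
#'
#' @param a_apical,b_apical,a_basal,b_basal semi-axes, um; a >= b > 0 for
#'   each surface.
#' @return object of class `tube_geometry`.
#' @export
tube_geometry <- function(a_apical, b_apical, a_basal, b_basal) {
  v <- c(a_apical, b_apical, a_basal, b_basal)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("semi-axes must be positive")
  if (a_apical < b_apical || a_basal < b_basal)
    stop("major semi-axis a must be >= minor semi-axis b")
  structure(list(a_apical = a_apical, b_apical = b_apical,
                 a_basal = a_basal, b_basal = b_basal),
            class = "tube_geometry")
}

#' Tube geometry from per-section boundary points
#'
#' Fits ellipses to apical and basal boundary point sets per section and
#' averages the semi-axes over sections.
#'
#' @param boundaries data.frame with columns surface ("apical"/"basal"),
#'   section_index, x, y.
#' @return [tube_geometry()].
#' @export
fit_tube_geometry <- function(boundaries) {
  stopifnot(all(c("surface", "section_index", "x", "y") %in%
                  names(boundaries)))
  mean_axes <- function(surface) {
    sub <- boundaries[boundaries$surface == surface, ]
    if (nrow(sub) == 0) stop("no ", surface, " boundary points")
    fits <- lapply(split(sub, sub$section_index), function(s)
      fit_ellipse(cbind(s$x, s$y)))
    c(a = mean(vapply(fits, `[[`, numeric(1), "a")),
      b = mean(vapply(fits, `[[`, numeric(1), "b")))
  }
  ap <- mean_axes("apical")
  ba <- mean_axes("basal")
  tube_geometry(ap[["a"]], ap[["b"]], ba[["a"]], ba[["b"]])
}

#' Local radius of curvature along the apical-basal axis
#'
#' At the minor vertex of an ellipse with semi-axes a and b the curvature
#' is \eqn{b / a^2}, i.e. the radius is \eqn{a^2 / b}. Interpolating both
#' semi-axes linearly between the apical (x = 0) and basal (x = 1)
#' surfaces gives the local radius
#' \deqn{R(x) = (a_{ap} + x (a_{ba} - a_{ap}))^2 /
#'              (b_{ap} + x (b_{ba} - b_{ap})).}
#'
#' @param x relative apical-basal position(s) in `[0, 1]` (0 = apical).
#' @param geom a [tube_geometry()].
#' @return local radius (um).
#' @export
local_radius <- function(x, geom) {
  stopifnot(inherits(geom, "tube_geometry"))
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  a <- geom$a_apical + x * (geom$a_basal - geom$a_apical)
  b <- geom$b_apical + x * (geom$b_basal - geom$b_apical)
  a^2 / b
}

#' Curvature fold change between consecutive T1 transitions
#'
#' For every pair of consecutive lateral T1 transitions of each cell,
#' the ratio \eqn{R_2 / R_1} of the local radii at the two transition
#' positions, with \eqn{R_2} taken at the more basal transition (so fold
#' changes exceed 1 when the basal side is flatter). `n_between` is the
#' cell's neighbour count on the segment between the two transitions.
#' Only interior segments (between two transitions) exist for this
#' quantity, so columns with fewer than two events contribute nothing.
#'
#' @param columns list of [cell_column()].
#' @param geom a [tube_geometry()].
#' @return data.frame: cell_id, x1, x2, R1, R2, fold (R2/R1), n_between.
#' @export
event_fold_changes <- function(columns, geom) {
  stopifnot(inherits(geom, "tube_geometry"))
  rows <- lapply(columns, function(cl) {
    ev <- detect_t1(cl)
    if (nrow(ev) < 2) return(NULL)
    out <- list()
    for (i in seq_len(nrow(ev) - 1)) {
      x1 <- ev$rel_position[i]
      x2 <- ev$rel_position[i + 1]
      # neighbour count on the sections strictly between the two interfaces
      sect <- which(cl$z > x1 & cl$z < x2)
      nb <- if (length(sect) > 0)
        round(mean(lengths(cl$neighbours)[sect])) else
          length(cl$neighbours[[ev$interface_index[i] + 1]])
      out[[i]] <- data.frame(cell_id = cl$cell_id, x1 = x1, x2 = x2,
                             R1 = local_radius(x1, geom),
                             R2 = local_radius(x2, geom),
                             fold = local_radius(x2, geom) /
                               local_radius(x1, geom),
                             n_between = nb)
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = character(0), x1 = numeric(0),
                      x2 = numeric(0), R1 = numeric(0), R2 = numeric(0),
                      fold = numeric(0), n_between = integer(0))
  out
}

#' Summary of curvature fold changes by neighbour number
#'
#' @param folds data.frame from [event_fold_changes()].
#' @return data.frame per n: count, median, q25, q75, mean, ci_low,
#'   ci_high (95% normal approximation).
#' @export
summarise_fold_changes <- function(folds) {
  do.call(rbind, lapply(split(folds, folds$n_between), function(s) {
    v <- s$fold
    half <- if (length(v) > 1) qnorm(0.975) * sd(v) / sqrt(length(v)) else 0
    data.frame(n = s$n_between[1], count = length(v),
               median = median(v),
               q25 = unname(quantile(v, 0.25)),
               q75 = unname(quantile(v, 0.75)),
               mean = mean(v),
               ci_low = mean(v) - half, ci_high = mean(v) + half)
  }))
}

#' Curvature fold change required for one neighbour gain
#'
#' Under the default model the neighbour number of a cell scales with the
#' local circumference, so gaining one neighbour requires a curvature
#' fold change of (n + 1)/n: cells with few neighbours would need a much
#' larger curvature change per exchange than cells with many. This is an
#' explicit modelling assumption; an alternative closed form can be
#' supplied through `model`.
#'
#' @param n integer neighbour number(s), n >= 3.
#' @param model function(n) returning the predicted fold change;
#'   defaults to the circumference-proportional model.
#' @return predicted fold change(s).
#' @export
predicted_fold <- function(n, model = NULL) {
  check_n(n)
  if (is.null(model)) (n + 1) / n else model(n)
}
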