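#' Lewis' law: linear normalised-area relation
#'
#' The mean normalised cross-sectional area of cells with n neighbours
#' under the linear Lewis relation, \eqn{A_n / \bar A = (n - 2) / 4}.
#'
#' @param n integer neighbour number(s), n >= 3.
#' @return numeric normalised area(s).
#' @export
lewis_linear <- function(n) {
  check_n(n)
  (n - 2) / 4
}

#' Quadratic normalised-area relation
#'
#' The alternative quadratic area relation expected at higher area
#' variability, \eqn{A_n / \bar A = (n/6) \tan(\pi/6) / \tan(\pi/n)},
#' under which polygon side lengths equalise across classes. Approaches
#' \eqn{(n/6)^2} scaling for large n.
#'
#' @inheritParams lewis_linear
#' @return numeric normalised area(s).
#' @export
lewis_quadratic <- function(n) {
  check_n(n)
  (n / 6) * tan(pi / 6) / tan(pi / n)
}

#' Aboav-Weaire law
#'
#' Predicted mean neighbour number of the neighbours of an n-sided cell:
#' \eqn{m(n) = 5 + 8/n}.
#'
#' @inheritParams lewis_linear
#' @return numeric m(n).
#' @export
aw_prediction <- function(n) {
  check_n(n)
  5 + 8 / n
}

#' Internal angle of a regular polygon
#'
#' \eqn{\theta_n = (n - 2)/n \cdot 180} degrees.
#'
#' @inheritParams lewis_linear
#' @return numeric angle(s) in degrees.
#' @export
regular_angle <- function(n) {
  check_n(n)
  (n - 2) / n * 180
}

check_n <- function(n) {
  if (any(n %% 1 != 0) || any(n < 3))
    stop("n must be integer(s) >= 3")
  invisible(n)
}

#' Predicted polygon-class distribution at a given area variability
#'
#' Predicts the fractions of polygon classes (and hence the hexagon
#' fraction) for a layer whose normalised cell areas have unit mean and
#' coefficient of variation `cv`, under either area law. Each cell adopts
#' the class whose law-predicted normalised area bin contains its area;
#' bin edges lie at arithmetic midpoints between consecutive class areas
#' (classes 3..16). A self-consistency loop rescales the bin edges so the
#' implied mean class area matches the unit population mean. The area
#' distribution family is a truncated normal by default (renormalised to
#' unit mean after truncation at zero); a gamma alternative is available
#' since the variability family of real layers is an empirical choice.
#'
#' @param cv area coefficient of variation, >= 0.
#' @param law `"lewis_linear"` or `"quadratic"`.
#' @param family `"tnorm"` (truncated normal) or `"gamma"`.
#' @param n_range integer range of supported polygon classes.
#' @param tol self-consistency tolerance on the mean class area.
#' @param maxit maximum self-consistency iterations.
#' @return object of class `theory_table`: list with `law`, `cv`,
#'   `class_areas` (named by n), `class_fractions` (named by n, sums to
#'   1), `hex_fraction`, `scale` (final bin-edge scale factor).
#' @export
predict_class_distribution <- function(cv, law = c("lewis_linear", "quadratic"),
                                       family = c("tnorm", "gamma"),
                                       n_range = 3:16, tol = 1e-6,
                                       maxit = 50L) {
  law <- match.arg(law)
  family <- match.arg(family)
  stopifnot(cv >= 0)
  area_fun <- if (law == "lewis_linear") lewis_linear else lewis_quadratic
  class_areas <- stats::setNames(area_fun(n_range), n_range)

  # bin edges at arithmetic midpoints; outermost bins extended symmetric
  mids <- (class_areas[-1] + class_areas[-length(class_areas)]) / 2
  lo <- max(0, class_areas[1] - (mids[1] - class_areas[1]))
  hi <- class_areas[length(class_areas)] +
    (class_areas[length(class_areas)] - mids[length(mids)])
  edges <- c(lo, mids, hi)

  # P(A <= q) for the unit-mean area variable
  cdf <- area_cdf(cv, family)

  s <- 1
  fr <- NULL
  for (it in seq_len(maxit)) {
    p <- diff(vapply(edges * s, cdf, numeric(1)))
    outside <- 1 - sum(p)
    if (outside > 0.2)
      stop(sprintf(
        "cv = %.3f puts %.1f%% of the area mass outside classes %d..%d",
        cv, 100 * outside, min(n_range), max(n_range)))
    fr <- p / sum(p)
    mean_class_area <- sum(fr * class_areas) * s
    if (abs(mean_class_area - 1) < tol) break
    s <- s / mean_class_area
  }
  structure(list(law = law, cv = cv, family = family,
                 class_areas = class_areas,
                 class_fractions = stats::setNames(fr, n_range),
                 hex_fraction = unname(fr[n_range == 6]),
                 scale = s),
            class = "theory_table")
}

# CDF of the normalised area distribution: unit mean, sd = cv before the
# unit-mean renormalisation that follows truncation at zero
area_cdf <- function(cv, family) {
  if (cv == 0) return(function(q) as.numeric(q >= 1))
  if (family == "gamma") {
    shape <- 1 / cv^2
    return(function(q) pgamma(q, shape = shape, rate = shape))
  }
  # normal(1, cv) truncated to (0, Inf), then rescaled back to unit mean
  z0 <- -1 / cv
  denom <- 1 - pnorm(z0)
  trunc_mean <- 1 + cv * dnorm(z0) / denom
  function(q) {
    qq <- q * trunc_mean
    ifelse(qq <= 0, 0, (pnorm((qq - 1) / cv) - pnorm(z0)) / denom)
  }
}

#' @export
print.theory_table <- function(x, ...) {
  cat(sprintf("<theory_table> %s law, CV = %.3f: hexagon fraction %.3f\n",
              x$law, x$cv, x$hex_fraction))
  invisible(x)
}

#' Theory curves over a CV grid
#'
#' Tidy table of predicted class fractions over a grid of area CVs for
#' one or both laws, suitable for overlaying on observed hexagon-fraction
#' data.
#'
#' @param cv_grid numeric vector of CV values.
#' @param laws character vector of laws to evaluate.
#' @inheritParams predict_class_distribution
#' @return data.frame with columns law, cv, n, fraction.
#' @export
theory_curves <- function(cv_grid = seq(0, 1, length.out = 50),
                          laws = c("lewis_linear", "quadratic"),
                          family = "tnorm") {
  out <- list()
  for (law in laws) {
    for (cv in cv_grid) {
      tt <- predict_class_distribution(cv, law = law, family = family)
      out[[length(out) + 1L]] <- data.frame(
        law = law, cv = cv, n = as.integer(names(tt$class_fractions)),
        fraction = as.numeric(tt$class_fractions))
    }
  }
  do.call(rbind, out)
}
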