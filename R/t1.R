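#' Cell column: one cell's stack of cross-sections
#'
#' Ordered apical-to-basal record of a single cell: per-section area,
#' neighbour set and optional nuclear cross-sectional area.
#'
#' @param cell_id identifier.
#' @param layer_index integer section indices, ascending (0 = apical).
#' @param z relative apical-basal positions in `[0, 1]`, strictly
#'   increasing.
#' @param area cross-sectional areas, um^2 (> 0).
#' @param neighbours list of neighbour-id vectors, one per section.
#'   Identifiers of unsegmented surrounding cells may appear as opaque
#'   ids; exchanges with them are still detected.
#' @param nuclear_area optional nuclear cross-sectional areas, um^2
#'   (0 or NA where the nucleus is absent).
#' @param height cell height, um (apical to basal surface).
#' @return object of class `cell_column`.
#' @export
cell_column <- function(cell_id, layer_index, z, area, neighbours,
                        nuclear_area = NULL, height = NA_real_) {
  k <- length(layer_index)
  stopifnot(k == length(z), k == length(area), k == length(neighbours),
            all(area > 0))
  if (is.unsorted(layer_index, strictly = TRUE) ||
      is.unsorted(z, strictly = TRUE))
    stop("column entries must be strictly ordered apical to basal")
  if (!is.null(nuclear_area)) stopifnot(k == length(nuclear_area))
  structure(list(cell_id = as.character(cell_id),
                 layer_index = as.integer(layer_index),
                 z = as.numeric(z), area = as.numeric(area),
                 neighbours = lapply(neighbours, as.character),
                 nuclear_area = nuclear_area,
                 height = height),
            class = "cell_column")
}

#' @export
print.cell_column <- function(x, ...) {
  cat(sprintf("<cell_column> %s: %d sections, mean n = %.2f\n", x$cell_id,
              length(x$z), mean(lengths(x$neighbours))))
  invisible(x)
}

#' Detect lateral T1 transitions along a cell column
#'
#' A lateral T1 transition (T1L) is any change in a cell's neighbour-id
#' set between adjacent cross-sections along the apical-basal axis. This
#' includes scutoid-type exchanges that conserve the neighbour count
#' (`delta_n = 0`) while swapping partners; count-based analyses can
#' filter on `delta_n` downstream. The event position is the midpoint of
#' the two bounding sections' relative z, since the true exchange point
#' is unresolved between sections.
#'
#' @param column a [cell_column()] with at least two entries.
#' @return data.frame with one row per event: cell_id, interface_index
#'   (between entries i and i+1, 1-based i), rel_position, delta_n,
#'   gained, lost (semicolon-joined ids), delta_area and
#'   delta_nuclear_area (um^2; NA when nuclear areas are absent). Events
#'   are ordered apically to basally.
#' @export
detect_t1 <- function(column) {
  stopifnot(inherits(column, "cell_column"))
  k <- length(column$z)
  if (k < 2) stop("column needs at least two entries")
  rows <- list()
  for (i in seq_len(k - 1)) {
    a <- column$neighbours[[i]]
    b <- column$neighbours[[i + 1]]
    gained <- setdiff(b, a)
    lost <- setdiff(a, b)
    if (length(gained) == 0 && length(lost) == 0) next
    dn_nuc <- if (is.null(column$nuclear_area)) NA_real_ else
      column$nuclear_area[i + 1] - column$nuclear_area[i]
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = column$cell_id, interface_index = i,
      rel_position = (column$z[i] + column$z[i + 1]) / 2,
      delta_n = length(b) - length(a),
      gained = paste(gained, collapse = ";"),
      lost = paste(lost, collapse = ";"),
      delta_area = column$area[i + 1] - column$area[i],
      delta_nuclear_area = dn_nuc,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_t1_events())
  do.call(rbind, rows)
}

empty_t1_events <- function() {
  data.frame(cell_id = character(0), interface_index = integer(0),
             rel_position = numeric(0), delta_n = integer(0),
             gained = character(0), lost = character(0),
             delta_area = numeric(0), delta_nuclear_area = numeric(0),
             stringsAsFactors = FALSE)
}

#' T1 events for a list of columns
#'
#' @param columns list of [cell_column()].
#' @return combined event data.frame (see [detect_t1()]).
#' @export
detect_t1_all <- function(columns) {
  do.call(rbind, c(list(empty_t1_events()), lapply(columns, detect_t1)))
}

#' Poisson statistics of lateral T1 transitions
#'
#' Per-cell transition counts, their mean and variance, the dispersion
#' index (variance/mean; unity for a Poisson law), the mean relative
#' apical-basal event position with a normal-approximation 95% CI,
#' inter-transition distances in microns, and a chi-squared
#' goodness-of-fit test against a Poisson law (when enough cells are
#' available).
#'
#' Inter-transition distances are the z-gaps between consecutive events
#' of a cell multiplied by the cell height. With `interior_only = TRUE`
#' only interior segments between two transitions enter; the end segments
#' (apical surface to first event, last event to basal surface) are
#' dropped to reduce boundary effects. Consecutive-event gaps are interior
#' by construction, so `interior_only = FALSE` additionally includes the
#' two end segments of each cell.
#'
#' @param columns list of [cell_column()].
#' @param interior_only logical (see Details).
#' @return object of class `transition_stats`: list with
#'   `counts_per_cell` (named integer), `mean`, `variance`,
#'   `dispersion_index`, `mean_rel_position`, `rel_position_ci`
#'   (length-2), `inter_transition_distances` (um), `chi2`, `dof`,
#'   `p_value` (NA when the test is not applicable), `n_cells`,
#'   `n_events`.
#' @export
transition_stats <- function(columns, interior_only = TRUE) {
  if (length(columns) == 0) stop("no columns supplied")
  events <- lapply(columns, detect_t1)
  counts <- vapply(events, nrow, integer(1))
  names(counts) <- vapply(columns, function(cl) cl$cell_id, character(1))
  mu <- mean(counts)
  s2 <- if (length(counts) > 1) var(counts) else 0
  disp <- if (mu > 0) s2 / mu else NA_real_

  pos <- unlist(lapply(events, function(e) e$rel_position))
  if (length(pos) > 0) {
    mp <- mean(pos)
    half <- if (length(pos) > 1)
      qnorm(0.975) * sd(pos) / sqrt(length(pos)) else 0
    ci <- c(mp - half, mp + half)
  } else {
    mp <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }

  dists <- unlist(lapply(seq_along(columns), function(i) {
    e <- events[[i]]
    h <- columns[[i]]$height
    if (is.na(h)) return(numeric(0))
    zs <- e$rel_position
    segs <- numeric(0)
    if (nrow(e) >= 2) segs <- diff(zs) * h
    if (!interior_only && nrow(e) >= 1)
      segs <- c(zs[1] * h, segs, (1 - zs[nrow(e)]) * h)
    segs
  }))

  gof <- tryCatch(poisson_gof(counts),
                  error = function(e) list(chi2 = NA_real_, dof = NA_integer_,
                                           p_value = NA_real_))
  structure(list(counts_per_cell = counts, mean = mu, variance = s2,
                 dispersion_index = disp, mean_rel_position = mp,
                 rel_position_ci = ci,
                 inter_transition_distances = dists,
                 chi2 = gof$chi2, dof = gof$dof, p_value = gof$p_value,
                 n_cells = length(counts), n_events = sum(counts)),
            class = "transition_stats")
}

#' @export
print.transition_stats <- function(x, ...) {
  cat(sprintf(
    "<transition_stats> %d cells, %d events: mean %.2f, dispersion %.2f, mean position %.3f\n",
    x$n_cells, x$n_events, x$mean, x$dispersion_index, x$mean_rel_position))
  invisible(x)
}

#' Chi-squared goodness of fit against a Poisson law
#'
#' Pearson chi-squared test of per-cell transition counts against a
#' Poisson distribution with the sample mean as rate. Tail bins are
#' merged from both ends until every expected count is at least 5;
#' degrees of freedom are bins - 2 (one for the total, one for the
#' estimated rate).
#'
#' @param counts integer vector of per-cell counts (>= 20 cells).
#' @return list with `chi2`, `dof`, `p_value`.
#' @export
poisson_gof <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) < 20)
    stop("poisson_gof needs at least 20 cells")
  mu <- mean(counts)
  kmax <- max(counts)
  ks <- 0:kmax
  p <- dpois(ks, mu)
  p[length(p)] <- p[length(p)] + ppois(kmax, mu, lower.tail = FALSE)
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  expd <- p * length(counts)

  # merge from the upper then lower tail until all expected counts >= 5
  while (length(expd) > 1 && expd[length(expd)] < 5) {
    expd[length(expd) - 1] <- expd[length(expd) - 1] + expd[length(expd)]
    obs[length(obs) - 1] <- obs[length(obs) - 1] + obs[length(obs)]
    expd <- expd[-length(expd)]
    obs <- obs[-length(obs)]
  }
  while (length(expd) > 1 && expd[1] < 5) {
    expd[2] <- expd[2] + expd[1]
    obs[2] <- obs[2] + obs[1]
    expd <- expd[-1]
    obs <- obs[-1]
  }
  if (length(expd) < 3)
    stop("fewer than 3 bins after merging; goodness-of-fit test undefined")
  chi2 <- sum((obs - expd)^2 / expd)
  dof <- length(expd) - 2L
  list(chi2 = chi2, dof = dof,
       p_value = pchisq(chi2, dof, lower.tail = FALSE))
}

#' All adjacent-section interfaces of a set of columns
#'
#' One row per adjacent pair of sections of every column, whether or not
#' the neighbour set changes there; used to express transition
#' frequencies as per-interface rates.
#'
#' @param columns list of [cell_column()].
#' @return data.frame: cell_id, interface_index, rel_position,
#'   delta_area, delta_nuclear_area, delta_n, changed (logical).
#' @export
column_interfaces <- function(columns) {
  rows <- lapply(columns, function(cl) {
    k <- length(cl$z)
    if (k < 2) return(NULL)
    i <- seq_len(k - 1)
    ch <- vapply(i, function(j) !setequal(cl$neighbours[[j]],
                                          cl$neighbours[[j + 1]]), logical(1))
    data.frame(
      cell_id = cl$cell_id, interface_index = i,
      rel_position = (cl$z[i] + cl$z[i + 1]) / 2,
      delta_area = cl$area[i + 1] - cl$area[i],
      delta_nuclear_area = if (is.null(cl$nuclear_area)) NA_real_ else
        cl$nuclear_area[i + 1] - cl$nuclear_area[i],
      delta_n = lengths(cl$neighbours)[i + 1] - lengths(cl$neighbours)[i],
      changed = ch, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Transition direction versus cross-sectional area change
#'
#' Bins T1 events by the change in cell (or nuclear) cross-sectional area
#' across the event interface and reports, per bin, the fraction of
#' events that gain (`delta_n > 0`), keep (`= 0`) or lose (`< 0`)
#' neighbours. When `interfaces` (from [column_interfaces()]) is
#' supplied, per-interface transition rates are reported as well, so
#' frequencies are relative to all opportunities rather than to events
#' only. Empty bins are kept and flagged.
#'
#' @param events event data.frame from [detect_t1_all()].
#' @param breaks numeric bin breaks for the area change, um^2.
#' @param source `"cell"` or `"nucleus"`: which area change to bin on.
#' @param interfaces optional data.frame from [column_interfaces()].
#' @return data.frame per bin: bin_low, bin_high, bin_mid, n_events,
#'   frac_gain, frac_same, frac_lose, empty, and (with `interfaces`)
#'   n_interfaces, rate_gain, rate_lose.
#' @export
area_change_profile <- function(events, breaks, source = c("cell", "nucleus"),
                                interfaces = NULL) {
  source <- match.arg(source)
  dcol <- if (source == "cell") "delta_area" else "delta_nuclear_area"
  if (all(is.na(events[[dcol]])) && nrow(events) > 0)
    stop("events do not carry ", dcol)
  breaks <- sort(breaks)
  nb <- length(breaks) - 1
  stopifnot(nb >= 1)
  bin_of <- function(x) findInterval(x, breaks, rightmost.closed = TRUE,
                                     all.inside = FALSE)
  eb <- bin_of(events[[dcol]])
  out <- do.call(rbind, lapply(seq_len(nb), function(b) {
    sel <- which(eb == b)
    dn <- events$delta_n[sel]
    ne <- length(sel)
    row <- data.frame(
      bin_low = breaks[b], bin_high = breaks[b + 1],
      bin_mid = (breaks[b] + breaks[b + 1]) / 2,
      n_events = ne,
      frac_gain = if (ne > 0) mean(dn > 0) else NA_real_,
      frac_same = if (ne > 0) mean(dn == 0) else NA_real_,
      frac_lose = if (ne > 0) mean(dn < 0) else NA_real_,
      empty = ne == 0)
    if (!is.null(interfaces)) {
      ib <- bin_of(interfaces[[dcol]])
      ni <- sum(ib == b, na.rm = TRUE)
      row$n_interfaces <- ni
      row$rate_gain <- if (ni > 0) sum(dn > 0) / ni else NA_real_
      row$rate_lose <- if (ni > 0) sum(dn < 0) / ni else NA_real_
    }
    row
  }))
  out
}

#' Apical-basal histogram of transition positions
#'
#' Normalised histogram of relative event positions over `[0, 1]`.
#'
#' @param events event data.frame from [detect_t1_all()].
#' @param n_bins number of equal-width bins (>= 2).
#' @return data.frame: bin_low, bin_high, bin_mid, count, fraction.
#' @export
position_histogram <- function(events, n_bins = 10L) {
  stopifnot(n_bins >= 2)
  if (nrow(events) == 0) stop("no events to histogram")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  b <- findInterval(events$rel_position, breaks, rightmost.closed = TRUE)
  counts <- tabulate(b, nbins = n_bins)
  data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
             bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
             count = counts, fraction = counts / sum(counts))
}

#' Abstract columns with Poisson-distributed transition counts
#'
#' Generates neighbour-set sequences in which the number of neighbour
#' changes per column is Poisson with the given rate and transition
#' interfaces are placed uniformly at random; areas are constant. Used to
#' exercise the T1 machinery in isolation from the tissue generator.
#'
#' @param n_cells number of columns.
#' @param rate Poisson mean number of transitions per column (> 0 allowed
#'   to be 0 for the degenerate no-transition case).
#' @param n_layers sections per column.
#' @param seed integer seed; all randomness derives from it.
#' @param height cell height, um.
#' @return list of [cell_column()].
#' @export
generate_poisson_columns <- function(n_cells, rate, n_layers = 30L,
                                     seed = 1L, height = 25) {
  if (rate < 0) stop("rate must be non-negative")
  stopifnot(n_cells >= 1, n_layers >= 2)
  with_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      k_tr <- rpois(1, rate)
      n_if <- n_layers - 1
      k_tr <- min(k_tr, n_if)  # at most one change per interface
      ifs <- sort(sample.int(n_if, k_tr))
      base <- paste0("nb", 1:6)
      nbrs <- vector("list", n_layers)
      cur <- base
      next_id <- 7L
      j <- 1L
      for (l in seq_len(n_layers)) {
        if (j <= k_tr && l > ifs[j]) {
          while (j <= k_tr && l > ifs[j]) {
            drop <- sample(seq_along(cur), 1)
            cur <- c(cur[-drop], paste0("nb", next_id))
            next_id <- next_id + 1L
            j <- j + 1L
          }
        }
        nbrs[[l]] <- cur
      }
      cell_column(paste0("c", i), 0:(n_layers - 1),
                  z = (seq_len(n_layers) - 0.5) / n_layers,
                  area = rep(20, n_layers), neighbours = nbrs,
                  height = height)
    })
  })
}

# evaluate expr under a fixed RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
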