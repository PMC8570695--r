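#' Write an integer label stack as multi-page TIFF
#'
#' One page per cross-section, apical first; labels stored losslessly as
#' 16-bit samples (0 = background).
#'
#' @param stack list of integer matrices (equal dimensions).
#' @param path output file.
#' @export
write_label_stack <- function(stack, path) {
  stopifnot(length(stack) >= 1)
  dims <- lapply(stack, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("all pages must have identical dimensions")
  mx <- max(vapply(stack, max, numeric(1)))
  if (mx > 65535) stop("labels exceed the 16-bit range")
  pages <- lapply(stack, function(m) {
    if (any(m %% 1 != 0) || any(m < 0))
      stop("labels must be non-negative integers")
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read an integer label stack from multi-page TIFF
#'
#' @param path TIFF file with integer samples.
#' @param axis_order `"apical_first"` (default) or `"basal_first"`; the
#'   returned list is always ordered apical to basal (element 1 =
#'   apical).
#' @return list of integer matrices.
#' @export
read_label_stack <- function(path, axis_order = c("apical_first",
                                                  "basal_first")) {
  axis_order <- match.arg(axis_order)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) paste(dim(p), collapse = "x"),
                 character(1))
  if (length(unique(dims)) != 1)
    stop("inconsistent page shapes in ", path)
  out <- lapply(pages, function(p) {
    if (length(dim(p)) > 2) stop("expected single-channel label pages")
    if (any(p %% 1 != 0)) stop("float pixel types are not label images")
    # float samples read raw reinterpret as arbitrary (negative) integers
    if (any(p < 0)) stop("negative sample values are not label images")
    storage.mode(p) <- "integer"
    p
  })
  if (axis_order == "basal_first") out <- rev(out)
  out
}

#' Tidy per-section cell table of a synthetic tissue
#'
#' @param tissue a `synthetic_tissue`.
#' @return data.frame: cell_id, layer, z, area_um2, neighbour_ids
#'   (semicolon-joined), nuclear_area_um2, interior.
#' @export
cells_table <- function(tissue) {
  do.call(rbind, lapply(tissue$layers, function(ly) {
    i <- match(ly$cell_id, tissue$nuclei$cell_id)
    col_idx <- match(ly$cell_id,
                     vapply(tissue$columns, function(cl) cl$cell_id,
                            character(1)))
    nuc <- vapply(seq_along(ly$cell_id), function(k) {
      cl <- tissue$columns[[col_idx[k]]]
      cl$nuclear_area[ly$layer_index + 1L]
    }, numeric(1))
    data.frame(cell_id = ly$cell_id, layer = ly$layer_index, z = ly$z,
               area_um2 = ly$area,
               neighbour_ids = vapply(ly$neighbours, paste,
                                      character(1), collapse = ";"),
               nuclear_area_um2 = nuc, interior = ly$interior,
               stringsAsFactors = FALSE)
  }))
}

#' Per-nucleus table of a synthetic tissue
#'
#' @param tissue a `synthetic_tissue`.
#' @return data.frame: cell_id, centre_z, volume_um3, semi_xy, semi_z.
#' @export
nuclei_table <- function(tissue) tissue$nuclei

#' Read a cells table back into layers and columns
#'
#' Inverse of writing [cells_table()] to CSV: rebuilds the
#' [polygonal_layer()] list and [cell_column()] list.
#'
#' @param cells data.frame in the `cells.csv` dialect (or a file path).
#' @param height cell height, um, attached to the columns.
#' @return list with `layers` and `columns`.
#' @export
read_cells <- function(cells, height = NA_real_) {
  if (is.character(cells)) cells <- read.csv(cells,
                                             stringsAsFactors = FALSE)
  need <- c("cell_id", "layer", "z", "area_um2", "neighbour_ids")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0)
    stop("cells table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(cells$interior)) cells$interior <- TRUE
  if (is.null(cells$nuclear_area_um2)) cells$nuclear_area_um2 <- NA_real_
  cells$cell_id <- as.character(cells$cell_id)
  split_ids <- function(s) {
    if (is.na(s) || s == "") character(0) else strsplit(s, ";")[[1]]
  }
  layers <- lapply(split(cells, cells$layer), function(sub) {
    polygonal_layer(sub$cell_id, sub$area_um2,
                    stats::setNames(lapply(sub$neighbour_ids, split_ids),
                                    sub$cell_id),
                    sub$interior, layer_index = sub$layer[1],
                    z = sub$z[1])
  })
  layers <- layers[order(vapply(layers, `[[`, integer(1), "layer_index"))]
  columns <- lapply(split(cells, cells$cell_id), function(sub) {
    sub <- sub[order(sub$layer), ]
    cell_column(sub$cell_id[1], sub$layer, sub$z, sub$area_um2,
                lapply(sub$neighbour_ids, split_ids),
                nuclear_area = sub$nuclear_area_um2, height = height)
  })
  list(layers = layers, columns = unname(columns))
}

#' Per-layer statistics tables
#'
#' Long (per layer x class) and summary (per layer) tables for a list of
#' layers.
#'
#' @param layers list of [polygonal_layer()].
#' @return list with `per_class` (layer, z, n, count, freq, m_n, m_n_sem,
#'   lewis_ratio, lewis_sem) and `summary` (layer, z, n_cells, n_bar,
#'   area_cv, hex_fraction).
#' @export
layer_stats_tables <- function(layers) {
  stats <- lapply(layers, layer_stats)
  per_class <- do.call(rbind, lapply(stats, function(s) {
    merge(
      data.frame(layer = s$layer_index, z = s$z,
                 n = as.integer(names(s$freq)),
                 freq = as.numeric(s$freq)),
      merge(s$aw_table[c("n", "m_n", "sem", "count")],
            s$lewis_table[c("n", "lewis_ratio", "sem")],
            by = "n", suffixes = c("_mn", "_lewis")),
      by = "n")
  }))
  names(per_class)[names(per_class) == "sem_mn"] <- "m_n_sem"
  names(per_class)[names(per_class) == "sem_lewis"] <- "lewis_sem"
  summary <- do.call(rbind, lapply(stats, function(s)
    data.frame(layer = s$layer_index, z = s$z, n_cells = s$n_interior,
               n_bar = s$n_bar, area_cv = s$area_cv,
               hex_fraction = s$hex_fraction)))
  list(per_class = per_class[order(per_class$layer, per_class$n), ],
       summary = summary)
}

#' Read a run configuration from YAML or JSON
#'
#' Field names mirror [simulation_config()]; unknown fields are
#' rejected. A `.json` extension selects the JSON parser, anything else
#' is read as YAML.
#'
#' @param path config file.
#' @return [simulation_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  allowed <- names(formals(simulation_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0)
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(simulation_config, vals)
}

#' Run the full analysis pipeline on a synthetic tissue
#'
#' Generates a tissue from the configuration and runs every analysis
#' stage: per-layer lattice statistics, T1 detection and Poisson
#' statistics, optional curvature fold changes (when a tube geometry is
#' given), nuclear morphometrics and couplings, and theory overlays. All
#' tables are written under `output_dir` together with a `report.json`
#' of headline statistics. Deterministic for a fixed config.
#'
#' @param config a [simulation_config()] or path to a YAML/JSON config.
#' @param output_dir directory for outputs (created if needed).
#' @param geometry optional [tube_geometry()] enabling the curvature
#'   stage.
#' @param write_stacks logical; also write the TIFF label stacks.
#' @return the report, invisibly (a named list mirroring report.json).
#' @export
run_pipeline <- function(config, output_dir, geometry = NULL,
                         write_stacks = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "simulation_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  tissue <- stage("simulate", generate_tissue(config))
  cells <- cells_table(tissue)
  write.csv(cells, file.path(output_dir, "cells.csv"), row.names = FALSE)
  write.csv(nuclei_table(tissue), file.path(output_dir, "nuclei.csv"),
            row.names = FALSE)
  if (write_stacks) {
    write_label_stack(tissue$label_stack,
                      file.path(output_dir, "cells.tif"))
    write_label_stack(tissue$nucleus_stack,
                      file.path(output_dir, "nuclei.tif"))
  }

  lt <- stage("layer_morphometrics", layer_stats_tables(tissue$layers))
  write.csv(lt$per_class, file.path(output_dir, "layer_stats.csv"),
            row.names = FALSE)
  write.csv(lt$summary, file.path(output_dir, "layer_summary.csv"),
            row.names = FALSE)

  ts <- stage("t1_dynamics", transition_stats(tissue$columns))
  events <- detect_t1_all(tissue$columns)
  write.csv(events, file.path(output_dir, "t1_events.csv"),
            row.names = FALSE)
  t1_json <- list(mean = ts$mean, variance = ts$variance,
                  dispersion_index = ts$dispersion_index,
                  chi2 = ts$chi2, dof = ts$dof, p_value = ts$p_value,
                  mean_rel_position = ts$mean_rel_position,
                  rel_position_ci = ts$rel_position_ci)
  jsonlite::write_json(t1_json, file.path(output_dir, "t1_stats.json"),
                       auto_unbox = TRUE, digits = NA)

  curvature <- NULL
  if (!is.null(geometry)) {
    folds <- stage("curvature_model",
                   event_fold_changes(tissue$columns, geometry))
    write.csv(folds, file.path(output_dir, "fold_changes.csv"),
              row.names = FALSE)
    jsonlite::write_json(unclass(geometry),
                         file.path(output_dir, "geometry.json"),
                         auto_unbox = TRUE, digits = NA)
    curvature <- list(
      n_segments = nrow(folds),
      mean_fold = if (nrow(folds) > 0) mean(folds$fold) else NA,
      overall_fold = local_radius(1, geometry) / local_radius(0, geometry))
  }

  nuc <- stage("nuclear_ikm", {
    nm <- nuclear_stats_from_tissue(tissue)
    corr <- cell_nucleus_correlation(tissue$columns, nm)
    write.csv(nm, file.path(output_dir, "nuclear_stats.csv"),
              row.names = FALSE)
    list(r_volume = corr$r_volume, r_area = corr$r_area,
         mean_volume_fraction = mean(nm$volume_um3) /
           (config$domain_width * config$domain_height *
              config$tissue_height / config$n_cells))
  })

  curves <- stage("organisation_theory", theory_curves())
  write.csv(curves, file.path(output_dir, "theory_curves.csv"),
            row.names = FALSE)

  report <- list(
    config = unclass(config)[setdiff(names(unclass(config)),
                                     "seed_points")],
    layers = list(n_bar = lt$summary$n_bar,
                  area_cv = lt$summary$area_cv,
                  hex_fraction = lt$summary$hex_fraction),
    t1 = t1_json,
    curvature = curvature,
    nuclear = nuc)
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
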