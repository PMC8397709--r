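#' Read and write ROI sets
#'
#' CSV layout: columns `id`, `x_um`, `y_um`, `diameter_um`. The JSON
#' layout stores the same records as an array of objects.
#'
#' @param rois A [roi_set()].
#' @param path Output path; `.json` extension selects JSON, anything else CSV.
#' @export
write_rois <- function(rois, path) {
  df <- data.frame(id = rois$ids, x_um = rois$centers[, 1L],
                   y_um = rois$centers[, 2L], diameter_um = rois$diameter,
                   row.names = NULL)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_rois
#' @param check_count Warn when the ROI count is outside 18-40.
#' @export
read_rois <- function(path, check_count = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
  need <- c("id", "x_um", "y_um", "diameter_um")
  if (!all(need %in% names(df))) {
    stopf("ROI table must have columns %s", paste(need, collapse = ", "))
  }
  roi_set(cbind(df$x_um, df$y_um), diameter = df$diameter_um, ids = df$id,
          check_count = check_count)
}

#' Serialise geometry or ground truth to JSON
#'
#' @param x An `islet_geometry` or `ground_truth` object.
#' @param path Output path.
#' @export
write_geometry_json <- function(x, path) {
  stopifnot(inherits(x, "islet_geometry"))
  obj <- list(cell_ids = x$cell_ids,
              positions = as.data.frame(x),
              islet_radius = x$islet_radius, min_spacing = x$min_spacing)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- as.matrix(obj$positions[, c("x_um", "y_um")])
  rownames(pos) <- as.character(obj$positions$id)
  structure(list(cell_ids = obj$positions$id, positions = pos,
                 islet_radius = obj$islet_radius, min_spacing = obj$min_spacing),
            class = "islet_geometry")
}

#' @rdname write_geometry_json
#' @export
write_ground_truth_json <- function(x, path) {
  stopifnot(inherits(x, "ground_truth"))
  obj <- list(level = x$level, origin = x$origin,
              true_velocity = x$true_velocity,
              onsets = x$onsets, recruited_cells = x$recruited_cells)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Serialise a classification to JSON
#'
#' Writes the level, the per-event table (type, times, regions, ordering
#' statistic, velocity) and the classifier parameters.
#'
#' @param x An `islet_activity` from [classify_activity()].
#' @param path Output path.
#' @export
write_classification_json <- function(x, path) {
  stopifnot(inherits(x, "islet_activity"))
  obj <- list(level = x$level, n_full = x$n_full, n_partial = x$n_partial,
              events = x$events %||% list(), params = x$params)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Write the pairwise adjacency as CSV
#'
#' One row per unordered off-diagonal pair: `cell_i, cell_j, R,
#' significant, bin`.
#'
#' @param result A [significant_pairs()] result.
#' @param path Output path.
#' @export
write_adjacency_csv <- function(result, path) {
  r <- result$r
  idx <- which(upper.tri(r), arr.ind = TRUE)
  df <- data.frame(cell_i = rownames(r)[idx[, 1L]],
                   cell_j = colnames(r)[idx[, 2L]],
                   R = r[idx],
                   significant = result$adjacency[idx],
                   bin = as.character(bin_correlation(r[idx])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a connectivity map specification to JSON
#'
#' @param map A [connectivity_map()].
#' @param path Output path.
#' @export
write_map_json <- function(map, path) {
  stopifnot(inherits(map, "connectivity_map"))
  jsonlite::write_json(list(points = map$points, segments = map$segments),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort design from a YAML config
#'
#' The config declares `groups`, `weeks`, `baseline_week`, optional method
#' defaults and a `design` block of per-group, per-week level
#' probabilities:
#'
#' ```yaml
#' baseline_week: 0
#' islets_per_group: 20
#' design:
#'   - {group: sham, week: 0, p0: 0.05, p1: 0.15, p2: 0.30, p3: 0.40, p4: 0.10}
#' ```
#'
#' @param path YAML file path.
#' @return A list with `design` (data.frame ready for [simulate_cohort()])
#'   and the remaining top-level settings.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$design)) stopf("config lacks a `design` block")
  design <- do.call(rbind, lapply(cfg$design, function(row) {
    need <- c("group", "week", paste0("p", 0:4))
    if (!all(need %in% names(row))) {
      stopf("malformed design row: needs %s", paste(need, collapse = ", "))
    }
    as.data.frame(row[need])
  }))
  cfg$design <- design
  cfg
}
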