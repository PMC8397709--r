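#' Generate an islet geometry of ROI-scale cell positions
#'
#' Samples `n_cells` cell (ROI) centres uniformly inside a disc of radius
#' `islet_radius`, rejecting proposals closer than `min_spacing` to an
#' accepted centre. This mimics the cell-scale regions of interest drawn on
#' an imaged islet plane: centres are expressed in micrometres relative to
#' the islet centroid, and the default spacing corresponds to near
#' single-cell resolution (ROI diameters of 10-20 um).
#'
#' @param n_cells Number of cells (>= 1). Study-like islets carry 18-40.
#' @param islet_radius Islet radius in um; every centre lies within it.
#' @param min_spacing Minimum pairwise centre distance in um.
#' @param seed Optional integer seed; identical seeds give identical
#'   geometries and the caller's RNG stream is left untouched.
#' @param max_restarts Number of complete re-samplings attempted before the
#'   packing is declared infeasible.
#'
#' @return An object of class `islet_geometry`: a list with `cell_ids`,
#'   `positions` (an `n_cells` x 2 matrix of x/y in um), `islet_radius` and
#'   `min_spacing`.
#'
#' @details Random sequential packing of discs jams well below the
#' hexagonal-packing density, so a requested configuration whose spacing
#' discs would occupy more than ~55% of the (dilated) islet area is refused
#' up front rather than after a long futile search.
#'
#' @examples
#' geom <- make_islet_geometry(25, islet_radius = 60, min_spacing = 12, seed = 1)
#' geom
#' @export
make_islet_geometry <- function(n_cells, islet_radius = 60, min_spacing = 12,
                                seed = NULL, max_restarts = 25L) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1 ||
      n_cells != round(n_cells)) {
    stopf("`n_cells` must be a single integer >= 1")
  }
  n_cells <- as.integer(n_cells)
  assert_number(islet_radius, "islet_radius", lower = 0, strict_lower = TRUE)
  assert_number(min_spacing, "min_spacing", lower = 0, strict_lower = TRUE)

  # area bound: random sequential disc packing jams near 55% coverage
  cover <- n_cells * (min_spacing / 2)^2 / (islet_radius + min_spacing / 2)^2
  if (cover > 0.55) {
    stopf(paste0(
      "packing infeasible: %d cells with %.3g um spacing cannot fit in an ",
      "islet of radius %.3g um (requested coverage %.0f%% of the disc)"),
      n_cells, min_spacing, islet_radius, 100 * cover)
  }

  pos <- with_seed(seed, {
    out <- NULL
    for (restart in seq_len(max_restarts)) {
      pts <- matrix(NA_real_, n_cells, 2L)
      k <- 0L
      tries <- 0L
      budget <- 4000L * n_cells
      while (k < n_cells && tries < budget) {
        tries <- tries + 1L
        r <- islet_radius * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        p <- c(r * cos(th), r * sin(th))
        if (k == 0L ||
            min(sqrt((pts[seq_len(k), 1L] - p[1L])^2 +
                     (pts[seq_len(k), 2L] - p[2L])^2)) >= min_spacing) {
          k <- k + 1L
          pts[k, ] <- p
        }
      }
      if (k == n_cells) {
        out <- pts
        break
      }
    }
    out
  })
  if (is.null(pos)) {
    stopf("packing infeasible: could not place %d cells with %.3g um spacing in radius %.3g um after %d restarts",
          n_cells, min_spacing, islet_radius, max_restarts)
  }
  colnames(pos) <- c("x_um", "y_um")
  ids <- seq_len(n_cells)
  rownames(pos) <- as.character(ids)
  structure(
    list(cell_ids = ids, positions = pos,
         islet_radius = islet_radius, min_spacing = min_spacing),
    class = "islet_geometry")
}

#' @export
print.islet_geometry <- function(x, ...) {
  cat(sprintf("<islet_geometry> %d cells, radius %.4g um, min spacing %.4g um\n",
              length(x$cell_ids), x$islet_radius, x$min_spacing))
  invisible(x)
}

#' @export
as.data.frame.islet_geometry <- function(x, ...) {
  data.frame(id = x$cell_ids, x_um = x$positions[, 1L], y_um = x$positions[, 2L],
             row.names = NULL)
}

n_cells_of <- function(geometry) length(geometry$cell_ids)

#' Manually assemble a region partition
#'
#' Wraps an explicit cell-to-region assignment (for example hand-drawn
#' region masks) into the object consumed by [classify_activity()].
#'
#' @param region Integer vector of region labels `1..n_regions`
#'   (1 = distal, increasing towards proximal), one per cell.
#' @param cell_ids Cell identifiers, recycled from `names(region)` or
#'   positional indices when absent.
#' @param n_regions Number of regions; defaults to `max(region)`.
#' @return An object of class `region_partition`.
#' @export
region_partition <- function(region, cell_ids = NULL, n_regions = max(region)) {
  nm <- names(region)
  region <- as.integer(region)
  names(region) <- nm
  if (anyNA(region) || any(region < 1L) || any(region > n_regions)) {
    stopf("`region` must assign every cell to a region in 1..%d", n_regions)
  }
  cell_ids <- cell_ids %||% names(region) %||% seq_along(region)
  if (anyDuplicated(cell_ids)) stopf("cell ids must be unique")
  structure(
    list(region = stats::setNames(region, as.character(cell_ids)),
         n_regions = as.integer(n_regions), axis = NULL),
    class = "region_partition")
}

#' Partition an islet into ordered regions along an axis
#'
#' Projects cell positions onto an axis and splits them into `n_regions`
#' bands of equal cell count (within one). Region 1 is the distal band
#' (lowest projection), region `n_regions` the proximal band, reproducing
#' the three-region layout used to categorise wave propagation across an
#' imaged islet.
#'
#' @param x An `islet_geometry`, `roi_set`, or a 2-column position matrix.
#' @param n_regions Number of bands (default 3).
#' @param axis Either `"principal"` (first principal axis of the positions)
#'   or an explicit length-2 direction vector.
#' @return A `region_partition` with the (unit) axis recorded.
#' @examples
#' geom <- make_islet_geometry(24, seed = 2)
#' part <- partition_regions(geom)
#' table(part$region)
#' @export
partition_regions <- function(x, n_regions = 3L, axis = "principal") {
  pos <- positions_of(x)
  n <- nrow(pos)
  if (!is.numeric(n_regions) || n_regions < 1L) stopf("`n_regions` must be >= 1")
  n_regions <- as.integer(n_regions)
  if (n < n_regions) stopf("need at least %d cells for %d regions", n_regions, n_regions)

  if (is.character(axis) && identical(axis, "principal")) {
    centred <- sweep(pos, 2L, colMeans(pos))
    if (max(abs(centred)) < sqrt(.Machine$double.eps)) {
      stopf("principal axis undefined: all positions identical; supply `axis` explicitly")
    }
    v <- svd(centred, nu = 0L, nv = 1L)$v[, 1L]
  } else {
    if (!is.numeric(axis) || length(axis) != 2L || all(axis == 0)) {
      stopf("`axis` must be \"principal\" or a non-zero length-2 vector")
    }
    v <- axis / sqrt(sum(axis^2))
  }
  # canonical sign so a given point cloud always yields the same labels
  if (v[which.max(abs(v))] < 0) v <- -v

  proj <- as.numeric(pos %*% v)
  rk <- rank(proj, ties.method = "first")
  region <- as.integer(ceiling(rk * n_regions / n))
  ids <- rownames(pos) %||% as.character(seq_len(n))
  structure(
    list(region = stats::setNames(region, ids),
         n_regions = n_regions, axis = v),
    class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> %d regions: %s cells\n", x$n_regions,
              paste(tabulate(x$region, x$n_regions), collapse = "/")))
  invisible(x)
}

positions_of <- function(x) {
  if (inherits(x, "islet_geometry")) return(x$positions)
  if (inherits(x, "roi_set")) return(x$centers)
  if (is.matrix(x) && ncol(x) == 2L) {
    if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
    return(x)
  }
  stopf("expected an islet_geometry, roi_set or n x 2 position matrix")
}
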