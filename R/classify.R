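#' Classify a recording on the five-level activity scale
#'
#' Clusters detected onsets into candidate events and grades the recording:
#' 0 no activity, 1 oscillations (activity without ordered inter-region
#' propagation), 2 partial wave (ordered recruitment of two of the three
#' regions), 3 full wave (ordered recruitment of all three regions within
#' the propagation window), 4 superwave (two or more full waves in one
#' capture). The recording's level is the highest level supported by any
#' of its events.
#'
#' An event is graded a *wave* (full or partial) when it shows all the
#' hallmarks of a propagating front, each physically motivated and each a
#' tunable parameter:
#' * enough recruitment: at least `min_wave_cells` cells and
#'   `min_wave_fraction` of the islet fire in the event;
#' * ordered onsets: the Spearman agreement between cell onset times and a
#'   spatial coordinate of the cells -- either the projection on the
#'   partition axis or the radial distance from the earliest-firing cell
#'   (the natural coordinate of a radially spreading front) -- reaches
#'   `ordered_rho` in magnitude with rank-test p-value at most
#'   `ordered_alpha`. Recruitment and compactness carry most of the
#'   discrimination, so the ordering screen is tuned for sensitivity;
#'   sporadic site activity that happens to be compact rarely shows even
#'   this much spatial order;
#' * temporal compactness: the mean gap between consecutive onsets is at
#'   most `max_mean_gap_s` (recruitment by a front at tens of um/s is
#'   quasi-continuous, whereas independent oscillations straggle over
#'   seconds);
#' * a real lag: the onset span exceeds one frame, so a synchronous
#'   whole-islet burst grades as oscillation, not wave.
#'
#' A wave is *full* when all three regions are recruited (at least
#' `min_region_cells` cells each) with their median onsets inside the
#' propagation window -- or, alternatively, when it recruits at least
#' `full_fraction` of all cells, if that criterion is enabled. An ordered
#' wave that does not reach full recruitment is *partial*.
#'
#' @param onsets An [detect_onsets()] table (or a named list of per-cell
#'   onset-time vectors).
#' @param partition A [partition_regions()] result over the same cells;
#'   the default grading requires exactly 3 regions.
#' @param geometry Optional [make_islet_geometry()]: enables per-event
#'   velocity estimates and an islet-size-based propagation window.
#' @param full_fraction Optional cell-level full-wave criterion: when set
#'   (e.g. 0.9), a full wave must additionally recruit at least this
#'   fraction of all cells.
#' @param propagation_window_s Window (s) within which all regions must be
#'   recruited for one wave. Default: `2 * islet diameter / 5 um/s` when a
#'   geometry is supplied (twice the crossing time at a slow 5 um/s
#'   front), otherwise 40 s.
#' @param event_gap_s Pooled onsets further apart than this start a new
#'   candidate event (default 5 s).
#' @param ordered_rho Minimum |Spearman rho| for ordered propagation.
#' @param ordered_alpha Maximum two-sided rank-test p-value for ordered
#'   propagation.
#' @param min_wave_cells,min_wave_fraction Minimum recruitment (count and
#'   islet fraction) for an event to qualify as a wave.
#' @param max_mean_gap_s Maximum mean inter-onset gap (s) within a wave.
#' @param min_region_cells Cells a region must contribute to count as
#'   recruited (capped at the region's size).
#' @param velocity_reference Passed to [wave_velocity()] for per-event
#'   velocities.
#' @return An object of class `islet_activity`: list with `level`, the
#'   per-event table `events` (type, times, regions recruited, ordering
#'   statistic, velocity), counts of full/partial events, and parameters.
#' @export
classify_activity <- function(onsets, partition, geometry = NULL,
                              full_fraction = NULL,
                              propagation_window_s = NULL,
                              event_gap_s = 5,
                              ordered_rho = 0.5,
                              ordered_alpha = 0.25,
                              min_wave_cells = 4L,
                              min_wave_fraction = 0.15,
                              max_mean_gap_s = 0.75,
                              min_region_cells = 2L,
                              velocity_reference = c("cells", "regions")) {
  onset_list <- if (inherits(onsets, "onset_table")) onsets$onsets else onsets
  if (!inherits(partition, "region_partition")) stopf("`partition` must be a region_partition")
  if (partition$n_regions != 3L) {
    stopf("default grading expects a 3-region partition (got %d)", partition$n_regions)
  }
  velocity_reference <- match.arg(velocity_reference)
  ids <- names(partition$region)
  missing_ids <- setdiff(names(onset_list), ids)
  if (length(missing_ids) > 0L) {
    stopf("onsets and partition refer to different cells (e.g. %s)", missing_ids[1L])
  }
  if (is.null(propagation_window_s)) {
    propagation_window_s <- if (!is.null(geometry)) {
      2 * (2 * geometry$islet_radius) / 5
    } else 40
  }

  n_total <- length(partition$region)
  region_size <- tabulate(partition$region, partition$n_regions)

  # pooled (cell, onset) pairs
  cell <- rep(names(onset_list), vapply(onset_list, length, 1L))
  tt <- unlist(onset_list, use.names = FALSE)
  if (length(tt) == 0L) {
    return(structure(list(level = 0L, events = NULL, n_full = 0L, n_partial = 0L,
                          params = list(propagation_window_s = propagation_window_s,
                                        event_gap_s = event_gap_s,
                                        ordered_rho = ordered_rho,
                                        ordered_alpha = ordered_alpha,
                                        min_wave_cells = min_wave_cells,
                                        min_wave_fraction = min_wave_fraction,
                                        max_mean_gap_s = max_mean_gap_s,
                                        min_region_cells = min_region_cells,
                                        full_fraction = full_fraction)),
                     class = "islet_activity"))
  }
  ord <- order(tt)
  tt <- tt[ord]; cell <- cell[ord]
  new_event <- c(TRUE, diff(tt) > event_gap_s)
  event_id <- cumsum(new_event)

  fps <- if (inherits(onsets, "onset_table")) onsets$fps else 3
  # cell coordinate along the partition axis; fallback: region ordinal
  proj <- if (!is.null(geometry) && !is.null(partition$axis)) {
    stats::setNames(as.numeric(positions_of(geometry)[ids, , drop = FALSE] %*%
                                 partition$axis), ids)
  } else {
    stats::setNames(as.numeric(partition$region), ids)
  }

  events <- NULL
  for (e in unique(event_id)) {
    sel <- event_id == e
    ec <- cell[sel]; et <- tt[sel]
    first_onset <- stats::setNames(et, ec)
    first_onset <- first_onset[!duplicated(ec)]          # earliest onset per cell
    reg <- partition$region[names(first_onset)]
    per_region <- tabulate(reg, partition$n_regions)
    recruited_regions <- which(per_region >= pmin(min_region_cells, region_size))
    n_ev <- length(first_onset)
    span <- max(first_onset) - min(first_onset)
    mean_gap <- if (n_ev > 1L) span / (n_ev - 1L) else Inf
    spread <- if (length(recruited_regions) >= 2L) {
      med <- vapply(recruited_regions, function(g) {
        stats::median(first_onset[reg == g])
      }, numeric(1))
      max(med) - min(med)
    } else span

    type <- "oscillation"
    rho <- NA_real_
    p_ord <- NA_real_
    vel <- NA_real_
    candidate <- n_ev >= max(min_wave_cells, ceiling(min_wave_fraction * n_total)) &&
      mean_gap <= max_mean_gap_s && span > 1 / fps
    if (candidate) {
      coords <- list(axis = proj[names(first_onset)])
      if (!is.null(geometry)) {
        pos_ev <- positions_of(geometry)[names(first_onset), , drop = FALSE]
        o1 <- pos_ev[which.min(first_onset), ]
        coords$radial <- sqrt((pos_ev[, 1L] - o1[1L])^2 + (pos_ev[, 2L] - o1[2L])^2)
      }
      ordered <- FALSE
      for (co in coords) {
        ord <- suppressWarnings(stats::cor.test(first_onset, co, method = "spearman"))
        if (is.finite(ord$estimate) &&
            (!is.finite(p_ord) || ord$p.value < p_ord)) {
          rho <- unname(ord$estimate)
          p_ord <- ord$p.value
        }
        if (is.finite(ord$estimate) && abs(ord$estimate) >= ordered_rho &&
            ord$p.value <= ordered_alpha) ordered <- TRUE
      }
      if (ordered) {
        region_full <- length(recruited_regions) == partition$n_regions &&
          spread <= propagation_window_s
        cell_full <- !is.null(full_fraction) && n_ev / n_total >= full_fraction
        type <- if (region_full || cell_full) "full" else "partial"
      }
    }
    if (type %in% c("full", "partial") && !is.null(geometry)) {
      vel <- tryCatch(
        wave_velocity(first_onset, geometry, partition,
                      reference = velocity_reference),
        error = function(e) NA_real_)
    }
    events <- rbind(events, data.frame(
      event = e, type = type, t_start = min(et), t_end = max(et),
      n_cells = n_ev,
      n_regions = length(recruited_regions),
      regions = paste(recruited_regions, collapse = ","),
      spread_s = spread, mean_gap_s = mean_gap, rho = rho, p_ordered = p_ord,
      velocity_um_s = as.numeric(vel),
      stringsAsFactors = FALSE))
  }

  n_full <- sum(events$type == "full")
  n_partial <- sum(events$type == "partial")
  level <- if (n_full >= 2L) 4L else if (n_full >= 1L) 3L else if (n_partial >= 1L) 2L else 1L
  structure(
    list(level = level, events = events, n_full = n_full, n_partial = n_partial,
         params = list(propagation_window_s = propagation_window_s,
                       event_gap_s = event_gap_s, ordered_rho = ordered_rho,
                       ordered_alpha = ordered_alpha,
                       min_wave_cells = min_wave_cells,
                       min_wave_fraction = min_wave_fraction,
                       max_mean_gap_s = max_mean_gap_s,
                       min_region_cells = min_region_cells,
                       full_fraction = full_fraction)),
    class = "islet_activity")
}

#' @export
print.islet_activity <- function(x, ...) {
  lab <- c("no activity", "oscillations", "partial wave", "wave", "superwave")
  cat(sprintf("<islet_activity> level %d (%s); %d full / %d partial / %d event(s)\n",
              x$level, lab[x$level + 1L], x$n_full, x$n_partial,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

#' Wavefront velocity as distance over onset lag (d / dt, um/s)
#'
#' Estimates the speed of a propagating event from per-cell onset times
#' and cell positions. Two choices of reference points are provided:
#'
#' * `"cells"` (default): `d` is the distance between the first- and
#'   last-recruited cells and `dt` the lag between their onsets. For
#'   radially spreading waves this reference is the less biased of the
#'   two, because the extreme cells sit on the wave path.
#' * `"regions"`: `d` is the distance between the centroids of the first-
#'   and last-recruited regions' cells and `dt` the difference of the
#'   regions' median onset times.
#'
#' @param onset_times Named numeric vector: one onset time (s) per
#'   recruited cell (names = cell ids), typically the cells of one event.
#' @param geometry An [make_islet_geometry()] covering those cells.
#' @param partition A [partition_regions()] result (required for
#'   `reference = "regions"`).
#' @param reference `"cells"` or `"regions"` (see above).
#' @return The velocity in um/s, with attributes `d_um`, `dt_s` and
#'   `reference`.
#' @examples
#' geom <- make_islet_geometry(2, islet_radius = 60, min_spacing = 10, seed = 1)
#' geom$positions[] <- c(0, 100, 0, 0)  # 100 um apart
#' v <- wave_velocity(c(`1` = 0, `2` = 2), geom)
#' as.numeric(v)  # 50 um/s
#' @export
wave_velocity <- function(onset_times, geometry, partition = NULL,
                          reference = c("cells", "regions")) {
  reference <- match.arg(reference)
  if (!is.numeric(onset_times) || is.null(names(onset_times))) {
    stopf("`onset_times` must be a named numeric vector of per-cell onsets")
  }
  onset_times <- onset_times[is.finite(onset_times)]
  if (length(onset_times) < 2L) stopf("not a wave: fewer than two recruited cells")
  pos <- positions_of(geometry)
  miss <- setdiff(names(onset_times), rownames(pos))
  if (length(miss) > 0L) stopf("geometry lacks position(s) for cell(s) %s", paste(miss, collapse = ", "))

  if (reference == "cells") {
    i1 <- names(onset_times)[which.min(onset_times)]
    i2 <- names(onset_times)[which.max(onset_times)]
    d <- euclid(pos[i1, ], pos[i2, ])
    dt <- onset_times[[i2]] - onset_times[[i1]]
  } else {
    if (!inherits(partition, "region_partition")) {
      stopf("`partition` is required for reference = \"regions\"")
    }
    reg <- partition$region[names(onset_times)]
    if (anyNA(reg)) stopf("partition lacks region(s) for some recruited cells")
    med <- tapply(onset_times, reg, stats::median)
    if (length(med) < 2L) stopf("not a wave: only one region recruited")
    g1 <- names(med)[which.min(med)]
    g2 <- names(med)[which.max(med)]
    cells1 <- names(partition$region)[partition$region == as.integer(g1)]
    cells2 <- names(partition$region)[partition$region == as.integer(g2)]
    c1 <- colMeans(pos[intersect(cells1, names(onset_times)), , drop = FALSE])
    c2 <- colMeans(pos[intersect(cells2, names(onset_times)), , drop = FALSE])
    d <- euclid(c1, c2)
    dt <- med[[g2]] - med[[g1]]
  }
  if (dt <= 0) stopf("undefined velocity: onset lag dt = %g s", dt)
  v <- d / dt
  if (!is.finite(v)) stopf("undefined velocity: non-finite d/dt")
  structure(v, d_um = d, dt_s = dt, reference = reference)
}
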