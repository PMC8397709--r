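#' Parameters for a synthetic islet recording
#'
#' Bundles and validates the generator settings for one activity level.
#' The five levels mirror the in vivo taxonomy: 0 no activity, 1
#' oscillations (transients that do not advance across the islet), 2
#' partial wave, 3 full wave, 4 recurrent superwave.
#'
#' @param level Integer 0-4.
#' @param wave_velocity Wavefront speed in um/s (levels 2-4).
#' @param n_events Number of wave passes; a superwave (level 4) needs >= 2.
#' @param rise_time,decay_time Transient kinetics in s. The transient after
#'   onset follows `amplitude * (1 - exp(-t/rise)) * exp(-t/decay)`,
#'   peak-normalised so every full pass reaches `amplitude`. Defaults are
#'   GCaMP6f-like at islet-wave timescales.
#' @param amplitude,baseline Relative fluorescence units.
#' @param noise_sd Additive Gaussian noise SD per frame (same units).
#' @param poisson_noise If `TRUE`, photon shot noise replaces part of the
#'   additive model: frame values are Poisson-resampled at
#'   `photon_scale` counts per intensity unit.
#' @param photon_scale Counts per intensity unit for `poisson_noise`.
#' @param fps Frame rate, frames/s (acquisition default 3).
#' @param n_frames Frames per capture (default 400, i.e. ~133 s at 3 fps).
#' @param recruitment_radius Level 2 only: distance from the origin within
#'   which cells are recruited; defaults to 40% of the islet diameter.
#' @param oscillation_rate Level 1 only: per-cell Poisson event rate in Hz;
#'   the default gives about two transients per cell per 400-frame capture.
#' @param origin Optional length-2 origin in um (levels 2-4); by default a
#'   uniformly random point on the islet boundary.
#' @param event_start Start time in s of the (first) wave; default 10% of
#'   the capture.
#' @param seed Optional integer seed; the generator is a pure function of it.
#'
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(level,
                       wave_velocity = 50,
                       n_events = NULL,
                       rise_time = 0.5,
                       decay_time = 4,
                       amplitude = 1,
                       baseline = 1,
                       noise_sd = 0.05,
                       poisson_noise = FALSE,
                       photon_scale = 200,
                       fps = 3,
                       n_frames = 400L,
                       recruitment_radius = NULL,
                       oscillation_rate = 0.015,
                       origin = NULL,
                       event_start = NULL,
                       seed = NULL) {
  if (!is.numeric(level) || length(level) != 1L || !(level %in% 0:4)) {
    stopf("`level` must be an integer 0..4")
  }
  level <- as.integer(level)
  assert_number(fps, "fps", lower = 0, strict_lower = TRUE)
  if (!is.numeric(n_frames) || n_frames < 2) stopf("`n_frames` must be >= 2")
  n_frames <- as.integer(n_frames)
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(rise_time, "rise_time", lower = 0, strict_lower = TRUE)
  assert_number(decay_time, "decay_time", lower = 0, strict_lower = TRUE)
  assert_number(amplitude, "amplitude", lower = 0)
  if (level >= 2L) {
    if (is.null(wave_velocity) || !is.numeric(wave_velocity) ||
        length(wave_velocity) != 1L || !is.finite(wave_velocity) ||
        wave_velocity <= 0) {
      stopf("`wave_velocity` (um/s, > 0) is required for levels 2-4")
    }
  }
  if (is.null(n_events)) n_events <- if (level == 4L) 3L else 1L
  n_events <- as.integer(n_events)
  if (level == 4L && n_events < 2L) stopf("a superwave (level 4) needs n_events >= 2")
  if (n_events < 1L) stopf("`n_events` must be >= 1")
  if (!is.null(origin) && (!is.numeric(origin) || length(origin) != 2L)) {
    stopf("`origin` must be a length-2 coordinate in um")
  }
  structure(
    list(level = level, wave_velocity = wave_velocity, n_events = n_events,
         rise_time = rise_time, decay_time = decay_time,
         amplitude = amplitude, baseline = baseline, noise_sd = noise_sd,
         poisson_noise = isTRUE(poisson_noise), photon_scale = photon_scale,
         fps = fps, n_frames = n_frames,
         recruitment_radius = recruitment_radius,
         oscillation_rate = oscillation_rate,
         origin = origin, event_start = event_start, seed = seed),
    class = "sim_params")
}

# Peak-normalised single-compartment transient evaluated at times `t`
# (seconds after onset; negative times give 0).
ca_kernel <- function(t, rise_time, decay_time, amplitude = 1) {
  t_peak <- rise_time * log1p(decay_time / rise_time)
  peak <- (1 - exp(-t_peak / rise_time)) * exp(-t_peak / decay_time)
  out <- ifelse(t > 0, (1 - exp(-t / rise_time)) * exp(-t / decay_time), 0)
  amplitude * out / peak
}

# Time after onset at which the rising limb of the peak-normalised kernel
# crosses half maximum (closed form is transcendental; bisection on the
# rising limb is exact enough for any test at frame resolution).
kernel_half_max_time <- function(rise_time, decay_time) {
  t_peak <- rise_time * log1p(decay_time / rise_time)
  f <- function(t) ca_kernel(t, rise_time, decay_time) - 0.5
  stats::uniroot(f, c(1e-12, t_peak), tol = 1e-10)$root
}

#' Simulate a ground-truthed calcium recording
#'
#' Generates per-cell fluorescence traces for one activity level on a fixed
#' frame clock, together with the ground truth (true level, origin,
#' velocity, per-cell onset times and recruited cells) that lets every
#' downstream stage be scored without animal data.
#'
#' Level semantics: 0 = baseline plus noise only; 1 = independent per-cell
#' transients at Poisson times with no spatial order; 2 = one wavefront
#' recruiting only cells within `recruitment_radius` of the origin; 3 = one
#' wavefront recruiting every cell with onset equal to `event_start +
#' distance(origin, cell) / wave_velocity`; 4 = the level-3 event repeated
#' `n_events` times within the capture.
#'
#' @param geometry An [make_islet_geometry()] object.
#' @param params A [sim_params()] object (its `seed` makes the simulation a
#'   pure function of its arguments).
#' @return A list with elements `recording` (a [calcium_recording]) and
#'   `truth` (class `ground_truth`).
#' @examples
#' geom <- make_islet_geometry(20, seed = 1)
#' sim <- simulate_recording(geom, sim_params(3, noise_sd = 0, seed = 1))
#' sim$truth$level
#' @export
simulate_recording <- function(geometry, params) {
  if (!inherits(geometry, "islet_geometry")) stopf("`geometry` must be an islet_geometry")
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  n <- n_cells_of(geometry)
  nf <- params$n_frames
  t_frames <- (seq_len(nf) - 1) / params$fps
  duration <- nf / params$fps

  sim <- with_seed(params$seed, {
    onsets <- rep(list(numeric(0)), n)        # kernel start times per cell
    recruited <- list()
    origin <- NULL
    if (params$level == 1L) {
      lambda <- params$oscillation_rate * duration
      counts <- stats::rpois(n, lambda)
      if (sum(counts) == 0L) counts[sample.int(n, 1L)] <- 1L
      for (i in seq_len(n)) {
        if (counts[i] > 0L) {
          onsets[[i]] <- sort(stats::runif(counts[i], 0, duration * 0.9))
        }
      }
      recruited <- list(geometry$cell_ids[vapply(onsets, length, 1L) > 0L])
    } else if (params$level >= 2L) {
      origin <- params$origin
      if (is.null(origin)) {
        a <- stats::runif(1, 0, 2 * pi)
        origin <- geometry$islet_radius * c(cos(a), sin(a))
      }
      d <- sqrt((geometry$positions[, 1L] - origin[1L])^2 +
                (geometry$positions[, 2L] - origin[2L])^2)
      recruit_idx <- seq_len(n)
      if (params$level == 2L) {
        rr <- params$recruitment_radius %||% (0.4 * 2 * geometry$islet_radius)
        recruit_idx <- which(d <= rr)
        if (length(recruit_idx) == 0L) recruit_idx <- which.min(d)
      }
      n_ev <- if (params$level == 4L) params$n_events else 1L
      t0 <- params$event_start %||% (0.1 * duration)
      traverse <- max(d[recruit_idx]) / params$wave_velocity
      starts <- if (n_ev == 1L) t0 else {
        # spread repeats so each pass (plus its traverse) fits the capture
        seq(t0, max(t0, duration - traverse - 3 * params$decay_time),
            length.out = n_ev)
      }
      for (s in starts) {
        for (i in recruit_idx) onsets[[i]] <- c(onsets[[i]], s + d[i] / params$wave_velocity)
      }
      recruited <- rep(list(geometry$cell_ids[recruit_idx]), n_ev)
    }

    traces <- matrix(params$baseline, n, nf)
    for (i in seq_len(n)) {
      for (on in onsets[[i]]) {
        traces[i, ] <- traces[i, ] +
          ca_kernel(t_frames - on, params$rise_time, params$decay_time,
                    params$amplitude)
      }
    }
    if (params$poisson_noise) {
      sc <- params$photon_scale
      traces[] <- stats::rpois(length(traces), pmax(traces, 0) * sc) / sc
    }
    if (params$noise_sd > 0) {
      traces <- traces + stats::rnorm(length(traces), 0, params$noise_sd)
    }
    list(traces = traces, onsets = onsets, recruited = recruited, origin = origin)
  })

  rownames(sim$traces) <- as.character(geometry$cell_ids)
  rec <- calcium_recording(sim$traces, fps = params$fps, geometry = geometry)
  truth <- structure(
    list(level = params$level,
         origin = sim$origin,
         true_velocity = if (params$level >= 2L) params$wave_velocity else NA_real_,
         onsets = stats::setNames(sim$onsets, as.character(geometry$cell_ids)),
         recruited_cells = sim$recruited,
         params = params),
    class = "ground_truth")
  list(recording = rec, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> level %d, %d event(s)%s\n", x$level,
              length(x$recruited_cells),
              if (is.finite(x$true_velocity)) sprintf(", v = %.3g um/s", x$true_velocity) else ""))
  invisible(x)
}

#' Default longitudinal cohort design
#'
#' Level probabilities per group and week emulating the longitudinal
#' imaging time course: sham islets progressively lose coordinated
#' activity (almost all inactive by week 10) while operated (VSG) islets
#' shift towards full waves and superwaves by week 8. The exact per-week
#' proportions are a design choice: published categorisations are shown
#' graphically only, so these values reproduce the direction and rough
#' magnitude of the divergence rather than a printed table.
#'
#' @return A data.frame with columns `group`, `week`, `p0`..`p4`.
#' @export
default_cohort_design <- function() {
  d <- rbind(
    data.frame(group = "sham", week = 0,  p0 = 0.05, p1 = 0.15, p2 = 0.30, p3 = 0.40, p4 = 0.10),
    data.frame(group = "sham", week = 4,  p0 = 0.10, p1 = 0.25, p2 = 0.30, p3 = 0.30, p4 = 0.05),
    data.frame(group = "sham", week = 8,  p0 = 0.30, p1 = 0.30, p2 = 0.25, p3 = 0.15, p4 = 0.00),
    data.frame(group = "sham", week = 10, p0 = 0.80, p1 = 0.15, p2 = 0.05, p3 = 0.00, p4 = 0.00),
    data.frame(group = "VSG",  week = 0,  p0 = 0.05, p1 = 0.15, p2 = 0.30, p3 = 0.40, p4 = 0.10),
    data.frame(group = "VSG",  week = 4,  p0 = 0.00, p1 = 0.10, p2 = 0.20, p3 = 0.50, p4 = 0.20),
    data.frame(group = "VSG",  week = 8,  p0 = 0.00, p1 = 0.05, p2 = 0.10, p3 = 0.45, p4 = 0.40),
    data.frame(group = "VSG",  week = 10, p0 = 0.00, p1 = 0.05, p2 = 0.10, p3 = 0.40, p4 = 0.45))
  d
}

#' Simulate a longitudinal imaging cohort
#'
#' Draws a ground-truth activity level per islet and week from the design's
#' level distributions and simulates the corresponding recording. Each
#' islet keeps one geometry across weeks (the same engrafted islet is
#' re-imaged), and all per-islet seeds are derived deterministically from
#' the master seed.
#'
#' @param design A data.frame with columns `group`, `week`, `p0`..`p4`
#'   whose rows each sum to 1 (see [default_cohort_design()]).
#' @param islets_per_group Islets simulated per group (default 20).
#' @param islets_per_animal Islets attributed to each animal id.
#' @param n_cells_range Range from which each islet's cell count is drawn.
#' @param noise_sd Additive noise SD passed to every recording.
#' @param fps,n_frames Acquisition clock.
#' @param seed Master seed; reruns reproduce identical level draws and traces.
#' @param ... Further arguments forwarded to [sim_params()].
#' @return A list of class `islet_cohort` with `records` (data.frame:
#'   animal, group, week, islet, level_true, seed) and parallel lists
#'   `recordings`, `truths`, plus `geometries` indexed by islet key.
#' @export
simulate_cohort <- function(design = default_cohort_design(),
                            islets_per_group = 20L,
                            islets_per_animal = 3L,
                            n_cells_range = c(18L, 30L),
                            noise_sd = 0.05,
                            fps = 3, n_frames = 400L,
                            seed = NULL, ...) {
  req <- c("group", "week", paste0("p", 0:4))
  if (!is.data.frame(design) || !all(req %in% names(design))) {
    stopf("`design` must be a data.frame with columns %s", paste(req, collapse = ", "))
  }
  p <- as.matrix(design[, paste0("p", 0:4)])
  if (any(!is.finite(p)) || any(p < 0)) stopf("level probabilities must be finite and >= 0")
  if (any(abs(rowSums(p) - 1) > 1e-8)) stopf("level probabilities must sum to 1 per group x week")
  if (islets_per_group < 1L) stopf("`islets_per_group` must be >= 1")

  groups <- unique(design$group)
  n_islets <- length(groups) * islets_per_group
  n_rec <- nrow(design) * islets_per_group

  seeds <- derive_seeds(seed, n_islets + 2L * n_rec + n_islets)
  # layout: [geometry seeds][level-draw seeds][recording seeds][cell-count seeds]
  geom_seeds <- seeds[seq_len(n_islets)]
  draw_seeds <- seeds[n_islets + seq_len(n_rec)]
  rec_seeds <- seeds[n_islets + n_rec + seq_len(n_rec)]
  ncell_seeds <- seeds[n_islets + 2L * n_rec + seq_len(n_islets)]

  geometries <- list()
  islet_key <- character(0)
  k <- 0L
  for (g in groups) {
    for (i in seq_len(islets_per_group)) {
      k <- k + 1L
      nc <- if (is.null(ncell_seeds[[k]])) {
        round(mean(n_cells_range))
      } else {
        with_seed(ncell_seeds[[k]],
                  sample(seq(n_cells_range[1L], n_cells_range[2L]), 1L))
      }
      key <- sprintf("%s_%02d", g, i)
      geometries[[key]] <- make_islet_geometry(nc, seed = geom_seeds[[k]])
      islet_key <- c(islet_key, key)
    }
  }

  records <- NULL
  recordings <- list()
  truths <- list()
  r <- 0L
  for (row in seq_len(nrow(design))) {
    g <- design$group[row]
    wk <- design$week[row]
    probs <- p[row, ]
    for (i in seq_len(islets_per_group)) {
      r <- r + 1L
      key <- sprintf("%s_%02d", g, i)
      lev <- with_seed(draw_seeds[[r]], sample(0:4, 1L, prob = probs))
      pars <- sim_params(lev, noise_sd = noise_sd, fps = fps,
                         n_frames = n_frames, seed = rec_seeds[[r]], ...)
      sim <- simulate_recording(geometries[[key]], pars)
      rec_key <- sprintf("%s_wk%g", key, wk)
      recordings[[rec_key]] <- sim$recording
      truths[[rec_key]] <- sim$truth
      records <- rbind(records, data.frame(
        animal = sprintf("%s_a%02d", g, ceiling(i / islets_per_animal)),
        group = g, week = wk, islet = key, level_true = lev,
        key = rec_key,
        seed = if (is.null(rec_seeds[[r]])) NA_integer_ else rec_seeds[[r]],
        stringsAsFactors = FALSE))
    }
  }
  structure(list(records = records, recordings = recordings, truths = truths,
                 geometries = geometries, design = design, seed = seed),
            class = "islet_cohort")
}

#' @export
print.islet_cohort <- function(x, ...) {
  cat(sprintf("<islet_cohort> %d recordings: %d islet(s) x %d week(s), groups %s\n",
              nrow(x$records), length(x$geometries),
              length(unique(x$records$week)),
              paste(unique(x$records$group), collapse = "/")))
  invisible(x)
}
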