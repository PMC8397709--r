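#' Detect activity onsets in smoothed traces
#'
#' Flags per-cell events where the trace rises more than `k_sd` robust
#' standard deviations above its baseline, and timestamps each event at
#' the linearly interpolated half-maximum crossing of its rising limb.
#' Working on the centred, scale-free statistic `(F - median) / sigma`
#' (sigma = 1.4826 * MAD) makes the detector invariant to affine intensity
#' rescaling; a constant trace has sigma 0 and no excursion, so it simply
#' yields no events.
#'
#' The noise scale of a boxcar-smoothed trace is estimated from its
#' first differences: for a centred moving average of window `w`, the lag-1
#' difference involves exactly two raw frames, so
#' `sigma_smoothed = 1.4826 * MAD(diff) * sqrt(w / 2)` recovers the
#' post-smoothing noise SD from ~n independent increments even though
#' neighbouring smoothed frames are strongly correlated.
#'
#' @param recording A smoothed [calcium_recording()] (see [smooth_traces()];
#'   a warning is emitted for raw traces).
#' @param k_sd Detection threshold in robust SD units (> 0, default 4).
#' @param min_separation Events closer than this (s) are merged (default 2 s).
#' @param min_duration_frames Supra-threshold run length required for an
#'   event (default 2 frames; suppresses single-frame noise spikes).
#' @param min_dff Minimum excursion as a fraction of the baseline
#'   (median) fluorescence, default 0.1: genuine indicator transients at
#'   islet waves are large (dF/F well above 10%), so sub-10% excursions
#'   are treated as noise regardless of the local SD. Set to 0 for traces
#'   without a meaningful positive baseline (e.g. already dF/F).
#' @return An object of class `onset_table`: a named list `onsets` of
#'   ascending per-cell onset times (s), plus the detector parameters.
#' @export
detect_onsets <- function(recording, k_sd = 4, min_separation = 2,
                          min_duration_frames = 2L, min_dff = 0.1) {
  if (!inherits(recording, "calcium_recording")) stopf("`recording` must be a calcium_recording")
  assert_number(k_sd, "k_sd", lower = 0, strict_lower = TRUE)
  assert_number(min_separation, "min_separation", lower = 0)
  if (!isTRUE(recording$smoothed)) {
    warnf("detect_onsets expects smoothed traces; consider smooth_traces() first")
  }
  nf <- n_frames(recording)
  fps <- recording$fps
  tt <- frame_times(recording)

  w <- if (isTRUE(recording$smoothed)) recording$smooth_window else 1L
  onsets <- lapply(seq_len(nrow(recording$traces)), function(i) {
    x <- recording$traces[i, ]
    centre <- stats::median(x)
    sigma <- stats::mad(diff(x)) * sqrt(w / 2)
    y <- x - centre
    thr <- max(k_sd * sigma, min_dff * max(centre, 0))
    above <- y > thr & y > 0            # strict: a flat trace never fires
    if (!any(above)) return(numeric(0))
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_duration_frames
    if (!any(keep)) return(numeric(0))
    runs <- cbind(starts[keep], ends[keep])

    # merge runs whose gap is below min_separation
    if (nrow(runs) > 1L) {
      merged <- runs[1L, , drop = FALSE]
      for (k in 2L:nrow(runs)) {
        gap_s <- (runs[k, 1L] - merged[nrow(merged), 2L]) / fps
        if (gap_s < min_separation) {
          merged[nrow(merged), 2L] <- runs[k, 2L]
        } else {
          merged <- rbind(merged, runs[k, ])
        }
      }
      runs <- merged
    }

    out <- vapply(seq_len(nrow(runs)), function(k) {
      i0 <- runs[k, 1L]; i1 <- runs[k, 2L]
      pk <- i0 - 1L + which.max(y[i0:i1])
      half <- y[pk] / 2
      # walk back from the peak to the last frame below half maximum
      j <- pk
      while (j > 1L && y[j - 1L] >= half) j <- j - 1L
      if (j == 1L || y[j] == y[j - 1L]) return(tt[j])
      frac <- (half - y[j - 1L]) / (y[j] - y[j - 1L])
      tt[j - 1L] + frac / fps
    }, numeric(1))
    sort(pmax(out, 0))
  })
  names(onsets) <- recording$cell_ids
  structure(
    list(onsets = onsets, fps = fps, n_frames = nf,
         params = list(k_sd = k_sd, min_separation = min_separation,
                       min_duration_frames = min_duration_frames,
                       min_dff = min_dff)),
    class = "onset_table")
}

#' @export
print.onset_table <- function(x, ...) {
  nev <- vapply(x$onsets, length, 1L)
  cat(sprintf("<onset_table> %d cells, %d events (%d active cells)\n",
              length(nev), sum(nev), sum(nev > 0L)))
  invisible(x)
}
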