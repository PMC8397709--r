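#' Construct a calcium recording
#'
#' A cells x frames matrix of fluorescence on a fixed frame clock. Frame
#' timestamps are `t = (frame_index - 1) / fps` seconds (first frame at 0).
#'
#' @param traces Numeric matrix, cells in rows, frames in columns; row
#'   names (or `cell_ids`) identify the cells.
#' @param fps Frames per second (> 0).
#' @param cell_ids Optional cell identifiers (default: row names).
#' @param geometry Optional [make_islet_geometry()] object linking cells to
#'   positions.
#' @param metadata Optional named list of capture metadata (animal, islet,
#'   week, ...).
#' @return An object of class `calcium_recording`.
#' @export
calcium_recording <- function(traces, fps, cell_ids = NULL, geometry = NULL,
                              metadata = list()) {
  if (!is.matrix(traces) || !is.numeric(traces)) {
    stopf("`traces` must be a numeric matrix (cells x frames)")
  }
  if (any(!is.finite(traces))) stopf("traces must be finite")
  assert_number(fps, "fps", lower = 0, strict_lower = TRUE)
  ids <- cell_ids %||% rownames(traces) %||% as.character(seq_len(nrow(traces)))
  if (anyDuplicated(ids)) stopf("cell ids must be unique")
  rownames(traces) <- as.character(ids)
  structure(
    list(traces = traces, fps = fps, cell_ids = as.character(ids),
         geometry = geometry, metadata = metadata, smoothed = FALSE,
         smooth_window = NA_integer_),
    class = "calcium_recording")
}

#' @export
print.calcium_recording <- function(x, ...) {
  cat(sprintf("<calcium_recording> %d cells x %d frames @ %g fps (%.1f s)%s\n",
              nrow(x$traces), ncol(x$traces), x$fps, n_frames(x) / x$fps,
              if (isTRUE(x$smoothed)) sprintf(", smoothed (w = %d)", x$smooth_window) else ""))
  invisible(x)
}

#' @rdname calcium_recording
#' @param x A `calcium_recording`.
#' @export
n_frames <- function(x) ncol(x$traces)

#' @rdname calcium_recording
#' @export
frame_times <- function(x) (seq_len(n_frames(x)) - 1) / x$fps

#' Rolling-average smoothing of fluorescence traces
#'
#' Centred moving average whose window is a fraction of the total data
#' points per capture (default 5%). The window `w = round(fraction *
#' n_frames)` is forced odd (incremented by one when even, minimum 1) so
#' the average is centred; at the edges the window shrinks symmetrically
#' with the data, so the output has the same length as the input and a
#' constant trace is unchanged.
#'
#' @param recording A [calcium_recording()].
#' @param window_fraction Fraction of frames in the window, in (0, 1).
#' @return A smoothed `calcium_recording` (flagged as such, window stored).
#' @examples
#' r <- calcium_recording(matrix(rnorm(400), 1), fps = 3)
#' smooth_traces(r)$smooth_window  # 21 for 400 frames at 5%
#' @export
smooth_traces <- function(recording, window_fraction = 0.05) {
  if (!inherits(recording, "calcium_recording")) stopf("`recording` must be a calcium_recording")
  assert_number(window_fraction, "window_fraction", lower = 0, upper = 1, strict_lower = TRUE)
  if (window_fraction >= 1) stopf("`window_fraction` must be < 1")
  nf <- n_frames(recording)
  if (nf < 2L) stopf("smoothing needs at least 2 frames")
  w <- smoothing_window(nf, window_fraction)
  h <- (w - 1L) %/% 2L

  out <- recording
  out$traces <- boxcar_rows(recording$traces, w)
  out$smoothed <- TRUE
  out$smooth_window <- w
  out
}

# centred boxcar over matrix rows, odd window, shrinking at the edges
boxcar_rows <- function(x, w) {
  nf <- ncol(x)
  h <- (w - 1L) %/% 2L
  if (h == 0L) return(x)
  cs <- cbind(0, t(apply(x, 1L, cumsum)))        # cells x (frames + 1)
  j <- seq_len(nf)
  lo <- pmax(j - h, 1L)
  hi <- pmin(j + h, nf)
  sm <- cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]
  sm <- sweep(sm, 2L, hi - lo + 1L, "/")
  dimnames(sm) <- dimnames(x)
  sm
}

#' @rdname smooth_traces
#' @param n_frames Number of frames in the capture.
#' @export
smoothing_window <- function(n_frames, window_fraction = 0.05) {
  w <- as.integer(round(window_fraction * n_frames))
  if (w %% 2L == 0L) w <- w + 1L
  max(w, 1L)
}

#' Relative fluorescence change (dF/F0)
#'
#' Per-cell baseline-normalised traces, `(F - F0) / F0`, with `F0` the
#' lower decile of the (ideally smoothed) trace. Used by the onset
#' detector; raw mean intensities remain the reported trace unit.
#'
#' @param recording A [calcium_recording()].
#' @param f0_quantile Baseline quantile (default 0.1).
#' @return A `calcium_recording` of dF/F0 values.
#' @export
dff <- function(recording, f0_quantile = 0.1) {
  x <- recording$traces
  f0 <- apply(x, 1L, stats::quantile, probs = f0_quantile, names = FALSE)
  scale <- ifelse(abs(f0) > sqrt(.Machine$double.eps), abs(f0), 1)
  out <- recording
  out$traces <- (x - f0) / scale
  out
}

#' Write / read ROI traces as CSV
#'
#' The table layout is one row per frame: first column `time_s`, then one
#' column per cell id.
#'
#' @param recording A [calcium_recording()].
#' @param path File path.
#' @return `write_traces_csv` returns `path` invisibly; `read_traces_csv`
#'   returns a `calcium_recording`.
#' @export
write_traces_csv <- function(recording, path) {
  df <- data.frame(time_s = frame_times(recording),
                   t(recording$traces), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param fps Frame rate; when `NULL` it is inferred from the `time_s`
#'   column spacing.
#' @export
read_traces_csv <- function(path, fps = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stopf("trace CSV must have a `time_s` first column")
  if (nrow(df) < 2L) stopf("trace CSV must contain at least 2 frames")
  if (is.null(fps)) {
    dt <- diff(df$time_s)
    if (any(dt <= 0)) stopf("`time_s` must be strictly increasing")
    fps <- 1 / stats::median(dt)
  }
  traces <- t(as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE]))
  calcium_recording(traces, fps = fps)
}
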