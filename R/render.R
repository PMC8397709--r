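#' Regions of interest for trace extraction
#'
#' Circular ROIs at cell-scale resolution. Centres are micrometre
#' coordinates in the same frame as the islet geometry (origin at the
#' islet centroid); a single diameter (default 15 um, within the 10-20 um
#' cell-scale convention) may be recycled over all ROIs.
#'
#' @param centers n x 2 matrix of ROI centres (um).
#' @param diameter ROI diameter(s) in um (> 0).
#' @param ids Unique ROI identifiers (default positional).
#' @param check_count If `TRUE`, warn (never error) when the ROI count
#'   falls outside the advisory 18-40 range of study-like islets.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(centers, diameter = 15, ids = NULL, check_count = FALSE) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 2L || !is.numeric(centers)) stopf("`centers` must be an n x 2 numeric matrix")
  n <- nrow(centers)
  diameter <- rep_len(diameter, n)
  if (any(!is.finite(diameter)) || any(diameter <= 0)) stopf("diameters must be > 0")
  ids <- ids %||% rownames(centers) %||% seq_len(n)
  if (anyDuplicated(ids)) stopf("ROI ids must be unique")
  if (isTRUE(check_count) && (n < 18L || n > 40L)) {
    warnf("%d ROIs is outside the advisory 18-40 range for study-like islets", n)
  }
  rownames(centers) <- as.character(ids)
  colnames(centers) <- c("x_um", "y_um")
  structure(list(centers = centers, diameter = diameter, ids = as.character(ids)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs, diameter %.3g-%.3g um\n",
              length(x$ids), min(x$diameter), max(x$diameter)))
  invisible(x)
}

#' @rdname roi_set
#' @param geometry An [make_islet_geometry()] object whose cell positions
#'   become ROI centres.
#' @export
rois_from_geometry <- function(geometry, diameter = 15) {
  roi_set(geometry$positions, diameter = diameter, ids = geometry$cell_ids)
}

#' Render a recording as a synthetic image stack
#'
#' Draws each frame as a constant background plus one isotropic Gaussian
#' spot per cell, centred at the cell's position and scaled by that cell's
#' trace value (spot peak = trace value). The rendered stack closes the
#' loop for testing ROI extraction end to end.
#'
#' @param recording A [calcium_recording()].
#' @param geometry An [make_islet_geometry()] matching the recording's cells.
#' @param pixel_size Pixel size in um/pixel.
#' @param image_shape `c(height, width)` in pixels; when `NULL` the image
#'   is sized to contain every spot with a margin.
#' @param spot_sigma Gaussian spot SD in um; the default is a quarter of
#'   `roi_diameter` so the spot mass sits within a cell-scale ROI.
#' @param roi_diameter Nominal ROI diameter in um used to size spots and
#'   the auto image margin.
#' @param background Constant background intensity.
#' @return Numeric array `frames x height x width` with attributes
#'   `pixel_size` and `spot_sigma`. Pixel centres are at integer (0-based)
#'   coordinates; the um origin maps to the image centre.
#' @export
render_movie <- function(recording, geometry, pixel_size = 2,
                         image_shape = NULL, spot_sigma = NULL,
                         roi_diameter = 15, background = 0) {
  if (!inherits(recording, "calcium_recording")) stopf("`recording` must be a calcium_recording")
  if (!inherits(geometry, "islet_geometry")) stopf("`geometry` must be an islet_geometry")
  nf <- n_frames(recording)
  if (nf < 1L) stopf("empty recording: no frames to render")
  n <- n_cells_of(geometry)
  if (nrow(recording$traces) != n) stopf("recording and geometry disagree on cell count")
  assert_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  spot_sigma <- spot_sigma %||% (roi_diameter / 4)

  pos <- geometry$positions
  margin <- 3 * spot_sigma + roi_diameter
  if (is.null(image_shape)) {
    half <- ceiling((max(abs(pos)) + margin) / pixel_size)
    image_shape <- c(2L * half + 1L, 2L * half + 1L)
  }
  H <- as.integer(image_shape[1L]); W <- as.integer(image_shape[2L])
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  px <- pos[, 1L] / pixel_size + cx
  py <- pos[, 2L] / pixel_size + cy
  outside <- px < 0 | px > W - 1 | py < 0 | py > H - 1
  if (any(outside)) {
    stopf("cell(s) %s fall outside the %d x %d field of view",
          paste(rownames(pos)[outside], collapse = ", "), H, W)
  }

  s_px <- spot_sigma / pixel_size
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  spots <- matrix(0, H * W, n)                  # column-major: index = row + H*col
  for (i in seq_len(n)) {
    gx <- exp(-(xs - px[i])^2 / (2 * s_px^2))
    gy <- exp(-(ys - py[i])^2 / (2 * s_px^2))
    spots[, i] <- as.numeric(outer(gy, gx))
  }
  flat <- spots %*% recording$traces + background   # (H*W) x frames
  stack <- aperm(array(flat, dim = c(H, W, nf)), c(3L, 1L, 2L))
  attr(stack, "pixel_size") <- pixel_size
  attr(stack, "spot_sigma") <- spot_sigma
  stack
}

#' Write / read a multi-page TIFF image stack
#'
#' Stacks are stored one page per frame, single channel, 16-bit. Written
#' intensities are scaled by `full_scale` into `[0, 1]` (the TIFF unit
#' range) and read back on that scale; `read_stack` restores the original
#' units when the scale is supplied.
#'
#' @param stack Numeric array `frames x height x width` (e.g. from
#'   [render_movie()]).
#' @param path TIFF file path.
#' @param full_scale Intensity mapped to the top of the 16-bit range;
#'   defaults to the stack maximum.
#' @return `write_stack` returns `full_scale` invisibly.
#' @export
write_stack <- function(stack, path, full_scale = NULL) {
  if (length(dim(stack)) != 3L) stopf("`stack` must be a frames x height x width array")
  if (dim(stack)[1L] == 0L) stopf("empty stack: no frames to write")
  full_scale <- full_scale %||% max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[1L]), function(f) {
    pmin(pmax(stack[f, , ] / full_scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(full_scale)
}

#' @rdname write_stack
#' @param full_scale_read Scale to multiply intensities back to original
#'   units on read (default 1: values stay in `[0, 1]`).
#' @return `read_stack` returns a `frames x height x width` array with
#'   attributes `pages` and `bits_per_sample`.
#' @export
read_stack <- function(path, full_scale_read = 1) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stopf("not a readable TIFF: %s (%s)", path, conditionMessage(e)))
  if (is.matrix(pages)) pages <- list(pages)
  if (length(pages) == 0L) stopf("format error: TIFF has zero pages: %s", path)
  ch <- vapply(pages, function(p) if (length(dim(p)) == 3L) dim(p)[3L] else 1L, 1L)
  if (any(ch != 1L)) {
    stopf("format error: expected a single-channel stack, found %d channels", max(ch))
  }
  H <- nrow(pages[[1L]]); W <- ncol(pages[[1L]])
  if (any(vapply(pages, nrow, 1L) != H) || any(vapply(pages, ncol, 1L) != W)) {
    stopf("format error: pages have inconsistent dimensions")
  }
  stack <- array(0, dim = c(length(pages), H, W))
  for (f in seq_along(pages)) stack[f, , ] <- pages[[f]] * full_scale_read
  attr(stack, "pages") <- length(pages)
  attr(stack, "bits_per_sample") <- attr(pages[[1L]], "bits.per.sample") %||% NA_integer_
  stack
}

#' Extract mean-intensity ROI traces from an image stack
#'
#' The trace of each ROI is the mean pixel intensity over the ROI's disc
#' (pixels whose integer-coordinate centre lies within `diameter/2` of the
#' ROI centre) in every frame. Output rows follow the ROI id order.
#'
#' @param stack Array `frames x height x width` ([read_stack()] or
#'   [render_movie()] output).
#' @param rois A [roi_set()] with centres in um.
#' @param fps Frame rate of the recording.
#' @param pixel_size um per pixel; defaults to the stack's `pixel_size`
#'   attribute. The um origin is taken at the image centre, matching
#'   [render_movie()].
#' @return A [calcium_recording()].
#' @export
extract_roi_traces <- function(stack, rois, fps, pixel_size = NULL) {
  if (length(dim(stack)) != 3L) stopf("`stack` must be a frames x height x width array")
  if (!inherits(rois, "roi_set")) stopf("`rois` must be a roi_set")
  assert_number(fps, "fps", lower = 0, strict_lower = TRUE)
  pixel_size <- pixel_size %||% attr(stack, "pixel_size")
  if (is.null(pixel_size)) stopf("`pixel_size` is required when the stack carries none")

  nf <- dim(stack)[1L]; H <- dim(stack)[2L]; W <- dim(stack)[3L]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  px <- rois$centers[, 1L] / pixel_size + cx
  py <- rois$centers[, 2L] / pixel_size + cy
  r_px <- (rois$diameter / 2) / pixel_size
  out_of_bounds <- px - r_px < 0 | px + r_px > W - 1 | py - r_px < 0 | py + r_px > H - 1
  if (any(out_of_bounds)) {
    stopf("ROI(s) %s extend outside the %d x %d image",
          paste(rois$ids[out_of_bounds], collapse = ", "), H, W)
  }

  xs <- 0:(W - 1); ys <- 0:(H - 1)
  n <- length(rois$ids)
  masks <- matrix(0, H * W, n)
  for (i in seq_len(n)) {
    d2 <- outer((ys - py[i])^2, (xs - px[i])^2, "+")
    m <- d2 <= r_px[i]^2
    if (!any(m)) {  # ROI smaller than a pixel: use the nearest pixel centre
      m[which.min(d2)] <- TRUE
    }
    masks[, i] <- as.numeric(m) / sum(m)
  }
  flat <- matrix(aperm(stack, c(2L, 3L, 1L)), H * W, nf)   # (H*W) x frames
  traces <- t(crossprod(flat, masks))                      # n x frames
  rownames(traces) <- rois$ids
  calcium_recording(traces, fps = fps)
}
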