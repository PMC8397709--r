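#' Pairwise Pearson correlation over an analysis window
#'
#' Correlates every unordered cell pair over exactly `window_len`
#' consecutive frames (default 100, the connectivity analysis window).
#' The diagonal (autocorrelation) is masked and never consumed by any
#' summary. Zero-variance traces yield flagged `NA` correlations rather
#' than silent zeros.
#'
#' @param recording A (smoothed) [calcium_recording()] with >= 2 cells.
#' @param window_start First frame of the window (1-based, default 1).
#' @param window_len Window length in frames (default 100).
#' @return An object of class `correlation_matrix`: list with the
#'   symmetric matrix `r` (diagonal `NA`), the window, and the ids of any
#'   `undefined_cells` (zero variance).
#' @export
pairwise_pearson <- function(recording, window_start = 1L, window_len = 100L) {
  if (!inherits(recording, "calcium_recording")) stopf("`recording` must be a calcium_recording")
  n <- nrow(recording$traces)
  if (n < 2L) stopf("need at least 2 cells")
  nf <- n_frames(recording)
  window_start <- as.integer(window_start)
  window_len <- as.integer(window_len)
  if (window_len < 2L) stopf("`window_len` must be >= 2 frames")
  if (window_start < 1L || window_start + window_len - 1L > nf) {
    stopf("window [%d, %d] does not fit in %d frames",
          window_start, window_start + window_len - 1L, nf)
  }
  X <- t(recording$traces[, window_start:(window_start + window_len - 1L), drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  undefined <- recording$cell_ids[sds == 0]
  r <- suppressWarnings(stats::cor(X))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- NA_real_
  dimnames(r) <- list(recording$cell_ids, recording$cell_ids)
  structure(list(r = r, window_start = window_start, window_len = window_len,
                 undefined_cells = undefined),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d cells, window frames %d-%d%s\n",
              nrow(x$r), x$window_start, x$window_start + x$window_len - 1L,
              if (length(x$undefined_cells)) sprintf(", %d undefined", length(x$undefined_cells)) else ""))
  invisible(x)
}

#' @export
as.matrix.correlation_matrix <- function(x, ...) x$r

#' Determine significantly connected cell pairs
#'
#' Two modes. `"permutation"` (default) builds a per-pair null by randomly
#' circularly shifting one trace of the pair; a pair is connected when its
#' exact permutation p-value `(1 + #{null >= observed}) / (n_shuffles + 1)`
#' is at most `alpha` and its correlation is positive. When the raw
#' (pre-smoothing) recording is supplied, each null draw shifts the raw
#' trace over the full capture and re-applies the rolling average before
#' windowing: the smoothing seam and edge effects are then identical
#' between null and observed traces, which keeps the test exactly
#' calibrated on smoothed data (for independent white-noise traces a
#' circular shift of the raw frames is again white noise). Without the raw
#' recording the smoothed window itself is shifted, which is slightly
#' anticonservative because the wrap discontinuity whitens the null.
#' `"threshold"` simply connects pairs with `R >= threshold_R` (the lowest
#' drawn map bin starts at R = 0.1).
#'
#' @param corr A [pairwise_pearson()] result.
#' @param recording The same recording the correlations came from (the
#'   permutation null re-uses its window).
#' @param method `"permutation"` or `"threshold"`.
#' @param n_shuffles Circular shifts for the null (>= 100).
#' @param alpha One-sided significance level (default 0.05).
#' @param threshold_R Threshold for `method = "threshold"`.
#' @param p_adjust Optional multiple-testing correction across pairs
#'   (a `stats::p.adjust` method, e.g. `"BH"`); default none.
#' @param raw_recording Optional raw (unsmoothed) recording backing
#'   `recording`; enables the exactly calibrated shift-then-smooth null.
#' @param seed Optional seed; a fixed seed reproduces the adjacency.
#' @return An object of class `connectivity_result`: adjacency matrix,
#'   per-pair p-values (permutation mode), percentages of connected pairs
#'   and of connected cells, `mean_positive_r`, per-cell degree, and the
#'   colour bin of every pair.
#' @export
significant_pairs <- function(corr, recording, method = c("permutation", "threshold"),
                              n_shuffles = 1000L, alpha = 0.05,
                              threshold_R = 0.25, p_adjust = NULL,
                              raw_recording = NULL, seed = NULL) {
  method <- match.arg(method)
  if (!inherits(corr, "correlation_matrix")) stopf("`corr` must come from pairwise_pearson()")
  r <- corr$r
  n <- nrow(r)
  pmat <- NULL

  if (method == "threshold") {
    adj <- !is.na(r) & r >= threshold_R
  } else {
    if (n_shuffles < 100L) stopf("permutation needs n_shuffles >= 100 (unstable quantile below that)")
    if (!inherits(recording, "calcium_recording")) stopf("`recording` must be a calcium_recording")
    if (n_frames(recording) < corr$window_start + corr$window_len - 1L ||
        !identical(recording$cell_ids, rownames(r))) {
      stopf("`recording` does not match the correlation matrix window/cells")
    }
    idx <- corr$window_start:(corr$window_start + corr$window_len - 1L)
    X <- t(recording$traces[, idx, drop = FALSE])
    f <- nrow(X)
    raw <- NULL
    if (!is.null(raw_recording)) {
      if (!inherits(raw_recording, "calcium_recording") ||
          n_frames(raw_recording) != n_frames(recording) ||
          !identical(raw_recording$cell_ids, recording$cell_ids)) {
        stopf("`raw_recording` does not match `recording`")
      }
      raw <- t(raw_recording$traces)               # full capture, frames x cells
    }
    w <- if (isTRUE(recording$smoothed)) recording$smooth_window else 1L
    nf_full <- if (is.null(raw)) f else nrow(raw)
    if (!is.null(raw)) {
      # smoothed value at frame t is (cumsum[hi] - cumsum[lo - 1]) / count;
      # only the window's frames are ever consumed, so smooth just those
      h <- (w - 1L) %/% 2L
      lo <- pmax(idx - h, 1L)
      hi <- pmin(idx + h, nf_full)
      cnt <- hi - lo + 1L
    }
    exceed <- matrix(0L, n, n)
    with_seed(seed, {
      for (b in seq_len(n_shuffles)) {
        sh <- sample.int(nf_full - 1L, n, replace = TRUE)
        if (is.null(raw)) {
          Xs <- X
          for (j in seq_len(n)) {
            s <- sh[j]
            Xs[, j] <- X[c((s + 1L):f, 1L:s), j]
          }
        } else {
          Rs <- raw
          for (j in seq_len(n)) {
            s <- sh[j]
            Rs[, j] <- raw[c((s + 1L):nf_full, 1L:s), j]
          }
          cs <- rbind(0, apply(Rs, 2L, cumsum))
          Xs <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / cnt
        }
        rb <- suppressWarnings(stats::cor(X, Xs))
        exceed <- exceed + (!is.na(rb) & !is.na(r) & rb >= r)
      }
    })
    pmat <- (1 + exceed) / (n_shuffles + 1)
    # one test per unordered pair: keep the upper-triangle orientation
    # (i, shifted j) and mirror it, preserving the exact calibration
    # P(p <= alpha) = floor(alpha * (B + 1)) / (B + 1) under the null
    pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
    pmat[is.na(r)] <- NA_real_
    if (!is.null(p_adjust)) {
      up <- upper.tri(pmat)
      pmat[up] <- stats::p.adjust(pmat[up], method = p_adjust)
      pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
    }
    adj <- !is.na(pmat) & pmat <= alpha & !is.na(r) & r > 0
  }
  diag(adj) <- FALSE
  dimnames(adj) <- dimnames(r)

  valid <- !is.na(r)
  n_valid_pairs <- sum(valid[upper.tri(valid)])
  n_sig_pairs <- sum(adj[upper.tri(adj)])
  degree <- rowSums(adj)
  defined_cell <- !(rownames(r) %in% corr$undefined_cells)
  pct_pairs <- if (n_valid_pairs > 0L) 100 * n_sig_pairs / n_valid_pairs else NA_real_
  pct_cells <- if (any(defined_cell)) 100 * sum(degree > 0 & defined_cell) / sum(defined_cell) else NA_real_

  structure(
    list(adjacency = adj, p = pmat, r = r,
         pct_connected_pairs = pct_pairs,
         pct_connected_cells = pct_cells,
         mean_positive_r = mean_positive_r(corr),
         degree = degree,
         bins = bin_matrix(r),
         method = method,
         params = list(n_shuffles = if (method == "permutation") n_shuffles else NA_integer_,
                       alpha = alpha, threshold_R = threshold_R,
                       p_adjust = p_adjust, seed = seed,
                       window_start = corr$window_start,
                       window_len = corr$window_len)),
    class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("<connectivity_result> %s: %.1f%% pairs, %.1f%% cells connected, mean positive R = %s\n",
              x$method, x$pct_connected_pairs, x$pct_connected_cells,
              if (is.na(x$mean_positive_r)) "undefined" else sprintf("%.3f", x$mean_positive_r)))
  invisible(x)
}

#' Mean of the positive pairwise correlations
#'
#' Arithmetic mean over the strictly positive off-diagonal correlations
#' (the autocorrelation is never included). Returns `NA` with attribute
#' `undefined = TRUE` when no positive correlation exists, so the value
#' can be excluded from cohort averages rather than silently propagated.
#'
#' @param corr A [pairwise_pearson()] result or a square correlation matrix.
#' @return Mean positive R in `(0, 1]`, or flagged `NA`.
#' @export
mean_positive_r <- function(corr) {
  r <- if (inherits(corr, "correlation_matrix")) corr$r else as.matrix(corr)
  if (length(r) == 0L) stopf("empty correlation matrix")
  if (nrow(r) != ncol(r)) stopf("correlation matrix must be square")
  off <- r[upper.tri(r)]
  pos <- off[!is.na(off) & off > 0]
  if (length(pos) == 0L) return(structure(NA_real_, undefined = TRUE))
  mean(pos)
}

#' Colour bin of a correlation value
#'
#' Map legend bins: `none` below 0.1 (and all negative R), `blue`
#' 0.1-0.25, `green` 0.26-0.5, `yellow` 0.51-0.75, `red` 0.76-1.0. The
#' printed endpoints are honoured exactly; values between printed
#' endpoints (e.g. 0.255) fall into the upper bin by half-open
#' continuation.
#'
#' @param R Numeric vector of correlations in `[-1, 1]`.
#' @return A factor with levels none/blue/green/yellow/red.
#' @examples
#' bin_correlation(c(0.05, 0.25, 0.26, 0.6, 1.0))
#' @export
bin_correlation <- function(R) {
  if (any(abs(R) > 1, na.rm = TRUE)) stopf("|R| > 1 is not a correlation")
  levs <- c("none", "blue", "green", "yellow", "red")
  out <- cut(R, breaks = c(-1, 0.1, 0.255, 0.505, 0.755, 1),
             labels = levs, right = FALSE, include.lowest = TRUE)
  out[!is.na(R) & R == 1] <- "red"
  out
}

bin_matrix <- function(r) {
  b <- bin_correlation(as.numeric(r))
  m <- matrix(as.character(b), nrow(r), ncol(r), dimnames = dimnames(r))
  m
}

#' Cartesian connectivity map specification
#'
#' Builds a drawable specification of the islet connectivity map: one dot
#' per cell at its x-y position, one line segment per significantly
#' connected pair coloured by its correlation bin, and hub dots marking
#' the cells with the highest number of significant connections.
#'
#' @param geometry An [make_islet_geometry()] covering every correlated cell.
#' @param corr A [pairwise_pearson()] result.
#' @param result A [significant_pairs()] result (its adjacency draws the
#'   segments).
#' @return An object of class `connectivity_map`: list with data.frames
#'   `points` (id, x, y, degree, hub) and `segments` (from, to, R, bin).
#'   Serialise with [write_map_json()]; draw with `plot()`.
#' @export
connectivity_map <- function(geometry, corr, result) {
  pos <- positions_of(geometry)
  r <- if (inherits(corr, "correlation_matrix")) corr$r else as.matrix(corr)
  adj <- result$adjacency
  if (!all(rownames(r) %in% rownames(pos))) {
    stopf("geometry does not cover every correlated cell")
  }
  if (!identical(dimnames(adj), dimnames(r))) stopf("adjacency and correlation ids disagree")

  degree <- rowSums(adj)
  hub <- degree > 0 & degree == max(degree)
  points <- data.frame(id = rownames(r),
                       x_um = pos[rownames(r), 1L],
                       y_um = pos[rownames(r), 2L],
                       degree = as.integer(degree),
                       hub = hub, row.names = NULL)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  segments <- if (nrow(idx) == 0L) {
    data.frame(from = character(0), to = character(0),
               R = numeric(0), bin = character(0))
  } else {
    data.frame(from = rownames(r)[idx[, 1L]],
               to = rownames(r)[idx[, 2L]],
               R = r[idx],
               bin = as.character(bin_correlation(r[idx])),
               row.names = NULL)
  }
  structure(list(points = points, segments = segments),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> %d cells, %d segments, %d hub(s)\n",
              nrow(x$points), nrow(x$segments), sum(x$points$hub)))
  invisible(x)
}

#' @export
plot.connectivity_map <- function(x, main = "Islet connectivity", ...) {
  cols <- c(none = "grey80", blue = "#3B6FB6", green = "#3FA34D",
            yellow = "#E8B90C", red = "#C0392B")
  graphics::plot(x$points$x_um, x$points$y_um, type = "n", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", main = main, ...)
  if (nrow(x$segments) > 0L) {
    from <- match(x$segments$from, x$points$id)
    to <- match(x$segments$to, x$points$id)
    graphics::segments(x$points$x_um[from], x$points$y_um[from],
                       x$points$x_um[to], x$points$y_um[to],
                       col = cols[x$segments$bin], lwd = 1.5)
  }
  graphics::points(x$points$x_um, x$points$y_um, pch = 19,
                   col = ifelse(x$points$hub, "red", "grey30"),
                   cex = ifelse(x$points$hub, 1.4, 0.9))
  invisible(x)
}

#' Heatmap of pairwise connectivity strength
#'
#' Correlation matrix drawn as an image with a blue-to-red ramp over
#' `[0, 1]` (negative values clamp to the bottom colour); both axes list
#' the cell pairs.
#'
#' @param x A `correlation_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.correlation_matrix <- function(x, ...) {
  r <- x$r
  r[is.na(r)] <- 0
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(64)
  graphics::image(seq_len(nrow(r)), seq_len(ncol(r)), pmin(pmax(r, 0), 1),
                  zlim = c(0, 1), col = pal, xlab = "cell", ylab = "cell",
                  main = "Pairwise R", ...)
  invisible(x)
}

#' Baseline correction of a longitudinal metric
#'
#' Expresses each week's value of a per-islet metric as fold change over
#' the baseline week (the baseline week itself maps to 1 exactly). A
#' missing, undefined or zero baseline flags the whole series as excluded
#' (all `NA`, attribute `excluded = TRUE`) instead of silently propagating.
#'
#' @param values Numeric metric values.
#' @param weeks Week labels aligned with `values`.
#' @param baseline_week The week used as baseline (default 0).
#' @return Numeric vector of fold changes (same order as `values`).
#' @examples
#' baseline_correct(c(0.4, 0.6), c(0, 8))  # 1.0, 1.5
#' @export
baseline_correct <- function(values, weeks, baseline_week = 0) {
  if (length(values) != length(weeks)) stopf("`values` and `weeks` lengths differ")
  base_idx <- which(weeks == baseline_week)
  if (length(base_idx) == 0L) {
    stopf("baseline week %s absent from `weeks`", format(baseline_week))
  }
  base <- values[base_idx[1L]]
  if (!is.finite(base) || base == 0) {
    return(structure(rep(NA_real_, length(values)), excluded = TRUE))
  }
  values / base
}
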