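#' Analyse every recording of a cohort
#'
#' Runs [analyze_islet()] over a simulated (or assembled) cohort and
#' returns the per-islet record table augmented with the classified level,
#' median wavefront velocity and, optionally, connectivity metrics, ready
#' for [summarize_levels()], [compare_groups()] and [report()].
#'
#' @param cohort An [simulate_cohort()] result.
#' @param connectivity Compute connectivity metrics per recording?
#' @param method,n_shuffles,alpha,threshold_R Connectivity settings
#'   (see [significant_pairs()]).
#' @param seed Master seed for the permutation nulls (one child seed per
#'   recording).
#' @param ... Passed to [analyze_islet()].
#' @return The cohort `records` data.frame with columns `level`,
#'   `velocity_um_s`, and (if requested) `pct_connected_pairs`,
#'   `pct_connected_cells`, `mean_positive_r`.
#' @export
analyze_cohort <- function(cohort, connectivity = TRUE,
                           method = c("permutation", "threshold"),
                           n_shuffles = 1000L, alpha = 0.05, threshold_R = 0.25,
                           seed = NULL, ...) {
  if (!inherits(cohort, "islet_cohort")) stopf("`cohort` must come from simulate_cohort()")
  method <- match.arg(method)
  rec <- cohort$records
  seeds <- derive_seeds(seed, nrow(rec))
  out <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    key <- rec$key[i]
    fit <- analyze_islet(cohort$recordings[[key]],
                         geometry = cohort$geometries[[rec$islet[i]]],
                         connectivity = connectivity,
                         method = method, n_shuffles = n_shuffles,
                         alpha = alpha, threshold_R = threshold_R,
                         seed = seeds[[i]], ...)
    out[[i]] <- summary(fit)
  }
  met <- do.call(rbind, out)
  cbind(rec, level = met$level, velocity_um_s = met$velocity_um_s,
        pct_connected_pairs = met$pct_connected_pairs,
        pct_connected_cells = met$pct_connected_cells,
        mean_positive_r = met$mean_positive_r)
}

#' Restrict a cohort to a subset of its recordings
#'
#' @param cohort An [simulate_cohort()] result.
#' @param keep Logical vector (or indices) over the rows of
#'   `cohort$records`.
#' @return The filtered `islet_cohort` (geometries are kept).
#' @export
subset_cohort <- function(cohort, keep) {
  if (!inherits(cohort, "islet_cohort")) stopf("`cohort` must come from simulate_cohort()")
  rec <- cohort$records[keep, , drop = FALSE]
  cohort$records <- rec
  cohort$recordings <- cohort$recordings[rec$key]
  cohort$truths <- cohort$truths[rec$key]
  cohort
}

#' Mean activity level and level distribution per group and week
#'
#' @param records Data.frame with columns `group`, `week` and `level`
#'   (e.g. from [analyze_cohort()]; pass `level_true` as `level` to
#'   summarise ground truth).
#' @return A data.frame with one row per observed group x week: islet
#'   count, mean level, SEM, and the count of islets at each level 0-4.
#'   Empty group x week combinations are omitted (with a warning when the
#'   full group x week grid is incomplete).
#' @examples
#' summarize_levels(data.frame(group = "sham", week = 0, level = c(0, 4)))
#' @export
summarize_levels <- function(records) {
  if (!all(c("group", "week", "level") %in% names(records))) {
    stopf("`records` needs columns group, week, level")
  }
  records <- records[is.finite(records$level), , drop = FALSE]
  if (nrow(records) == 0L) stopf("no records with a defined level")
  grid <- expand.grid(group = unique(records$group), week = unique(records$week),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    lv <- records$level[records$group == grid$group[i] & records$week == grid$week[i]]
    if (length(lv) == 0L) return(NULL)
    cnt <- tabulate(lv + 1L, 5L)
    data.frame(group = grid$group[i], week = grid$week[i], n = length(lv),
               mean_level = mean(lv),
               sem = if (length(lv) > 1L) stats::sd(lv) / sqrt(length(lv)) else 0,
               n_level0 = cnt[1L], n_level1 = cnt[2L], n_level2 = cnt[3L],
               n_level3 = cnt[4L], n_level4 = cnt[5L])
  })
  missing <- sum(vapply(rows, is.null, TRUE))
  if (missing > 0L) warnf("%d empty group x week combination(s) omitted", missing)
  out <- do.call(rbind, rows)
  out[order(out$group, out$week), , drop = FALSE]
}

#' Two-group comparison (unpaired two-sided Student's t-test)
#'
#' Plumbing for the headline group comparisons. Degenerate inputs follow
#' explicit contracts: two identical constant samples give `t = 0, p = 1`;
#' two different constant samples give `p = 0` flagged as a zero-variance
#' limit.
#'
#' @param x,y Numeric samples (each n >= 2, finite values).
#' @return List with `statistic`, `df`, `p_value`, `mean_x`, `mean_y` and
#'   a `degenerate` flag.
#' @export
compare_groups <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) stopf("each sample needs n >= 2")
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("samples must be finite")
  pooled_var <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  df <- length(x) + length(y) - 2L
  if (pooled_var == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, df = df, p_value = 1,
                  mean_x = mean(x), mean_y = mean(y), degenerate = TRUE))
    }
    warnf("zero pooled variance with unequal means: p-value reported as the 0 limit")
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, df = df, p_value = 0,
                mean_x = mean(x), mean_y = mean(y), degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_x = mean(x), mean_y = mean(y),
       degenerate = FALSE)
}

#' Cohort report: time-course tables, figures, and a machine-readable JSON
#'
#' Writes the level time course, the connectivity metric time courses (raw
#' and week-0 baseline-corrected per islet), per-week group comparisons,
#' and a JSON file containing every reported number together with its
#' analysis provenance. Reruns on identical inputs produce byte-identical
#' JSON. Missing sections (e.g. no connectivity columns) are reported as
#' explicit "no data" entries rather than dropped silently.
#'
#' @param records Data.frame from [analyze_cohort()] (columns `group`,
#'   `week`, `islet`, `level`, optionally connectivity metrics).
#' @param output_dir Directory to write into (created if needed).
#' @param baseline_week Week used for baseline correction (default 0).
#' @param provenance Optional named list recorded verbatim in the JSON.
#' @return Invisibly, the list written to `report.json`.
#' @export
report <- function(records, output_dir, baseline_week = 0, provenance = list()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir)) stopf("cannot create output directory %s", output_dir)

  empty <- is.null(records) || nrow(records) == 0L
  rep_list <- list(provenance = provenance, baseline_week = baseline_week)

  if (empty) {
    rep_list$levels <- "no data"
    rep_list$connectivity <- "no data"
    rep_list$comparisons <- "no data"
  } else {
    lev <- summarize_levels(records)
    utils::write.csv(lev, file.path(output_dir, "level_timecourse.csv"),
                     row.names = FALSE)
    rep_list$levels <- lev

    metrics <- intersect(c("pct_connected_pairs", "pct_connected_cells",
                           "mean_positive_r"), names(records))
    metrics <- metrics[vapply(metrics, function(m) any(is.finite(records[[m]])), TRUE)]
    if (length(metrics) == 0L) {
      rep_list$connectivity <- "no data"
    } else {
      conn <- aggregate_metrics(records, metrics)
      bc <- baseline_corrected_records(records, metrics, baseline_week)
      conn_bc <- if (nrow(bc) > 0L) {
        aggregate_metrics(bc, paste0(metrics, "_bc"))
      } else "no data"
      utils::write.csv(conn, file.path(output_dir, "connectivity_timecourse.csv"),
                       row.names = FALSE)
      if (is.data.frame(conn_bc)) {
        utils::write.csv(conn_bc,
                         file.path(output_dir, "connectivity_timecourse_baseline_corrected.csv"),
                         row.names = FALSE)
      }
      rep_list$connectivity <- conn
      rep_list$connectivity_baseline_corrected <- conn_bc
    }

    rep_list$comparisons <- week_comparisons(records)
  }

  json_path <- file.path(output_dir, "report.json")
  jsonlite::write_json(rep_list, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(rep_list)
}

aggregate_metrics <- function(records, metrics) {
  grid <- unique(records[, c("group", "week")])
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- records$group == grid$group[i] & records$week == grid$week[i]
    row <- data.frame(group = grid$group[i], week = grid$week[i], n = sum(sel))
    for (m in metrics) {
      v <- records[[m]][sel]
      v <- v[is.finite(v)]
      row[[paste0("mean_", m)]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0("sem_", m)]] <- if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  out[order(out$group, out$week), , drop = FALSE]
}

baseline_corrected_records <- function(records, metrics, baseline_week) {
  if (!"islet" %in% names(records)) return(records[0, , drop = FALSE])
  out <- NULL
  for (isl in unique(records$islet)) {
    sub <- records[records$islet == isl, , drop = FALSE]
    if (!baseline_week %in% sub$week) next
    row <- sub[, c("group", "week", "islet"), drop = FALSE]
    keep <- FALSE
    for (m in metrics) {
      bc <- baseline_correct(sub[[m]], sub$week, baseline_week)
      row[[paste0(m, "_bc")]] <- as.numeric(bc)
      if (!isTRUE(attr(bc, "excluded"))) keep <- TRUE
    }
    if (keep) out <- rbind(out, row)
  }
  out %||% records[0, , drop = FALSE]
}

week_comparisons <- function(records) {
  groups <- unique(records$group)
  if (length(groups) != 2L || !"level" %in% names(records)) return("no data")
  rows <- lapply(sort(unique(records$week)), function(wk) {
    a <- records$level[records$group == groups[1L] & records$week == wk]
    b <- records$level[records$group == groups[2L] & records$week == wk]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    cg <- compare_groups(a, b)
    data.frame(week = wk, group_a = groups[1L], group_b = groups[2L],
               mean_a = cg$mean_x, mean_b = cg$mean_y,
               t = cg$statistic, p_value = cg$p_value)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) "no data" else out
}
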