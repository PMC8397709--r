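test_that("level summaries report mean, SEM and the level distribution", {
  rec <- data.frame(group = rep("sham", 4), week = 0, level = c(3, 3, 3, 3))
  s <- summarize_levels(rec)
  expect_equal(s$mean_level, 3)
  expect_equal(s$sem, 0)
  rec2 <- data.frame(group = "VSG", week = 8, level = c(0, 4))
  s2 <- summarize_levels(rec2)
  expect_equal(s2$mean_level, 2)
  expect_equal(s2$n_level0, 1)
  expect_equal(s2$n_level4, 1)
  expect_equal(s2$n_level0 + s2$n_level1 + s2$n_level2 + s2$n_level3 + s2$n_level4,
               s2$n)
})

test_that("group comparison follows the Student's t contract", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  jit <- c(0, 0, 0, 1e-9)
  res <- compare_groups(jit, c(4, 4, 4, 4 + 1e-9))
  expect_lt(res$p_value, 0.001)

  # independent textbook-formula oracle on a 5 + 5 toy sample
  x <- c(1.1, 2.3, 0.7, 1.9, 1.4)
  y <- c(2.8, 3.1, 2.2, 3.6, 2.9)
  sp2 <- ((5 - 1) * var(x) + (5 - 1) * var(y)) / (5 + 5 - 2)
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_manual <- 2 * stats::pt(-abs(t_manual), df = 8)
  res2 <- compare_groups(x, y)
  expect_lt(abs(res2$statistic - t_manual), 1e-10)
  expect_lt(abs(res2$p_value - p_manual), 1e-10)

  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
  expect_warning(z <- compare_groups(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_equal(z$p_value, 0)
})

test_that("reports handle empty record sets explicitly and succeed", {
  dir <- withr::local_tempdir()
  out <- report(data.frame(), dir)
  expect_identical(out$levels, "no data")
  expect_true(file.exists(file.path(dir, "report.json")))
})

test_that("a 2-group x 3-week cohort reports six distribution rows", {
  rec <- expand.grid(group = c("sham", "VSG"), week = c(0, 4, 8),
                     islet = 1:3, stringsAsFactors = FALSE)
  set.seed(2)
  rec$level <- sample(0:4, nrow(rec), replace = TRUE)
  rec$pct_connected_pairs <- runif(nrow(rec), 10, 80)
  dir <- withr::local_tempdir()
  out <- report(rec, dir)
  expect_equal(nrow(out$levels), 6)
  expect_true(file.exists(file.path(dir, "level_timecourse.csv")))
  expect_true(file.exists(file.path(dir, "connectivity_timecourse.csv")))
})

test_that("report JSON is byte-identical across reruns and round-trips", {
  rec <- data.frame(group = rep(c("sham", "VSG"), each = 4),
                    week = rep(c(0, 8), 4), islet = rep(1:4, each = 2),
                    level = c(3, 2, 1, 0, 3, 4, 2, 3),
                    pct_connected_pairs = c(40, 20, 35, 5, 42, 51, 30, 44))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  report(rec, d1, provenance = list(seed = 1))
  report(rec, d2, provenance = list(seed = 1))
  j1 <- readBin(file.path(d1, "report.json"), "raw", file.size(file.path(d1, "report.json")))
  j2 <- readBin(file.path(d2, "report.json"), "raw", file.size(file.path(d2, "report.json")))
  expect_identical(j1, j2)
  parsed <- jsonlite::read_json(file.path(d1, "report.json"), simplifyVector = TRUE)
  expect_equal(parsed$provenance$seed, 1)
  expect_equal(parsed$baseline_week, 0)
})

test_that("baseline-corrected week-0 entries equal 1 wherever defined", {
  rec <- data.frame(group = "VSG", week = rep(c(0, 4, 8), 2),
                    islet = rep(c("i1", "i2"), each = 3),
                    level = 3,
                    pct_connected_pairs = c(40, 44, 60, 20, 10, 30))
  dir <- withr::local_tempdir()
  out <- report(rec, dir)
  bc <- out$connectivity_baseline_corrected
  wk0 <- bc$mean_pct_connected_pairs_bc[bc$week == 0]
  expect_true(all(wk0 == 1))
})

test_that("cohort YAML configs load into a simulate-ready design", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "baseline_week: 0",
    "islets_per_group: 3",
    "design:",
    "  - {group: sham, week: 0, p0: 0.0, p1: 0.0, p2: 0.5, p3: 0.5, p4: 0.0}",
    "  - {group: sham, week: 10, p0: 1.0, p1: 0.0, p2: 0.0, p3: 0.0, p4: 0.0}"),
    cfg_path)
  cfg <- read_cohort_config(cfg_path)
  expect_equal(nrow(cfg$design), 2)
  coh <- simulate_cohort(cfg$design, islets_per_group = cfg$islets_per_group,
                         n_frames = 40, seed = 1)
  expect_equal(nrow(coh$records), 6)
  expect_true(all(coh$records$level_true[coh$records$week == 10] == 0))
})

test_that("cohort analysis carries provenance columns end to end", {
  des <- data.frame(group = c("sham", "VSG"), week = 8,
                    p0 = c(1, 0), p1 = 0, p2 = 0, p3 = c(0, 1), p4 = 0)
  coh <- simulate_cohort(des, islets_per_group = 2, seed = 9)
  met <- analyze_cohort(coh, connectivity = FALSE)
  expect_true(all(c("level", "velocity_um_s", "group", "week", "islet") %in% names(met)))
  expect_true(all(met$level[met$group == "VSG"] >= met$level[met$group == "sham"]))
})
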