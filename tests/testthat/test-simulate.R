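test_that("parameter validation enforces the level contracts", {
  expect_error(sim_params(5), "level")
  expect_error(sim_params(3, wave_velocity = NULL), "wave_velocity")
  expect_error(sim_params(3, wave_velocity = -2), "wave_velocity")
  expect_error(sim_params(4, n_events = 1), "n_events")
  expect_error(sim_params(0, n_frames = 1), "n_frames")
  expect_error(sim_params(0, noise_sd = -0.1), "noise_sd")
  p <- sim_params(4)
  expect_gte(p$n_events, 2L)
})

test_that("a noiseless inactive islet stays at baseline", {
  sim <- quick_sim(0, seed = 1, noise_sd = 0, baseline = 1.5)
  expect_true(all(sim$recording$traces == 1.5))
  expect_equal(sim$truth$level, 0L)
})

test_that("simulation is bit-identical under a fixed seed", {
  g <- fixture_geometry(12, seed = 2)
  a <- simulate_recording(g, sim_params(3, seed = 9))
  b <- simulate_recording(g, sim_params(3, seed = 9))
  expect_identical(a$recording$traces, b$recording$traces)
  expect_identical(a$truth$onsets, b$truth$onsets)
})

test_that("level-3 ground-truth onsets are start + distance/velocity", {
  g <- fixture_geometry(15, seed = 4)
  v <- 40
  sim <- simulate_recording(g, sim_params(3, wave_velocity = v, noise_sd = 0, seed = 3))
  d <- sqrt((g$positions[, 1] - sim$truth$origin[1])^2 +
            (g$positions[, 2] - sim$truth$origin[2])^2)
  on <- vapply(sim$truth$onsets, `[`, numeric(1), 1)
  start <- min(on) - d[which.min(on)] / v
  expect_equal(unname(on), unname(start + d / v), tolerance = 1e-10)
  # ordering invariant: onset strictly increases with distance from origin
  expect_identical(order(on), order(d))
})

test_that("noiseless full waves give every cell the same peak amplitude", {
  sim <- quick_sim(3, seed = 6, noise_sd = 0, amplitude = 0.8, baseline = 1)
  peaks <- apply(sim$recording$traces, 1, max) - 1
  # every cell reaches the same amplitude up to frame-sampling jitter
  expect_equal(unname(peaks), rep(0.8, nrow(sim$recording$traces)), tolerance = 0.02)
  expect_lt(diff(range(peaks)), 0.02 * 0.8)
})

test_that("partial waves recruit exactly the cells inside the recruitment radius", {
  g <- fixture_geometry(25, seed = 5)
  sim <- simulate_recording(g, sim_params(2, noise_sd = 0, seed = 8))
  rec_ids <- sim$truth$recruited_cells[[1]]
  d <- sqrt((g$positions[, 1] - sim$truth$origin[1])^2 +
            (g$positions[, 2] - sim$truth$origin[2])^2)
  rr <- 0.4 * 2 * g$islet_radius
  expect_setequal(rec_ids, g$cell_ids[d <= rr])
  expect_lt(length(rec_ids), length(g$cell_ids))
  expect_gt(length(rec_ids), 0)
})

test_that("superwaves repeat the full wave n_events times", {
  sim <- quick_sim(4, seed = 7, noise_sd = 0, n_events = 3)
  expect_length(sim$truth$recruited_cells, 3L)
  expect_true(all(lengths(sim$truth$onsets) == 3L))
})

test_that("level-1 activity is present but carries no recruitment wavefront", {
  sim <- quick_sim(1, seed = 10)
  expect_gt(sum(lengths(sim$truth$onsets)), 0)
  expect_true(is.null(sim$truth$origin))
})

test_that("all ground-truth onsets lie inside the recording", {
  for (L in 1:4) {
    sim <- quick_sim(L, seed = 20 + L)
    on <- unlist(sim$truth$onsets)
    expect_true(all(on >= 0 & on <= 400 / 3))
  }
})

test_that("cohort level draws follow the design and reproduce under the seed", {
  des <- data.frame(group = c("sham", "sham"), week = c(0, 10),
                    p0 = c(0, 1), p1 = c(0, 0), p2 = c(0, 0),
                    p3 = c(1, 0), p4 = c(0, 0))
  coh <- simulate_cohort(des, islets_per_group = 4, n_frames = 60, seed = 5)
  expect_true(all(coh$records$level_true[coh$records$week == 10] == 0))
  expect_true(all(coh$records$level_true[coh$records$week == 0] == 3))
  coh2 <- simulate_cohort(des, islets_per_group = 4, n_frames = 60, seed = 5)
  expect_identical(coh$records$level_true, coh2$records$level_true)
  expect_identical(coh$recordings[[1]]$traces, coh2$recordings[[1]]$traces)
})

test_that("malformed cohort designs are rejected", {
  des <- default_cohort_design()
  bad <- des
  bad$p0[1] <- bad$p0[1] + 0.5
  expect_error(simulate_cohort(bad), "sum to 1")
  expect_error(simulate_cohort(des[, -2]), "columns")
})

test_that("one islet keeps one geometry across weeks", {
  des <- default_cohort_design()[c(1, 4), ]
  coh <- simulate_cohort(des, islets_per_group = 2, n_frames = 40, seed = 3)
  expect_length(coh$geometries, 2L)
  keys <- coh$records$islet[coh$records$week == 0]
  expect_setequal(keys, names(coh$geometries))
})
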