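test_that("a single constant-trace cell renders to its trace value at its pixel", {
  g <- make_islet_geometry(1, islet_radius = 10, min_spacing = 5, seed = 1)
  g$positions[] <- c(0, 0)
  rec <- calcium_recording(matrix(4, 1, 5), fps = 3)
  st <- render_movie(rec, g, pixel_size = 2, background = 0)
  expect_equal(dim(st)[1], 5L)
  for (f in 1:5) expect_equal(max(st[f, , ]), 4, tolerance = 1e-6)
})

test_that("rendering refuses empty recordings and out-of-view cells", {
  g <- make_islet_geometry(1, islet_radius = 10, min_spacing = 5, seed = 1)
  empty <- calcium_recording(matrix(numeric(0), 1, 0), fps = 3)
  expect_error(render_movie(empty, g), "empty|frames")
  g$positions[] <- c(500, 0)
  rec <- calcium_recording(matrix(1, 1, 3), fps = 3)
  expect_error(render_movie(rec, g, pixel_size = 2, image_shape = c(64, 64)), "1")
})

test_that("TIFF stacks round-trip through write_stack / read_stack", {
  sim <- quick_sim(3, seed = 4, geometry = fixture_geometry(8, seed = 4),
                   n_frames = 20)
  st <- render_movie(sim$recording, fixture_geometry(8, seed = 4), pixel_size = 3)
  path <- withr::local_tempfile(fileext = ".tif")
  scale <- write_stack(st, path)
  back <- read_stack(path, full_scale_read = scale)
  expect_equal(dim(back), dim(st))
  expect_equal(attr(back, "pages"), 20L)
  expect_lt(max(abs(back - st)), scale / 65535 * 1.01)  # 16-bit quantisation
})

test_that("multi-channel and unreadable TIFFs raise format errors", {
  rgb_path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, dim = c(8, 8, 3)), rgb_path)
  expect_error(read_stack(rgb_path), "3 channels")
  bad <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff", bad)
  expect_error(read_stack(bad), "TIFF")
  expect_error(read_stack(file.path(tempdir(), "nope.tif")), "not found")
})

test_that("ROI extraction returns the mean intensity and respects locality", {
  st <- array(3.7, dim = c(4, 41, 41))
  rois <- roi_set(rbind(c(-10, 0), c(10, 0)), diameter = 10, ids = c("a", "b"))
  rec <- extract_roi_traces(st, rois, fps = 3, pixel_size = 1)
  expect_equal(unname(rec$traces), matrix(3.7, 2, 4))
  # only pixels far from ROI "b" vary
  st2 <- st
  st2[, 21, 11] <- 1:4   # inside ROI a (x = -10 -> col 11)
  rec2 <- extract_roi_traces(st2, rois, fps = 3, pixel_size = 1)
  expect_equal(unname(rec2$traces["b", ]), rep(3.7, 4))
  expect_gt(stats::sd(rec2$traces["a", ]), 0)
})

test_that("extraction is linear in pixel intensities", {
  set.seed(5)
  st <- array(runif(3 * 31 * 31), dim = c(3, 31, 31))
  rois <- roi_set(rbind(c(0, 0)), diameter = 12, ids = "c")
  t1 <- extract_roi_traces(st, rois, fps = 3, pixel_size = 1)$traces
  t2 <- extract_roi_traces(2 * st, rois, fps = 3, pixel_size = 1)$traces
  st3 <- st
  st3[2, , ] <- st[2, , ] + st[1, , ]
  t3 <- extract_roi_traces(st3, rois, fps = 3, pixel_size = 1)$traces
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
  expect_equal(t3[1, 2], t1[1, 2] + t1[1, 1], tolerance = 1e-12)
})

test_that("ROIs outside the image are refused by name", {
  st <- array(0, dim = c(2, 21, 21))
  rois <- roi_set(rbind(c(0, 0), c(30, 0)), diameter = 10, ids = c("in", "out"))
  expect_error(extract_roi_traces(st, rois, fps = 3, pixel_size = 1), "out")
})

test_that("render -> extract recovers the input traces (R > 0.99)", {
  g <- fixture_geometry(15, seed = 6)
  sim <- simulate_recording(g, sim_params(3, noise_sd = 0, seed = 6, n_frames = 120))
  st <- render_movie(sim$recording, g, pixel_size = 2)
  rec <- extract_roi_traces(st, rois_from_geometry(g), fps = 3)
  for (i in seq_len(15)) {
    expect_gt(stats::cor(rec$traces[i, ], sim$recording$traces[i, ]), 0.99)
  }
})

test_that("ROI tables round-trip through CSV and JSON", {
  rois <- roi_set(rbind(c(-5, 3), c(8, -2)), diameter = c(12, 15), ids = c("r1", "r2"))
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_rois(rois, path)
    back <- read_rois(path)
    expect_equal(back$centers, rois$centers)
    expect_equal(back$diameter, rois$diameter)
    expect_identical(back$ids, rois$ids)
  }
})

test_that("study-range ROI-count validation warns but never errors", {
  expect_warning(roi_set(matrix(0, 2, 2), ids = c("a", "b"), check_count = TRUE),
                 "18-40")
  expect_silent(roi_set(matrix(rnorm(40), 20, 2), check_count = TRUE))
})

test_that("geometry and ground truth serialise to JSON and back", {
  g <- fixture_geometry(5, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_geometry_json(g, path)
  back <- read_geometry_json(path)
  expect_equal(back$positions, g$positions)
  expect_equal(back$islet_radius, g$islet_radius)
  sim <- quick_sim(2, seed = 9, geometry = g)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_ground_truth_json(sim$truth, p2)
  obj <- jsonlite::read_json(p2, simplifyVector = TRUE)
  expect_equal(obj$level, 2)
  expect_equal(obj$true_velocity, 50)
})
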