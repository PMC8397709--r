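test_that("identical and opposite traces hit the correlation bounds", {
  base <- sin(seq(0, 12, length.out = 120))
  tr <- rbind(a = base, b = base, c = -base)
  rec <- calcium_recording(tr, fps = 3)
  cm <- pairwise_pearson(rec, window_len = 100)
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$r["a", "c"], -1)
  expect_true(is.na(cm$r["a", "a"]))
})

test_that("the correlation matrix matches the textbook formula to 1e-12", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    f <- sample(5:30, 1)
    tr <- matrix(stats::rnorm(n * f), n, f)
    rec <- calcium_recording(tr, fps = 3)
    cm <- pairwise_pearson(rec, window_len = f)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      expect_lt(abs(cm$r[i, j] - pearson_formula(tr[i, ], tr[j, ])), 1e-12)
    }
  }
})

test_that("zero-variance traces are flagged undefined, never silent zeros", {
  tr <- rbind(a = sin(1:120), b = rep(2, 120), c = cos(1:120))
  rec <- calcium_recording(tr, fps = 3)
  cm <- pairwise_pearson(rec, window_len = 100)
  expect_identical(cm$undefined_cells, "b")
  expect_true(all(is.na(cm$r["b", ])))
  res <- significant_pairs(cm, rec, method = "threshold", threshold_R = 0.1)
  # the undefined cell is excluded from both numerator and denominator
  expect_equal(res$pct_connected_pairs, 100 * sum(res$adjacency) / 2 / 1)
  expect_false("b" %in% names(which(res$degree > 0)))
})

test_that("window bounds and cell counts are validated", {
  rec <- calcium_recording(matrix(rnorm(2 * 50), 2, 50), fps = 3)
  expect_error(pairwise_pearson(rec, window_start = 1, window_len = 100), "window")
  expect_error(pairwise_pearson(calcium_recording(matrix(1:50, 1), fps = 3),
                                window_len = 10), "2 cells")
})

test_that("a shared noiseless drive connects every pair with mean R of 1", {
  drive <- sin(seq(0, 15, length.out = 400))
  rec <- smooth_traces(calcium_recording(matrix(rep(drive, each = 12), 12, 400), fps = 3))
  cm <- pairwise_pearson(rec)
  res <- significant_pairs(cm, rec, method = "threshold")
  expect_equal(res$pct_connected_pairs, 100)
  expect_equal(as.numeric(mean_positive_r(cm)), 1)
  res_perm <- significant_pairs(cm, rec, method = "permutation",
                                n_shuffles = 199, seed = 1)
  expect_equal(res_perm$pct_connected_pairs, 100)
})

test_that("permutation adjacency is deterministic under a fixed seed", {
  set.seed(3)
  raw <- calcium_recording(matrix(rnorm(8 * 400, 1, 0.1), 8, 400), fps = 3)
  rec <- smooth_traces(raw)
  cm <- pairwise_pearson(rec)
  a <- significant_pairs(cm, rec, n_shuffles = 120, raw_recording = raw, seed = 9)
  b <- significant_pairs(cm, rec, n_shuffles = 120, raw_recording = raw, seed = 9)
  expect_identical(a$adjacency, b$adjacency)
  expect_identical(a$p, b$p)
  expect_error(significant_pairs(cm, rec, n_shuffles = 50), "100")
})

test_that("connected percentages shrink as the criterion tightens", {
  set.seed(4)
  drive <- sin(seq(0, 15, length.out = 400))
  tr <- matrix(rep(drive, each = 10), 10, 400) + matrix(rnorm(4000, 0, 0.7), 10)
  rec <- smooth_traces(calcium_recording(tr, fps = 3))
  cm <- pairwise_pearson(rec)
  pct <- vapply(c(0.1, 0.4, 0.7, 0.95), function(thr) {
    significant_pairs(cm, rec, method = "threshold", threshold_R = thr)$pct_connected_pairs
  }, numeric(1))
  expect_true(all(diff(pct) <= 0))
  p_alpha <- vapply(c(0.2, 0.05, 0.01), function(a) {
    significant_pairs(cm, rec, method = "permutation", n_shuffles = 199,
                      alpha = a, seed = 2)$pct_connected_pairs
  }, numeric(1))
  expect_true(all(diff(p_alpha) <= 0))
})

test_that("mean positive R averages only the positive off-diagonal entries", {
  r <- diag(3)
  r[upper.tri(r)] <- c(0.5, -0.2, 0.3)
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  diag(r) <- NA
  expect_equal(as.numeric(mean_positive_r(r)), 0.4)
  r_neg <- matrix(-0.5, 2, 2)
  diag(r_neg) <- NA
  out <- mean_positive_r(r_neg)
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
})

test_that("mean positive R falls as per-cell noise drowns a shared drive", {
  drive <- sin(seq(0, 15, length.out = 400))
  withr::with_seed(8, {
    means <- vapply(c(0.1, 0.5, 1.5), function(sd) {
      tr <- matrix(rep(drive, each = 10), 10, 400) + matrix(rnorm(4000, 0, sd), 10)
      cm <- pairwise_pearson(smooth_traces(calcium_recording(tr, fps = 3)))
      as.numeric(mean_positive_r(cm))
    }, numeric(1))
    expect_true(all(diff(means) < 0))
  })
})

test_that("correlation bins honour the printed legend endpoints", {
  expect_identical(as.character(bin_correlation(c(0.05, 0.25, 0.26, 0.6, 1.0))),
                   c("none", "blue", "green", "yellow", "red"))
  expect_identical(as.character(bin_correlation(c(-0.8, 0.1, 0.255, 0.505, 0.755))),
                   c("none", "blue", "green", "yellow", "red"))
  expect_identical(as.character(bin_correlation(c(0.51, 0.75, 0.76))),
                   c("yellow", "yellow", "red"))
  expect_error(bin_correlation(1.2), "correlation")
})

test_that("connectivity maps mark hubs by maximal degree", {
  g <- fixture_geometry(6, seed = 10)
  rownames(g$positions) <- as.character(1:6)
  r <- matrix(0.05, 6, 6, dimnames = list(1:6, 1:6))
  diag(r) <- NA
  cm <- structure(list(r = r, window_start = 1, window_len = 100,
                       undefined_cells = character(0)),
                  class = "correlation_matrix")
  adj <- matrix(FALSE, 6, 6, dimnames = dimnames(r))
  res <- list(adjacency = adj)
  m0 <- connectivity_map(g, cm, res)
  expect_identical(nrow(m0$segments), 0L)
  expect_false(any(m0$points$hub))

  # one significant pair at R = 0.8: a single red segment, both cells max-degree
  r2 <- r
  r2["1", "2"] <- r2["2", "1"] <- 0.8
  cm$r <- r2
  adj2 <- adj
  adj2["1", "2"] <- adj2["2", "1"] <- TRUE
  m1 <- connectivity_map(g, cm, list(adjacency = adj2))
  expect_identical(nrow(m1$segments), 1L)
  expect_identical(m1$segments$bin, "red")
  expect_setequal(m1$points$id[m1$points$hub], c("1", "2"))

  # star topology: centre cell is the unique hub (degree-count oracle)
  adj3 <- adj
  adj3["1", as.character(2:6)] <- adj3[as.character(2:6), "1"] <- TRUE
  m2 <- connectivity_map(g, cm, list(adjacency = adj3))
  deg_oracle <- colSums(adj3)
  expect_identical(m2$points$id[m2$points$hub],
                   names(which(deg_oracle == max(deg_oracle))))
  expect_identical(sum(m2$points$hub), 1L)
  path <- withr::local_tempfile(fileext = ".json")
  write_map_json(m2, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(obj$segments), 5)
})

test_that("baseline correction divides by week 0 and flags a zero baseline", {
  expect_equal(baseline_correct(c(0.4, 0.6), c(0, 8)), c(1.0, 1.5))
  out <- baseline_correct(c(0, 0.6), c(0, 8))
  expect_true(all(is.na(out)))
  expect_true(attr(out, "excluded"))
  v <- c(0.2, 0.5, 0.8)
  expect_equal(baseline_correct(3 * v, c(0, 4, 8)), baseline_correct(v, c(0, 4, 8)))
  expect_error(baseline_correct(1, 4, baseline_week = 0), "absent")
})
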