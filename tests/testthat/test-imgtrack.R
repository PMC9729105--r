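test_that("height maps recover constant and tilted interfaces within half a slice", {
  st_const <- slab_stack(h_fun = function(x, y) 7)
  hm <- compute_height_map(st_const, "ecm")
  expect_true(all(abs(hm$h - 8) <= 0.5))  # z-index 8 = depth 7 um, 1-based
  st_tilt <- slab_stack(nx = 60, h_fun = function(x, y) 5 + 0.01 * x)
  hmt <- compute_height_map(st_tilt, "ecm")
  truth <- outer((seq_len(40) - 1), (seq_len(60) - 1),
                 function(y, x) 5 + 0.01 * x) + 1
  expect_true(all(abs(hmt$h - truth) <= 0.5))
})

test_that("an empty interface channel errors", {
  st <- slab_stack()
  st$channels$ecm[] <- 0
  expect_error(compute_height_map(st, "ecm"), "no interface signal")
  expect_error(compute_height_map(st, "nope"), "not found")
})

test_that("flatten is identity at zero height and inverts a z shift in the interior", {
  st <- slab_stack(h_fun = function(x, y) 4)
  hm0 <- structure(list(h = matrix(1, 40, 40), voxel_size_um = c(1, 1, 1)),
                   class = "height_map")
  expect_equal(flatten_stack(st, hm0)$channels$ecm, st$channels$ecm)
  # shifting the slab down by 2 and flattening by 2 restores the interior
  st2 <- slab_stack(h_fun = function(x, y) 6)
  hm2 <- structure(list(h = matrix(3, 40, 40), voxel_size_um = c(1, 1, 1)),
                   class = "height_map")
  flat <- flatten_stack(st2, hm2)
  expect_equal(flat$channels$ecm[, , 1:9], st$channels$ecm[, , 1:9])
  hm_bad <- structure(list(h = matrix(1, 10, 10), voxel_size_um = c(1, 1, 1)),
                      class = "height_map")
  expect_error(flatten_stack(st, hm_bad), "shape mismatch")
})

test_that("flattening a curved sheet levels the interface onset", {
  st <- slab_stack(nx = 60, ny = 60,
                   h_fun = function(x, y) 4 + 1.5 * sin(2 * pi * x / 80))
  hm <- compute_height_map(st, "ecm")
  flat <- flatten_stack(st, hm)
  onset <- apply(flat$channels$ecm > 0.5, c(1, 2), function(v) which(v)[1])
  expect_lt(sd(onset), 1)  # interface level to within one slice
})

test_that("project_basal averages exactly and validates its range", {
  st <- slab_stack(h_fun = function(x, y) 5)
  pl <- project_basal(st, 3, 3)
  brute <- (st$channels$ecm[, , 3] + st$channels$ecm[, , 4] + st$channels$ecm[, , 5]) / 3
  expect_equal(pl$channels$ecm, brute)
  stc <- st; stc$channels$ecm[] <- 0.7
  expect_equal(unique(as.vector(project_basal(stc, 2, 3)$channels$ecm)), 0.7)
  expect_error(project_basal(st, 11, 3), "out of")
})

test_that("detect_cells finds a single blob to subpixel accuracy and ignores flat input", {
  xs <- (0:39); ys <- (0:39)
  blob <- outer(exp(-((ys - 17.3)^2) / 8), exp(-((xs - 21.6)^2) / 8))
  det <- detect_cells(blob, mode = "maxima", min_separation_um = 3)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$x_um - 21.6), 0.5)
  expect_lt(abs(det$y_um - 17.3), 0.5)
  expect_identical(nrow(detect_cells(matrix(1, 30, 30), mode = "maxima")), 0L)
  # minima mode is the mirrored problem
  det2 <- detect_cells(1 - blob, mode = "minima", min_separation_um = 3)
  expect_identical(nrow(det2), 1L)
  expect_lt(abs(det2$x_um - 21.6), 0.5)
})

test_that("min-separation pruning keeps the more prominent extremum", {
  m <- matrix(0, 30, 30)
  m[15, 10] <- 1
  m[15, 13] <- 0.6  # weaker peak 3 px away
  m[15, 25] <- 0.8
  det <- detect_cells(m, mode = "maxima", min_separation_um = 5,
                      smooth_sigma_um = 0.6)
  expect_identical(nrow(det), 2L)
  expect_true(any(abs(det$x_um - 9) < 1) && any(abs(det$x_um - 24) < 1))
})

test_that("register_frames recovers identity, injected shifts and survives dropout", {
  set.seed(42)
  p <- cbind(runif(60, 0, 120), runif(60, 0, 120))
  expect_equal(register_frames(p, p), c(0, 0), tolerance = 1e-6)
  q <- p + matrix(rep(c(4, -3), each = 60), ncol = 2)
  expect_equal(register_frames(p, q), c(4, -3), tolerance = 0.25)
  q20 <- q[sample(60, 48), ]
  expect_equal(register_frames(p, q20), c(4, -3), tolerance = 0.5)
  expect_error(register_frames(p[0, ], q), "empty position set")
})

test_that("register_frames(A, A + s) = s across shifts for small sets", {
  set.seed(7)
  p <- cbind(runif(12, 0, 60), runif(12, 0, 60))
  for (s in list(c(2, 2), c(-5, 1), c(0, -7))) {
    q <- sweep(p, 2, -s)
    expect_equal(register_frames(p, q), s, tolerance = 0.25)
  }
})

test_that("disc-mean reporter quantification matches brute force and handles borders", {
  set.seed(1)
  m <- matrix(runif(900), 30, 30)
  pos <- data.frame(cell_id = 1:2, x_um = c(10, 0), y_um = c(12, 0))
  lev <- quantify_reporter(m, pos, radius_um = 3)
  brute <- function(cx, cy) {
    acc <- c()
    for (i in 1:30) for (j in 1:30)
      if ((j - 1 - cx)^2 + (i - 1 - cy)^2 <= 9) acc <- c(acc, m[i, j])
    mean(acc)
  }
  expect_equal(lev$raw[1], brute(10, 12))
  expect_equal(lev$raw[2], brute(0, 0))  # border: in-bounds pixels only
  mc <- matrix(0.4, 20, 20)
  expect_equal(unique(quantify_reporter(mc, pos[1, ], radius_um = 3)$raw), 0.4)
  expect_error(quantify_reporter(m, pos, radius_um = 0), "radius")
})

test_that("segment_sum sums the labelled region containing each position", {
  m <- matrix(1, 10, 10)
  labels <- matrix(0L, 10, 10)
  labels[1:4, 1:5] <- 1L
  pos <- data.frame(cell_id = 1, x_um = 2, y_um = 1)
  lev <- quantify_reporter(m, pos, method = "segment_sum", labels = labels)
  expect_equal(lev$raw, 20)
})

test_that("dividing-cell normalization matches hand arithmetic on a toy table", {
  lev <- data.frame(cell_id = 1:5, raw = c(2, 4, 6, 1, 3))
  out <- normalize_by_dividing(lev, dividing_ids = c(2, 3))  # mean 5
  expect_equal(out$normalized, c(0.4, 0.8, 1.2, 0.2, 0.6))
  expect_equal(mean(out$normalized[out$cell_id %in% c(2, 3)]), 1)
  expect_error(normalize_by_dividing(lev, integer(0)), "no dividing cells")
})

test_that("high-reporter classification is a strict threshold", {
  lev <- data.frame(cell_id = 1:3, raw = 1:3, normalized = c(0.5, 1.0, 1.5))
  out <- classify_high(lev, 1.0)
  expect_identical(out$is_high, c(FALSE, FALSE, TRUE))
  expect_true(all(!classify_high(lev, 2)$is_high))
})

test_that("planted high/low reporter classes separate at the midpoint threshold", {
  set.seed(3)
  n <- 200
  truth <- rep(c(TRUE, FALSE), each = n / 2)
  raw <- ifelse(truth, rnorm(n, 3, 0.3), rnorm(n, 1, 0.3))  # ~3 sd apart
  lev <- normalize_by_dividing(data.frame(cell_id = 1:n, raw = raw),
                               dividing_ids = 1:n)
  thr <- 2 / mean(raw)
  out <- classify_high(lev, thr)
  expect_gte(mean(out$is_high == truth), 0.95)
})
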