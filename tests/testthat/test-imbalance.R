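cfg6 <- imbalance_config(radius_um = 10, max_lookback_h = 48, frame_interval_h = 6)

test_that("the neighbourhood rule is inclusive at the radius and excludes the focal", {
  ev <- data.frame(event_id = 1:3,
                   type = c("division", "delamination", "delamination"),
                   time_h = c(100, 90, 91),
                   x_um = c(0, 10, 10.1), y_um = 0,
                   cell_id = 1:3, daughter1 = c(4L, NA, NA),
                   daughter2 = c(5L, NA, NA), cause_event_id = NA)
  nb <- neighbor_events(ev, 1, cfg6)
  expect_identical(nb$event_id, 2L)  # 10.0 in, 10.1 out, focal out
  expect_error(neighbor_events(ev, 2, cfg6), "not a division")
  expect_error(neighbor_events(ev, 99, cfg6), "not found")
})

test_that("neighbour selection equals a brute-force filter on a random 50-event table", {
  set.seed(10)
  n <- 50
  ev <- data.frame(event_id = 1:n,
                   type = sample(c("division", "delamination"), n, TRUE),
                   time_h = runif(n, 0, 200),
                   x_um = runif(n, 0, 40), y_um = runif(n, 0, 40),
                   cell_id = 1:n, daughter1 = NA_integer_,
                   daughter2 = NA_integer_, cause_event_id = NA_integer_)
  ev$daughter1[ev$type == "division"] <- n + seq_len(sum(ev$type == "division"))
  ev$daughter2[ev$type == "division"] <- 2 * n + seq_len(sum(ev$type == "division"))
  cfg <- imbalance_config(radius_um = 10, max_lookback_h = 120, frame_interval_h = 12)
  focal <- ev$event_id[ev$type == "division"][3]
  k <- which(ev$event_id == focal)
  keep <- logical(n)
  for (i in seq_len(n)) {  # independent brute-force oracle
    d <- sqrt((ev$x_um[i] - ev$x_um[k])^2 + (ev$y_um[i] - ev$y_um[k])^2)
    keep[i] <- d <= 10 && ev$time_h[i] < ev$time_h[k] &&
      ev$time_h[i] > ev$time_h[k] - 120 && i != k
  }
  expect_identical(neighbor_events(ev, focal, cfg)$event_id, ev$event_id[keep])
})

test_that("the worked three-event lookback example evaluates exactly", {
  ev <- data.frame(event_id = 1:4,
                   type = c("division", "delamination", "division", "delamination"),
                   time_h = c(100, 70, 90, 95),
                   x_um = c(0, 3, 4, 2), y_um = c(0, 1, 2, 2),
                   cell_id = 1:4, daughter1 = c(10L, NA, 12L, NA),
                   daughter2 = c(11L, NA, 13L, NA), cause_event_id = NA)
  tr <- imbalance_track(ev, 1, cfg6)
  get <- function(tau) tr$imbalance[tr$lookback_h == tau]
  expect_identical(get(6), -1L)    # only the delamination at -5 h
  expect_identical(get(24), 0L)    # division at -10 h cancels it
  expect_identical(get(48), -1L)   # delamination at -30 h enters
})

test_that("no neighbours means an identically zero track", {
  ev <- data.frame(event_id = 1:2, type = c("division", "delamination"),
                   time_h = c(50, 40), x_um = c(0, 30), y_um = c(0, 30),
                   cell_id = 1:2, daughter1 = c(3L, NA), daughter2 = c(4L, NA),
                   cause_event_id = NA)
  tr <- imbalance_track(ev, 1, cfg6)
  expect_true(all(tr$imbalance == 0L))
})

test_that("the track is antisymmetric under swapping event types and ignores far events", {
  set.seed(2)
  n <- 30
  ev <- data.frame(event_id = 1:n,
                   type = c("division", sample(c("division", "delamination"), n - 1, TRUE)),
                   time_h = c(120, runif(n - 1, 0, 119)),
                   x_um = c(0, runif(n - 1, 0, 15)), y_um = c(0, runif(n - 1, 0, 15)),
                   cell_id = 1:n, daughter1 = NA_integer_, daughter2 = NA_integer_,
                   cause_event_id = NA_integer_)
  ev$daughter1[ev$type == "division"] <- 100 + seq_len(sum(ev$type == "division"))
  ev$daughter2[ev$type == "division"] <- 200 + seq_len(sum(ev$type == "division"))
  cfg <- imbalance_config(max_lookback_h = 120, frame_interval_h = 12)
  tr <- imbalance_track(ev, 1, cfg)
  swapped <- ev
  swapped$type <- ifelse(ev$type == "division", "delamination", "division")
  swapped$type[1] <- "division"  # keep the focal a division
  tr_sw <- imbalance_track(swapped, 1, cfg)
  # all neighbour signs flip (the focal row carries no sign)
  expect_identical(tr_sw$imbalance, -tr$imbalance)
  far <- rbind(ev, data.frame(event_id = 999, type = "delamination", time_h = 60,
                              x_um = 50, y_um = 50, cell_id = 999,
                              daughter1 = NA_integer_, daughter2 = NA_integer_,
                              cause_event_id = NA_integer_))
  expect_identical(imbalance_track(far, 1, cfg)$imbalance, tr$imbalance)
})

test_that("the methods sign convention mirrors the figure convention", {
  ev <- data.frame(event_id = 1:2, type = c("division", "delamination"),
                   time_h = c(50, 45), x_um = 0, y_um = 0, cell_id = 1:2,
                   daughter1 = c(3L, NA), daughter2 = c(4L, NA), cause_event_id = NA)
  a <- imbalance_track(ev, 1, imbalance_config(max_lookback_h = 24, frame_interval_h = 12))
  b <- imbalance_track(ev, 1, imbalance_config(max_lookback_h = 24, frame_interval_h = 12,
                                               sign_convention = "methods"))
  expect_identical(b$imbalance, -a$imbalance)
})

test_that("mean_imbalance matches brute-force mean/sd and validates inputs", {
  mk <- function(v) structure(list(focal_id = 1, lookback_h = c(12, 24),
                                   imbalance = v), class = "imbalance_track")
  mi <- mean_imbalance(list(mk(c(0L, -1L)), mk(c(0L, -1L))))
  expect_equal(mi$mean, c(0, -1))
  expect_equal(mi$sd, c(0, 0))
  set.seed(5)
  tracks <- lapply(1:10, function(i) mk(sample(-3:3, 2, TRUE)))
  mi2 <- mean_imbalance(tracks)
  m <- sapply(tracks, `[[`, "imbalance")
  expect_equal(mi2$mean, rowMeans(m))
  expect_equal(mi2$sd, apply(m, 1, sd))
  expect_error(mean_imbalance(list()), "no imbalance tracks")
  bad <- mk(c(0L, 1L)); bad$lookback_h <- c(6, 12)
  expect_error(mean_imbalance(list(mk(c(0L, 1L)), bad)), "mismatched")
})

test_that("a coupled simulation plateaus at -1 and excludes the focal's own birth", {
  cfg <- tissue_sim_config(field_size = c(200, 200), init_density = 2,
                           delam_rate = 0.05, coupling_prob = 1,
                           n_frames = 15, frame_interval = 12, seed = 3)
  sim <- simulate_basal_dynamics(cfg)
  mi <- mean_imbalance(imbalance_tracks_all(sim$events))
  expect_gt(mi$n_events[1], 20)
  plateau <- mean(mi$mean[mi$lookback_h >= 48 & mi$lookback_h <= 72])
  expect_equal(plateau, -1, tolerance = 0.25)
})
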