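test_that("circle IoU basics: identity, disjoint, unit-circle overlap", {
  expect_equal(circle_iou(c(0, 0, 1), c(0, 0, 1)), 1)
  expect_equal(circle_iou(c(0, 0, 1), c(2, 0, 1)), 0)
  expect_equal(circle_iou(c(0, 0, 1), c(5, 1, 2)), 0)
  expect_equal(circle_iou(c(0, 0, 1), c(1, 0, 1)), 0.2430, tolerance = 1e-3)
})

test_that("circle IoU is symmetric and rigid-motion invariant", {
  set.seed(13)
  for (i in 1:20) {
    c1 <- c(runif(2, -5, 5), runif(1, 0.5, 3))
    c2 <- c(runif(2, -5, 5), runif(1, 0.5, 3))
    v <- circle_iou(c1, c2)
    expect_equal(v, circle_iou(c2, c1))
    th <- runif(1, 0, 2 * pi); sh <- runif(2, -10, 10)
    rot <- function(p) c(cos(th) * p[1] - sin(th) * p[2] + sh[1],
                         sin(th) * p[1] + cos(th) * p[2] + sh[2], p[3])
    expect_equal(v, circle_iou(rot(c1), rot(c2)), tolerance = 1e-12)
    expect_equal(v, circle_iou_vec(c1[1], c1[2], c1[3], c2[1], c2[2], c2[3]))
  }
})

test_that("contained circle IoU is the area ratio", {
  expect_equal(circle_iou(c(0, 0, 4), c(1, 0, 2)), 4 / 16)
})

test_that("associate accepts a nearby detection under stable gates", {
  cfg <- tracker_config(roi_stable = 3, iou_stable = 0.3)
  dets <- data.frame(x = 2, y = 0, r = 5)
  expect_equal(associate(c(0, 0, 5), dets, "stable", cfg), 1L)
})

test_that("argmin-first semantics: only the distance minimizer faces the IoU gate", {
  cfg <- tracker_config(roi_stable = 4, iou_stable = 0.3)
  # nearest detection: tiny radius -> fails IoU; second-nearest would pass
  dets <- data.frame(x = c(4, 2), y = c(0, 0), r = c(5, 0.5))
  expect_true(is.na(associate(c(0, 0, 5), dets, "stable", cfg)))
  # best-feasible oracle would have chosen detection 1:
  expect_gt(circle_iou(c(0, 0, 5), c(4, 0, 5)), 0.3)
})

test_that("associate with an empty detection list returns none", {
  expect_true(is.na(associate(c(0, 0, 5), data.frame(x = numeric(0),
                                                     y = numeric(0),
                                                     r = numeric(0)),
                              "stable", tracker_config())))
})

test_that("recover_gap finds a reappearing detection and honors limits", {
  mk <- function(x) data.frame(x = x, y = rep(0, length(x)),
                               r = rep(5, length(x)))
  dbf <- list(mk(0), mk(numeric(0)), mk(numeric(0)), mk(numeric(0)), mk(1))
  rec <- recover_gap(c(0, 0, 5), dbf, t_gap = 1, config = tracker_config())
  expect_equal(rec$frame, 4)
  expect_equal(rec$index, 1L)
  # nothing within max_gap
  dbf2 <- c(list(mk(0)), rep(list(mk(numeric(0))), 12))
  expect_null(recover_gap(c(0, 0, 5), dbf2, t_gap = 1,
                          config = tracker_config()))
})

test_that("recover_gap picks the nearer candidate, ties to lower index", {
  mk <- function(x) data.frame(x = x, y = rep(0, length(x)),
                               r = rep(5, length(x)))
  dbf <- list(mk(0), mk(numeric(0)), mk(c(8, 3)))
  rec <- recover_gap(c(0, 0, 5), dbf, t_gap = 1, config = tracker_config())
  expect_equal(rec$index, 2L)
  dbf_tie <- list(mk(0), mk(numeric(0)), mk(c(3, -3)))
  rec <- recover_gap(c(0, 0, 5), dbf_tie, t_gap = 1,
                     config = tracker_config())
  expect_equal(rec$index, 1L)
})

test_that("interpolate_gap is linear in position and radius", {
  g <- interpolate_gap(c(0, 0, 10), c(10, 0, 10), 10, 15)
  expect_equal(g$frame, 11:14)
  expect_equal(g$x, c(2, 4, 6, 8))
  expect_equal(g$y, rep(0, 4))
  expect_equal(nrow(interpolate_gap(c(0, 0, 1), c(1, 0, 1), 3, 4)), 0)
  g2 <- interpolate_gap(c(0, 0, 10), c(0, 0, 12), 0, 2)
  expect_equal(g2$r, 11)
})

test_that("a 3-frame dropout is bridged with interpolated states", {
  frames <- 0:9
  x <- 2 * frames
  dets <- data.frame(frame = frames, x = x, y = 0, r = 5)
  dets <- dets[!(dets$frame %in% 4:6), ]
  ts <- track_sequence(dets, total_frames = 10)
  st <- ts$tracks[[1]]$states
  expect_equal(st$frame, 0:9)
  expect_equal(st$source[5:7], rep("interpolated", 3))
  expect_equal(st$x, 2 * (0:9), tolerance = 1e-12)
})

test_that("detections appearing after frame 0 never start tracks", {
  dets <- rbind(data.frame(frame = 0:9, x = 0, y = 0, r = 5),
                data.frame(frame = 5:9, x = 200, y = 200, r = 5))
  ts <- track_sequence(dets, total_frames = 10)
  expect_length(ts$tracks, 1)
})

test_that("out_of_range_filter partitions by length and mask", {
  dets <- rbind(data.frame(frame = 0:9, x = 10, y = 10, r = 3),
                data.frame(frame = 0:4, x = 50, y = 50, r = 3))
  ts <- track_sequence(dets, total_frames = 10)
  flt <- out_of_range_filter(ts, 10)
  expect_equal(flt$valid, 0L)
  expect_equal(flt$out_of_range, 1L)
  # full-length track drifting into a masked-out band
  mask <- matrix(TRUE, 64, 64); mask[1:12, ] <- FALSE
  dets3 <- data.frame(frame = 0:9, x = 30,
                      y = seq(30, 10, length.out = 10), r = 3)
  ts3 <- track_sequence(dets3, total_frames = 10)
  flt3 <- out_of_range_filter(ts3, 10, mask)
  expect_equal(flt3$out_of_range, 0L)
  expect_length(flt3$valid, 0)
})

test_that("conservation: first-frame detections = valid + out_of_range", {
  lay <- small_layout()
  cells <- make_cells(lay, 6, seed = 21)
  sch <- freq_schedule(data.frame(t_start = 0, t_end = 20, kind = "sweep",
                                  f_start = 15e3, f_end = 31e3))
  gt <- simulate_tracks(lay, field_proxy(lay), cells, sch, seed = 21)
  d <- corrupt_detections(gt, lay, p_miss = 0.05, p_fp = 0.3,
                          pos_sigma = 0.5, seed = 22)
  n0 <- sum(d$frame == 0)
  ts <- out_of_range_filter(track_sequence(d, total_frames = 200), 200)
  expect_equal(length(ts$valid) + length(ts$out_of_range), n0)
})

test_that("brief crossings produce no overlap event", {
  mk_states <- function(x, y, r = 3) {
    data.frame(frame = seq_along(x) - 1L, x = x, y = y, r = r,
               source = "detected")
  }
  a <- mk_states(0:20, rep(0, 21))
  b <- mk_states(20:0, rep(0, 21))
  ts <- structure(list(tracks = list(
    list(cell_id = 0L, states = a, last_frame = 20L, status = "active"),
    list(cell_id = 1L, states = b, last_frame = 20L, status = "active")),
    total_frames = 21L,
    conflicts = data.frame()), class = "track_set")
  out <- overlap_identity_check(ts, tau_overlap = 0.4, min_consecutive = 3)
  expect_equal(nrow(out$merge_events), 0)
})

test_that("a greedy-pass swap during a 5-frame overlap is corrected", {
  # true paths cross at frame 10; suffixes were swapped by the tracker
  fr <- 0:20
  ax_true <- fr; bx_true <- 20 - fr
  ax <- c(ax_true[1:12], bx_true[13:21])   # swapped after frame 11
  bx <- c(bx_true[1:12], ax_true[13:21])
  mk <- function(x) data.frame(frame = fr, x = x, y = 0, r = 3,
                               source = "detected")
  ts <- structure(list(tracks = list(
    list(cell_id = 0L, states = mk(ax), last_frame = 20L, status = "active"),
    list(cell_id = 1L, states = mk(bx), last_frame = 20L, status = "active")),
    total_frames = 21L,
    conflicts = data.frame()), class = "track_set")
  out <- overlap_identity_check(ts, tau_overlap = 0.4, min_consecutive = 3)
  expect_true("swapped" %in% out$merge_events$action)
  expect_equal(out$tracks[[1]]$states$x, ax_true)
  expect_equal(out$tracks[[2]]$states$x, bx_true)
})

test_that("fully coincident tracks are flagged merged", {
  st <- data.frame(frame = 0:9, x = 5, y = 5, r = 3, source = "detected")
  ts <- structure(list(tracks = list(
    list(cell_id = 0L, states = st, last_frame = 9L, status = "active"),
    list(cell_id = 1L, states = st, last_frame = 9L, status = "active")),
    total_frames = 10L,
    conflicts = data.frame()), class = "track_set")
  out <- overlap_identity_check(ts)
  expect_true(all(c(out$tracks[[1]]$status, out$tracks[[2]]$status)
                  == "merged"))
})
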