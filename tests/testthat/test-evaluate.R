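test_that("perfect tracking gives MOTA 1 with zero error terms", {
  gt <- data.frame(cell_id = rep(0:2, each = 10), frame = rep(0:9, 3),
                   x = rep(c(10, 50, 90), each = 10), y = 20, r = 4)
  m <- mota(gt, gt)
  expect_equal(m$mota, 1)
  expect_equal(c(m$fn, m$fp, m$id_switches), c(0L, 0L, 0L))
  expect_equal(m$n_gt, 30)
})

test_that("MOTA arithmetic: FN=2, FP=1, IDSW=1 over 100 objects is 0.96", {
  gt <- data.frame(cell_id = rep(0:9, each = 10),
                   frame = rep(0:9, times = 10),
                   x = rep(seq(10, 100, by = 10), each = 10), y = 50, r = 3)
  tr <- gt
  # two misses on cell 0 (frames 3, 4), one spurious detection, and one
  # identity switch on cell 1 from frame 5 on
  tr <- tr[!(tr$cell_id == 0 & tr$frame %in% c(3, 4)), ]
  tr$cell_id[tr$cell_id == 1 & tr$frame >= 5] <- 99L
  tr <- rbind(tr, data.frame(cell_id = 50L, frame = 7, x = 400, y = 400,
                             r = 3))
  m <- mota(gt, tr)
  expect_equal(c(m$fn, m$fp, m$id_switches), c(2L, 1L, 1L))
  expect_equal(m$mota, 1 - 4 / 100)
})

test_that("matching tolerance is each ground-truth cell's own radius", {
  gt <- data.frame(cell_id = c(0L, 1L), frame = 0L, x = c(10, 50), y = 10,
                   r = c(2, 8))
  tr <- data.frame(cell_id = c(0L, 1L), frame = 0L, x = c(14, 54), y = 10)
  m <- mota(gt, tr)                      # 4 px off: fails r=2, passes r=8
  expect_equal(m$fn, 1L)
  expect_equal(m$fp, 1L)
  m2 <- mota(gt, tr, match_tol = 5)      # global override accepts both
  expect_equal(m2$fn, 0L)
})

test_that("ground truth outside the mask is excluded from G_t and FN", {
  lay <- make_chip_layout(1, 1, 100, 20, c(256L, 256L), fov_radius = 100)
  fr <- render_frame(lay, noise_sigma = 0)
  msk <- make_fov_mask(fr, disk_radius = 15, strip_rows = 10)
  gt <- data.frame(cell_id = rep(0:1, each = 5), frame = rep(0:4, 2),
                   x = c(rep(127.5, 5), rep(127.5, 5)),
                   y = c(rep(127.5, 5), rep(3, 5)),   # cell 1 in masked band
                   r = 4)
  tr <- gt[gt$cell_id == 0, ]            # tracker never reports cell 1
  m <- mota(gt, tr, mask = msk)
  expect_equal(m$n_gt, 5)
  expect_equal(m$fn, 0L)
  expect_equal(m$mota, 1)
  # without the mask the unobservable cell counts as missed
  expect_equal(mota(gt, tr)$fn, 5L)
})

test_that("an identity that switches and switches back counts twice", {
  gt <- data.frame(cell_id = 0L, frame = 0:5, x = 10, y = 10, r = 3)
  tr <- gt
  tr$cell_id <- c(0L, 0L, 7L, 7L, 0L, 0L)
  expect_equal(mota(gt, tr)$id_switches, 2L)
})

test_that("retention of full-length tracks is constant 1", {
  df <- data.frame(cell_id = rep(0:3, each = 20), frame = rep(0:19, 4),
                   x = 0, y = 0, source = "detected")
  rc <- retention_curve(df, total_frames = 20)
  expect_equal(rc$fraction, rep(1, 20))
})

test_that("half the tracks ending mid-sequence steps the curve to 0.5", {
  df <- rbind(
    data.frame(cell_id = rep(0:1, each = 20), frame = rep(0:19, 2)),
    data.frame(cell_id = rep(2:3, each = 10), frame = rep(0:9, 2)))
  df$x <- 0; df$y <- 0
  rc <- retention_curve(df, total_frames = 20)
  expect_equal(rc$fraction[rc$frame <= 9], rep(1, 10))
  expect_equal(rc$fraction[rc$frame >= 10], rep(0.5, 10))
})

test_that("retention is monotone non-increasing and ignores interpolation", {
  df <- data.frame(cell_id = rep(0:2, each = 15), frame = rep(0:14, 3),
                   x = 0, y = 0, source = "detected")
  df$source[df$cell_id == 2 & df$frame >= 8] <- "interpolated"
  rc <- retention_curve(df, total_frames = 15)
  expect_true(all(diff(rc$fraction) <= 0))
  expect_equal(rc$fraction[rc$frame == 8], 2 / 3)
  expect_equal(rc$fraction[1], 1)
})

test_that("retention accepts a track_set directly", {
  dets <- rbind(data.frame(frame = 0:9, x = 10, y = 10, r = 3),
                data.frame(frame = 0:9, x = 60, y = 60, r = 3))
  ts <- track_sequence(dets, total_frames = 10)
  rc <- retention_curve(ts)
  expect_equal(nrow(rc), 10)
  expect_equal(rc$fraction, rep(1, 10))
})
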