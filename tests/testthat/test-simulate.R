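sweep_schedule <- function() {
  # single 25-s sweep through 15-35 kHz at +800 Hz/s
  freq_schedule(data.frame(t_start = 0, t_end = 25, kind = "sweep",
                           f_start = 15e3, f_end = 35e3))
}

test_that("constant f far above fco gives monotone approach to the rim", {
  lay <- small_layout()
  fp <- field_proxy(lay)
  sch <- freq_schedule(data.frame(t_start = 0, t_end = 20, kind = "static",
                                  f_start = 60e3, f_end = NA))
  cells <- data.frame(cell_id = 0L, fco_true = 20e3, r_cell = 9,
                      x0 = lay$hole_centers[1, 1] + 10,
                      y0 = lay$hole_centers[1, 2], hole = 1L)
  gt <- simulate_tracks(lay, fp, cells, sch, diffusion_sigma = 0)
  rho <- sqrt((gt$x - lay$hole_centers[1, 1])^2 +
              (gt$y - lay$hole_centers[1, 2])^2)
  drho <- diff(rho)
  # monotone outward until within a step of the rim, then hovering there
  expect_true(all(drho[rho[-length(rho)] < 29] > -1e-9))
  expect_gt(max(rho), 28)
  expect_lt(max(rho), 36)   # hovers within one per-frame step of the rim
})

test_that("constant f far below fco gives monotone motion to the hole center", {
  lay <- small_layout()
  fp <- field_proxy(lay)
  sch <- freq_schedule(data.frame(t_start = 0, t_end = 30, kind = "static",
                                  f_start = 1e3, f_end = NA))
  cells <- data.frame(cell_id = 0L, fco_true = 20e3, r_cell = 9,
                      x0 = lay$hole_centers[1, 1] + 18,
                      y0 = lay$hole_centers[1, 2], hole = 1L)
  gt <- simulate_tracks(lay, fp, cells, sch, diffusion_sigma = 0)
  rho <- sqrt((gt$x - lay$hole_centers[1, 1])^2 +
              (gt$y - lay$hole_centers[1, 2])^2)
  # non-increasing down to a small neighborhood of the center
  drho <- diff(rho)
  expect_true(all(drho[rho[-length(rho)] > 1] < 1e-9))
  expect_lt(min(rho), 1)
})

test_that("sweep through fco reverses the radial velocity within 1 frame", {
  lay <- small_layout()
  fp <- field_proxy(lay)
  sch <- sweep_schedule()
  fco <- 25e3
  cells <- data.frame(cell_id = 0L, fco_true = fco, r_cell = 9,
                      x0 = lay$hole_centers[1, 1] + 18,
                      y0 = lay$hole_centers[1, 2], hole = 1L)
  gt <- simulate_tracks(lay, fp, cells, sch, diffusion_sigma = 0)
  rho <- sqrt((gt$x - lay$hole_centers[1, 1])^2 +
              (gt$y - lay$hole_centers[1, 2])^2)
  v <- diff(rho)                       # signed radial step per frame
  flips <- which(diff(sign(v[v != 0])) != 0)
  sgn <- sign(v)
  sgn <- sgn[sgn != 0]
  expect_equal(sum(diff(sgn) != 0), 1)     # exactly one reversal
  crossing_frame <- which(v > 0)[1] - 1    # first outward step, 0-based start
  f_at_flip <- freq_at(sch, crossing_frame / sch$fps)
  expect_lt(abs(f_at_flip - fco), 800 / sch$fps * 2 + 1e-9)  # within 1 frame
})

test_that("simulate_tracks is bitwise reproducible for a fixed seed", {
  lay <- small_layout()
  fp <- field_proxy(lay)
  cells <- make_cells(lay, 5, seed = 2)
  sch <- sweep_schedule()
  a <- simulate_tracks(lay, fp, cells, sch, seed = 7)
  b <- simulate_tracks(lay, fp, cells, sch, seed = 7)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
})

test_that("per-cell streams are independent of population size", {
  lay <- small_layout()
  fp <- field_proxy(lay)
  sch <- sweep_schedule()
  cells5 <- make_cells(lay, 5, seed = 2)
  a <- simulate_tracks(lay, fp, cells5, sch, seed = 7)
  b <- simulate_tracks(lay, fp, cells5[1:2, ], sch, seed = 7)
  expect_identical(a$x[a$cell_id == 1], b$x[b$cell_id == 1])
})

test_that("uncorrupted stream equals ground truth exactly", {
  lay <- small_layout()
  cells <- make_cells(lay, 4, seed = 2)
  gt <- simulate_tracks(lay, field_proxy(lay), cells, sweep_schedule(),
                        seed = 3)
  d <- corrupt_detections(gt, lay, p_miss = 0, p_fp = 0, pos_sigma = 0)
  expect_equal(nrow(d), nrow(gt))
  gg <- gt[order(gt$frame, gt$x), ]
  expect_equal(d$x, gg$x)
  expect_equal(d$y, gg$y)
  expect_equal(d$r, gg$r)
})

test_that("p_miss = 1 empties every frame after frame 0", {
  lay <- small_layout()
  cells <- make_cells(lay, 4, seed = 2)
  gt <- simulate_tracks(lay, field_proxy(lay), cells, sweep_schedule(),
                        seed = 3)
  d <- corrupt_detections(gt, lay, p_miss = 1 - 1e-12, p_fp = 0,
                          pos_sigma = 0)
  expect_equal(sum(d$frame == 0), 4)
  expect_equal(sum(d$frame > 0), 0)
})

test_that("dropout count respects binomial bounds (~1000 cell-frames)", {
  lay <- small_layout()
  cells <- make_cells(lay, 4, seed = 2)
  sch <- sweep_schedule()
  gt <- simulate_tracks(lay, field_proxy(lay), cells, sch, seed = 3)
  gt1 <- gt[gt$frame > 0, ]                   # frame 0 is exempt
  d <- corrupt_detections(gt, lay, p_miss = 0.1, p_fp = 0, pos_sigma = 0,
                          seed = 11)
  dropped <- nrow(gt1) - sum(d$frame > 0)
  n <- nrow(gt1)
  bounds <- qbinom(c(0.005, 0.995), n, 0.1)
  expect_gte(dropped, bounds[1])
  expect_lte(dropped, bounds[2])
})
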