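test_that("trapped_site needs 10 states and rejects outliers", {
  expect_error(trapped_site(data.frame(x = 1:5, y = 1:5)), "at least 10")
  set.seed(5)
  st <- data.frame(x = rnorm(40, 50, 0.5), y = rnorm(40, 50, 0.5))
  st <- rbind(st, data.frame(x = 80, y = 80))
  site <- trapped_site(st)
  expect_true(site$valid)
  expect_lt(site$n_used, 41)
  expect_lt(max(abs(site$center - 50)), 0.5)
})

test_that("intensity_trace averages a uniform frame exactly", {
  frames <- replicate(3, matrix(100, 64, 64), simplify = FALSE)
  site <- list(center = c(30, 30))
  tr <- intensity_trace(frames, site, probe_radius = 5, frames = 0:2)
  expect_equal(unname(tr), rep(100, 3))
  expect_equal(names(tr), c("0", "1", "2"))
})

test_that("intensity_trace sees a step and skips off-grid pixels", {
  f1 <- matrix(100, 64, 64); f2 <- matrix(100, 64, 64)
  f2[28:34, 28:34] <- 140                    # bright patch at the site
  tr <- intensity_trace(list(f1, f2), list(center = c(30, 30)), 3, 0:1)
  expect_gt(tr["1"], tr["0"])
  # probe centred 1 px from the border: off-grid part is excluded, the
  # in-grid part still averages the uniform value
  tr_edge <- intensity_trace(list(f1), list(center = c(1, 30)), 5, 0)
  expect_equal(unname(tr_edge), 100)
})

test_that("intensity_fco reads the crossover off a sustained departure", {
  sch <- freq_schedule(data.frame(
    t_start = c(0, 20), t_end = c(20, 45), kind = c("static", "sweep"),
    f_start = c(1e3, 15e3), f_end = c(NA, 35e3)))
  bl_frames <- 150:199
  sw_frames <- 200:449
  set.seed(31)
  trace <- c(rnorm(length(bl_frames), 100, 2),
             rnorm(length(sw_frames), 100, 2))
  names(trace) <- c(bl_frames, sw_frames)
  # sustained +10 departure from frame 275, where f = 15e3 + 800*7.5 = 21 kHz
  idx <- as.character(275:449)
  trace[idx] <- trace[idx] + 10
  est <- intensity_fco(trace, sch, bl_frames, sw_frames)
  expect_true(est$valid)
  expect_equal(est$diagnostics$trigger_frame, 275)
  expect_equal(est$fco, 21e3)
})

test_that("flat or quiet traces give an invalid intensity estimate", {
  sch <- freq_schedule(data.frame(
    t_start = c(0, 20), t_end = c(20, 45), kind = c("static", "sweep"),
    f_start = c(1e3, 15e3), f_end = c(NA, 35e3)))
  flat <- rep(100, 300)
  names(flat) <- c(150:199, 200:449)
  expect_false(intensity_fco(flat, sch, 150:199, 200:449)$valid)
  set.seed(32)
  quiet <- rnorm(300, 100, 2)
  names(quiet) <- c(150:199, 200:449)
  expect_false(intensity_fco(quiet, sch, 150:199, 200:449)$valid)
})

test_that("a single-frame noise spike does not trigger the detector", {
  sch <- freq_schedule(data.frame(
    t_start = c(0, 20), t_end = c(20, 45), kind = c("static", "sweep"),
    f_start = c(1e3, 15e3), f_end = c(NA, 35e3)))
  set.seed(33)
  trace <- rnorm(300, 100, 2)
  names(trace) <- c(150:199, 200:449)
  trace["250"] <- 130                        # isolated spike
  idx <- as.character(350:449)
  trace[idx] <- trace[idx] + 12              # genuine sustained departure
  est <- intensity_fco(trace, sch, 150:199, 200:449)
  expect_equal(est$diagnostics$trigger_frame, 350)
})

test_that("select_ring reports band radii and gradient variation", {
  lay <- small_layout()
  ring <- select_ring(field_proxy(lay))
  expect_equal(ring$r_in, 0.35 * 30)
  expect_equal(ring$r_out, 0.65 * 30)
  expect_equal(ring$rim_radius, 30)
  expect_gt(ring$grad_cv, 0)
  expect_error(select_ring(field_proxy(lay), frac = c(0.7, 0.4)))
})

test_that("ring_velocity recovers signed radial speed", {
  lay <- small_layout()
  ring <- select_ring(field_proxy(lay))
  ctr <- ring$center
  # outward at 15 px/s: radius 5 -> 35 px over 2 s at fps 10
  st_out <- data.frame(frame = 0:20, x = ctr[["x"]] + 5 + 1.5 * (0:20),
                       y = ctr[["y"]])
  expect_equal(ring_velocity(st_out, ring, fps = 10), 15)
  st_in <- st_out; st_in$frame <- 0:20
  st_in$x <- ctr[["x"]] + 35 - 1.5 * (0:20)
  expect_equal(ring_velocity(st_in, ring, fps = 10), -15)
  # fewer than two in-ring states: not a crossing
  st_far <- data.frame(frame = 0:5, x = ctr[["x"]] + 25, y = ctr[["y"]])
  expect_true(is.na(ring_velocity(st_far, ring, fps = 10)))
})

test_that("recm_from_velocity evaluates the force balance", {
  expect_equal(recm_from_velocity(0, 9.5e-6, 1e-3, 78 * 8.854e-12, 1e13), 0)
  v <- recm_from_velocity(1e-5, 9.5e-6, 1e-3, 78 * 8.854e-12, 1e13)
  expect_equal(v, 0.04814, tolerance = 1e-3)
  # quartering under doubled radius at fixed velocity
  expect_equal(recm_from_velocity(1e-5, 2 * 9.5e-6, 1e-3,
                                  78 * 8.854e-12, 1e13), v / 4)
  expect_error(recm_from_velocity(1e-5, -1, 1e-3, 1, 1), "positive")
})

test_that("fit_zero_crossing recovers a symmetric crossover exactly", {
  f <- c(26e3, 28e3, 32e3, 34e3)
  y <- c(-1, -0.6, 0.6, 1)
  est <- fit_zero_crossing(f, y, scale = "linear")
  expect_true(est$valid)
  expect_equal(est$fco, 30e3, tolerance = 1e-6)
})

test_that("fit_zero_crossing matches the closed-form logistic root", {
  f <- seq(5e3, 35e3, by = 2.5e3)
  y <- -0.5 + 1.5 / (1 + exp(-0.2e-3 * (f - 20e3)))
  est <- fit_zero_crossing(f, y, scale = "linear")
  expect_equal(est$fco, 20e3 - log(2) / 0.2e-3, tolerance = 1e-4)
})

test_that("degenerate mobility inputs are invalid", {
  expect_false(fit_zero_crossing(c(1e3, 2e3, 3e3), c(-1, 0.1, 1))$valid)
  expect_false(fit_zero_crossing(seq(1e3, 8e3, 1e3), rep(0.4, 8))$valid)
})

test_that("population_summary splits by method and drops invalids", {
  df <- data.frame(
    fco = c(20e3, 22e3, 24e3, NA, 21e3, 30e3),
    method = c("velocity", "velocity", "velocity", "velocity",
               "intensity", "intensity"),
    valid = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  ps <- population_summary(df)
  expect_equal(ps$velocity$n_valid, 3)
  expect_equal(ps$velocity$n_invalid, 1)
  expect_equal(ps$velocity$mean, 22e3)
  expect_equal(ps$velocity$median, 22e3)
  expect_equal(ps$intensity$n_valid, 2)
  expect_equal(sum(ps$intensity$hist$counts), 2)
  # list-of-estimates input agrees with the data.frame path
  ests <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(fco = df$fco[i], method = df$method[i],
                   valid = df$valid[i]), class = "fco_estimate")
  })
  expect_equal(population_summary(ests)$velocity$mean, 22e3)
})

test_that("velocity route recovers a simulated 25 kHz crossover", {
  lay <- small_layout()
  fp <- field_proxy(lay)
  # alternating traps and static tests: high trap (rim) before low tests,
  # low trap (centre) before high tests
  tests <- c(10e3, 15e3, 20e3, 30e3, 35e3, 45e3)
  traps <- ifelse(tests < 25e3, 41e3, 1e3)
  rows <- do.call(rbind, lapply(seq_along(tests), function(i) {
    t0 <- (i - 1) * 24
    data.frame(t_start = c(t0, t0 + 12), t_end = c(t0 + 12, t0 + 24),
               kind = "static", f_start = c(traps[i], tests[i]), f_end = NA)
  }))
  sch <- freq_schedule(rows)
  ctr <- lay$hole_centers[1, ]
  cells <- data.frame(cell_id = 0L, fco_true = 25e3, r_cell = 9,
                      x0 = ctr[1] + 15, y0 = ctr[2], hole = 1L)
  gt <- simulate_tracks(lay, fp, cells, sch, seed = 17)
  ring <- select_ring(fp)
  est <- estimate_fco_velocity(gt, sch, ring,
                               segments = seq(2, 12, by = 2))
  expect_true(est$valid)
  expect_lt(abs(est$fco - 25e3) / 25e3, 0.15)
})

test_that("intensity route recovers a simulated 25 kHz crossover", {
  lay <- make_chip_layout(1, 1, 120, 30, c(256L, 256L), fov_radius = 120)
  fp <- field_proxy(lay)
  # up- and down-sweep pair so the trigger lag largely cancels in the mean
  sch <- freq_schedule(data.frame(
    t_start = c(0, 15, 40, 55),
    t_end = c(15, 40, 55, 80),
    kind = c("static", "sweep", "static", "sweep"),
    f_start = c(1e3, 15e3, 41e3, 35e3),
    f_end = c(NA, 35e3, NA, 15e3)))
  ctr <- lay$hole_centers[1, ]
  cells <- data.frame(cell_id = 0L, fco_true = 25e3, r_cell = 9,
                      x0 = ctr[1] + 12, y0 = ctr[2], hole = 1L)
  gt <- simulate_tracks(lay, fp, cells, sch, seed = 19)
  fs <- make_frame_source(lay, gt)
  est <- estimate_fco_intensity(gt, fs, sch)
  expect_true(est$valid)
  expect_lt(abs(est$fco - 25e3), 2e3)
})
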