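# Ground-truthed synthetic DEP experiments.
#
# The kinematic surrogate replaces full Stokes dynamics with a first-order
# velocity law that preserves the observable the pipeline estimates: the
# reversal of radial motion when the applied frequency crosses a cell's
# crossover frequency. Each cell is tied to its "home" electrode hole; its
# radial speed is
#
#   v(t) = mobility_gain * |S(f(t))| * r_cell^2 * grad_e2(rho)   [px/s]
#
# directed towards the hole rim (the high-field annulus) under pDEP
# (S > 0) and towards the hole centre (the low-field locus where nDEP
# traps cells) under nDEP (S < 0). S(f) is the normalised real part of the
# single-shell Clausius-Mossotti factor of a cell whose membrane
# permittivity is solved so that S(fco_true) = 0; the transition is
# therefore exactly the physical CM transition shape, with a sign change at
# fco_true. Gaussian positional jitter models residual Brownian motion and
# centroid noise.

#' Generate a synthetic cell population on a chip
#'
#' Places `n` cells, one per electrode hole (cycling if `n` exceeds the
#' hole count), at random angles and radial offsets inside their holes, and
#' draws per-cell crossover frequencies and radii.
#'
#' @param layout A [make_chip_layout()].
#' @param n Number of cells.
#' @param fco_range Range (Hz) for uniform per-cell true crossover
#'   frequencies.
#' @param r_range Range (px) for uniform per-cell radii.
#' @param rho_frac Radial start offset as a fraction of the hole radius.
#' @param seed Integer seed.
#' @return data.frame with `cell_id` (0-based), `fco_true`, `r_cell`,
#'   `x0`, `y0`, `hole` (1-based home hole index).
#' @export
make_cells <- function(layout, n, fco_range = c(15e3, 35e3),
                       r_range = c(7, 10), rho_frac = c(0.4, 0.8),
                       seed = 1) {
  stopifnot(inherits(layout, "chip_layout"), n >= 1)
  set.seed(seed)
  nh <- nrow(layout$hole_centers)
  hole <- ((seq_len(n) - 1) %% nh) + 1
  ang <- stats::runif(n, 0, 2 * pi)
  rho <- stats::runif(n, rho_frac[1], rho_frac[2]) * layout$hole_radius
  data.frame(cell_id = seq_len(n) - 1L,
             fco_true = stats::runif(n, fco_range[1], fco_range[2]),
             r_cell = stats::runif(n, r_range[1], r_range[2]),
             x0 = layout$hole_centers[hole, 1] + rho * cos(ang),
             y0 = layout$hole_centers[hole, 2] + rho * sin(ang),
             hole = hole)
}

#' Simulate ground-truth trajectories under a frequency schedule
#'
#' @param layout A [make_chip_layout()].
#' @param field A [field_proxy()] on the same layout.
#' @param cells data.frame as returned by [make_cells()] (columns `cell_id`,
#'   `fco_true`, `r_cell`, `x0`, `y0`; `hole` optional, inferred if absent).
#' @param schedule A [freq_schedule()].
#' @param mobility_gain Calibration constant linking the field-proxy
#'   gradient to pixel velocity, px/s per px^2 per field unit.
#' @param diffusion_sigma Per-frame isotropic positional jitter, px. The
#'   default matches the Brownian scale of a ~10 um radius cell at 10 fps.
#' @param seed Integer seed. Each cell consumes an independent substream
#'   derived from `seed` and its `cell_id`, so trajectories are reproducible
#'   independently of population size.
#' @param base_model Base [shell_model()] whose membrane permittivity is
#'   re-solved per cell to impose `fco_true`.
#' @param n_frames Number of frames; defaults to the schedule span.
#'
#' @return data.frame of class `gt_tracks` with one row per cell per frame:
#'   `cell_id`, `frame` (0-based), `x`, `y`, `r`, `fco_true`. Positions are
#'   clamped to the image by reflection.
#' @export
simulate_tracks <- function(layout, field, cells, schedule,
                            mobility_gain = 0.6, diffusion_sigma = 0.05,
                            seed = 1, base_model = shell_model(),
                            n_frames = NULL) {
  stopifnot(inherits(layout, "chip_layout"), inherits(field, "field_proxy"),
            inherits(schedule, "freq_schedule"))
  nT <- if (is.null(n_frames)) schedule_n_frames(schedule) else as.integer(n_frames)
  nc <- nrow(cells)
  fps <- schedule$fps
  fvec <- freq_at(schedule, (seq_len(nT) - 1) / fps)

  ctr <- layout$hole_centers
  if (is.null(cells$hole)) {
    d2 <- outer(cells$x0, ctr[, 1], "-")^2 + outer(cells$y0, ctr[, 2], "-")^2
    cells$hole <- apply(d2, 1, which.min)
  }
  hx <- ctr[cells$hole, 1]; hy <- ctr[cells$hole, 2]
  R <- layout$hole_radius

  # per-cell normalised CM response over the frame frequency axis
  fgrid <- 10^seq(3, 6, length.out = 500)
  S <- matrix(0, nc, nT)
  for (i in seq_len(nc)) {
    m <- shell_model_with_fco(base_model, cells$fco_true[i])
    smax <- max(abs(re_cm_single_shell(m, fgrid)))
    S[i, ] <- re_cm_single_shell(m, fvec) / smax
  }

  # per-cell jitter substreams, independent of population size
  jx <- matrix(0, nc, nT); jy <- matrix(0, nc, nT)
  if (diffusion_sigma > 0) {
    for (i in seq_len(nc)) {
      set.seed((seed + 1000003 * (cells$cell_id[i] + 1)) %% .Machine$integer.max)
      jx[i, ] <- stats::rnorm(nT, 0, diffusion_sigma)
      jy[i, ] <- stats::rnorm(nT, 0, diffusion_sigma)
    }
  }

  xs <- matrix(NA_real_, nc, nT); ys <- matrix(NA_real_, nc, nT)
  xs[, 1] <- cells$x0; ys[, 1] <- cells$y0
  G <- mobility_gain * cells$r_cell^2
  sb2 <- 2 * field$sigma_bump^2
  xmax <- layout$image_shape[2] - 1; ymax <- layout$image_shape[1] - 1
  for (t in seq_len(nT - 1)) {
    dx <- xs[, t] - hx; dy <- ys[, t] - hy
    rho <- sqrt(dx^2 + dy^2)
    g <- exp(-(rho - R)^2 / sb2) + field$floor
    st <- S[, t]
    speed <- G * abs(st) * g / fps
    # pDEP: towards the rim; nDEP: towards the hole centre
    dir <- ifelse(st > 0, sign(R - rho), -1)
    ok <- rho > 0
    step_x <- ifelse(ok, speed * dir * dx / rho, 0) + jx[, t]
    step_y <- ifelse(ok, speed * dir * dy / rho, 0) + jy[, t]
    nx <- xs[, t] + step_x; ny <- ys[, t] + step_y
    # reflecting clamp at the image bounds
    nx <- abs(nx); nx <- xmax - abs(xmax - nx)
    ny <- abs(ny); ny <- ymax - abs(ymax - ny)
    xs[, t + 1] <- nx; ys[, t + 1] <- ny
  }

  out <- data.frame(
    cell_id = rep(cells$cell_id, each = nT),
    frame = rep(seq_len(nT) - 1L, times = nc),
    x = as.vector(t(xs)), y = as.vector(t(ys)),
    r = rep(cells$r_cell, each = nT),
    fco_true = rep(cells$fco_true, each = nT))
  class(out) <- c("gt_tracks", "data.frame")
  attr(out, "layout") <- layout
  attr(out, "cells") <- cells
  out
}

#' Corrupt ground-truth tracks into a detection stream
#'
#' Emulates an imperfect detector: each true state is dropped independently
#' with probability `p_miss` and jittered by isotropic Gaussian noise;
#' spurious detections arrive as a Poisson process per frame, uniform over
#' the FoV disk. First-frame states are never dropped: tracks are seeded
#' from frame 0, so a dropout there would remove the cell from the
#' experiment instead of stressing gap recovery. Default rates mirror a
#' high-recall, high-precision detector (miss ~1%, <1 false positive per
#' frame, sub-pixel centroid noise).
#'
#' @param tracks `gt_tracks` from [simulate_tracks()].
#' @param layout The chip layout (for the FoV disk); taken from `tracks` if
#'   omitted.
#' @param p_miss Per-state drop probability in \[0, 1).
#' @param p_fp Expected false positives per frame (>= 0).
#' @param pos_sigma Centroid jitter, px.
#' @param seed Integer seed.
#' @return data.frame of class `detections` with columns `frame`, `x`, `y`,
#'   `w`, `h`, `r`, `score`.
#' @export
corrupt_detections <- function(tracks, layout = attr(tracks, "layout"),
                               p_miss = 0.01, p_fp = 0.5, pos_sigma = 0.3,
                               seed = 1) {
  stopifnot(p_miss >= 0, p_miss < 1, p_fp >= 0, pos_sigma >= 0)
  set.seed(seed)
  n <- nrow(tracks)
  keep <- stats::runif(n) >= p_miss
  keep[tracks$frame == 0] <- TRUE
  kept <- tracks[keep, c("frame", "x", "y", "r")]
  kept$x <- kept$x + stats::rnorm(nrow(kept), 0, pos_sigma)
  kept$y <- kept$y + stats::rnorm(nrow(kept), 0, pos_sigma)
  kept$score <- 0.99

  nT <- max(tracks$frame) + 1L
  fp <- NULL
  if (p_fp > 0) {
    nfp <- stats::rpois(nT, p_fp)
    tot <- sum(nfp)
    if (tot > 0) {
      ang <- stats::runif(tot, 0, 2 * pi)
      rad <- layout$fov_radius * sqrt(stats::runif(tot))
      fp <- data.frame(frame = rep(seq_len(nT) - 1L, nfp),
                       x = layout$fov_center[["x"]] + rad * cos(ang),
                       y = layout$fov_center[["y"]] + rad * sin(ang),
                       r = stats::runif(tot, 5, 10), score = 0.3)
    }
  }
  out <- rbind(kept, fp)
  out <- out[order(out$frame, out$x), ]
  out$w <- 2 * out$r; out$h <- 2 * out$r
  out <- out[, c("frame", "x", "y", "w", "h", "r", "score")]
  rownames(out) <- NULL
  class(out) <- c("detections", "data.frame")
  out
}

#' Assemble a complete synthetic DEP experiment
#'
#' Convenience wrapper tying together layout, field proxy, cells, schedule,
#' ground-truth simulation and detection corruption, and exposing an
#' on-demand frame renderer for intensity-based analyses.
#'
#' @param layout,cells,schedule,field See [simulate_tracks()];
#'   `field` defaults to `field_proxy(layout)`.
#' @param mobility_gain,diffusion_sigma,seed Passed to [simulate_tracks()].
#' @param p_miss,p_fp,pos_sigma Passed to [corrupt_detections()];
#'   set all to zero for a noise-free stream.
#' @param noise_sigma Additive pixel noise used by the renderer.
#' @param n_frames Optional frame-count override.
#' @return A list of class `dep_experiment`: `layout`, `field`, `cells`,
#'   `schedule`, `gt` (ground-truth tracks), `detections`, `frame_source`
#'   (see [render_frame()]), and the generation parameters.
#' @export
simulate_experiment <- function(layout, cells, schedule,
                                field = field_proxy(layout),
                                mobility_gain = 0.6, diffusion_sigma = 0.05,
                                p_miss = 0.01, p_fp = 0.5, pos_sigma = 0.3,
                                noise_sigma = 2, seed = 1, n_frames = NULL) {
  gt <- simulate_tracks(layout, field, cells, schedule,
                        mobility_gain = mobility_gain,
                        diffusion_sigma = diffusion_sigma, seed = seed,
                        n_frames = n_frames)
  dets <- corrupt_detections(gt, layout, p_miss = p_miss, p_fp = p_fp,
                             pos_sigma = pos_sigma, seed = seed + 1)
  fs <- make_frame_source(layout, gt, noise_sigma = noise_sigma,
                          seed = seed + 2)
  structure(list(layout = layout, field = field, cells = cells,
                 schedule = schedule, gt = gt, detections = dets,
                 frame_source = fs,
                 params = list(mobility_gain = mobility_gain,
                               diffusion_sigma = diffusion_sigma,
                               p_miss = p_miss, p_fp = p_fp,
                               pos_sigma = pos_sigma,
                               noise_sigma = noise_sigma, seed = seed)),
            class = "dep_experiment")
}
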