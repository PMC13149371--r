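# Synthetic bright-field frame rendering: mid-grey background, darker
# electrode-hole annuli, cells as radially shaded bright discs, optional
# circular vignette outside the FoV, additive Gaussian noise, 8-bit range.

.BG_LEVEL <- 40
.HOLE_RING_DEPTH <- 18     # rim annulus darkening
.HOLE_FLOOR_DEPTH <- 6     # hole interior darkening
.CELL_AMP <- 110           # peak cell brightness above background
.VIGNETTE_FLOOR <- 10

#' Render one synthetic microscopy frame
#'
#' @param layout A [make_chip_layout()].
#' @param states data.frame with columns `x`, `y`, `r`: the cells present in
#'   this frame (e.g. one frame of a `gt_tracks` object). May be empty.
#' @param noise_sigma Additive Gaussian pixel noise (8-bit units).
#' @param vignette If `TRUE`, pixels outside the FoV disk are set to a dark
#'   floor.
#' @param seed Integer seed for the noise; rendering is deterministic given
#'   `(states, window, seed)`.
#' @param window Optional crop `c(x0, x1, y0, y1)` (0-based, inclusive pixel
#'   bounds); only this region is rendered, which makes per-site intensity
#'   probing cheap on long sequences.
#' @return Numeric matrix (rows x cols) of integers in \[0, 255\].
#' @export
render_frame <- function(layout, states = NULL, noise_sigma = 2,
                         vignette = TRUE, seed = 1, window = NULL) {
  stopifnot(inherits(layout, "chip_layout"))
  sh <- layout$image_shape
  if (is.null(window)) {
    window <- c(0, sh[2] - 1, 0, sh[1] - 1)
  }
  window <- round(window)
  x0 <- max(window[1], 0); x1 <- min(window[2], sh[2] - 1)
  y0 <- max(window[3], 0); y1 <- min(window[4], sh[1] - 1)
  nx <- x1 - x0 + 1; ny <- y1 - y0 + 1
  xs <- seq.int(x0, x1); ys <- seq.int(y0, y1)
  img <- matrix(.BG_LEVEL, ny, nx)

  paint_radial <- function(img, cx, cy, fun, reach) {
    # apply fun(d) additively on the disc of radius `reach` around (cx, cy)
    ix <- which(xs >= cx - reach & xs <= cx + reach)
    iy <- which(ys >= cy - reach & ys <= cy + reach)
    if (length(ix) == 0 || length(iy) == 0) return(img)
    d <- sqrt(outer((ys[iy] - cy)^2, (xs[ix] - cx)^2, "+"))
    img[iy, ix] <- img[iy, ix] + fun(d)
    img
  }

  R <- layout$hole_radius
  ring_sd <- max(1.5, R / 12)
  for (h in seq_len(nrow(layout$hole_centers))) {
    cx <- layout$hole_centers[h, 1]; cy <- layout$hole_centers[h, 2]
    reach <- R + 4 * ring_sd
    img <- paint_radial(img, cx, cy, function(d) {
      -.HOLE_RING_DEPTH * exp(-(d - R)^2 / (2 * ring_sd^2)) -
        .HOLE_FLOOR_DEPTH * (d < R)
    }, reach)
  }

  if (!is.null(states) && nrow(states) > 0) {
    for (i in seq_len(nrow(states))) {
      r <- states$r[i]
      img <- paint_radial(img, states$x[i], states$y[i], function(d) {
        .CELL_AMP * pmax(0, 1 - (d / r)^2)
      }, r)
    }
  }

  if (vignette) {
    d2 <- outer((ys - layout$fov_center[["y"]])^2,
                (xs - layout$fov_center[["x"]])^2, "+")
    img[d2 > layout$fov_radius^2] <- .VIGNETTE_FLOOR
  }

  if (noise_sigma > 0) {
    set.seed(seed %% .Machine$integer.max)
    img <- img + stats::rnorm(length(img), 0, noise_sigma)
  }
  matrix(pmin(255, pmax(0, round(img))), ny, nx)
}

#' On-demand frame source for a simulated experiment
#'
#' Returns a closure `f(frame, window = NULL)` rendering the requested frame
#' (or crop) of a ground-truth track set. Only cells intersecting the window
#' are drawn, so probing small patches over long sequences stays cheap.
#'
#' @param layout A [make_chip_layout()].
#' @param gt `gt_tracks` from [simulate_tracks()].
#' @param noise_sigma,vignette Passed to [render_frame()].
#' @param seed Base seed; frame `t` uses `seed + t` so repeated calls are
#'   reproducible.
#' @return `function(frame, window = NULL)` returning a pixel matrix.
#' @export
make_frame_source <- function(layout, gt, noise_sigma = 2, vignette = TRUE,
                              seed = 1) {
  by_frame <- split(seq_len(nrow(gt)), gt$frame)
  function(frame, window = NULL) {
    key <- as.character(frame)
    states <- if (key %in% names(by_frame)) {
      gt[by_frame[[key]], c("x", "y", "r")]
    } else NULL
    if (!is.null(window) && !is.null(states)) {
      keep <- states$x + states$r >= window[1] & states$x - states$r <= window[2] &
              states$y + states$r >= window[3] & states$y - states$r <= window[4]
      states <- states[keep, , drop = FALSE]
    }
    render_frame(layout, states, noise_sigma = noise_sigma,
                 vignette = vignette, seed = seed + frame, window = window)
  }
}
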