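#' Chip layout for a circular-hole electrode array
#'
#' Describes the geometric substrate of a DEP microfluidic chip: a regular
#' grid of circular electrode holes centred inside the circular illuminated
#' field of view (FoV) of the microscope.
#'
#' All coordinates follow the package-wide convention: origin at the top-left
#' pixel, `x` along columns, `y` along rows, 0-based, pixel centres at
#' integers.
#'
#' @param rows,cols Number of hole rows / columns (>= 1).
#' @param pitch Centre-to-centre hole spacing in pixels. Must exceed twice the
#'   hole radius so that holes do not overlap.
#' @param hole_radius Electrode hole radius in pixels (> 0).
#' @param image_shape Integer vector `c(rows, cols)` of the image in pixels;
#'   the reference acquisition geometry is `c(1024, 1280)`.
#' @param fov_radius Radius of the valid FoV disk in pixels. Defaults to the
#'   largest disk inscribed in the image minus a 12-pixel illumination margin.
#'
#' @return An object of class `chip_layout`: a list with `hole_centers`
#'   (n x 2 matrix of x, y), `hole_radius`, `image_shape`, `fov_center`,
#'   `fov_radius`.
#' @examples
#' lay <- make_chip_layout(2, 2, pitch = 100, hole_radius = 20,
#'                         image_shape = c(512, 512))
#' lay$hole_centers
#' @export
make_chip_layout <- function(rows, cols, pitch, hole_radius,
                             image_shape = c(1024L, 1280L),
                             fov_radius = NULL) {
  stopifnot(rows >= 1, cols >= 1, hole_radius > 0, length(image_shape) == 2,
            all(image_shape > 0))
  if (pitch <= 2 * hole_radius) {
    stop("holes overlap: pitch (", pitch, ") must exceed 2 * hole_radius (",
         2 * hole_radius, ")")
  }
  fov_center <- c(x = (image_shape[2] - 1) / 2, y = (image_shape[1] - 1) / 2)
  if (is.null(fov_radius)) {
    fov_radius <- min(image_shape) / 2 - 12
  }
  gx <- (seq_len(cols) - (cols + 1) / 2) * pitch + fov_center[["x"]]
  gy <- (seq_len(rows) - (rows + 1) / 2) * pitch + fov_center[["y"]]
  centers <- cbind(x = rep(gx, each = rows), y = rep(gy, times = cols))
  d <- sqrt((centers[, 1] - fov_center[["x"]])^2 +
            (centers[, 2] - fov_center[["y"]])^2)
  if (any(d + hole_radius > fov_radius)) {
    stop("hole grid does not fit inside the FoV disk (radius ", fov_radius,
         "); reduce rows/cols/pitch or enlarge the image")
  }
  structure(list(hole_centers = centers, hole_radius = hole_radius,
                 image_shape = as.integer(image_shape),
                 fov_center = fov_center, fov_radius = fov_radius),
            class = "chip_layout")
}

#' @export
print.chip_layout <- function(x, ...) {
  cat("chip_layout:", nrow(x$hole_centers), "holes, radius",
      x$hole_radius, "px, image", x$image_shape[1], "x", x$image_shape[2],
      ", FoV radius", round(x$fov_radius, 1), "px\n")
  invisible(x)
}

#' Analytic DEP field proxy for a chip layout
#'
#' Stand-in for a numerically simulated gradient map of the squared electric
#' field, `grad |E_rms|^2`. The proxy places an isotropic Gaussian annular
#' bump of width `sigma_bump` on each electrode hole rim (the high-field
#' annulus), decaying towards hole centres and the far field, on top of a
#' small constant floor. The direction field points towards the nearest hole
#' rim; where the nearest rim is ambiguous (exact hole centres) the direction
#' is flagged undefined (zero vector).
#'
#' @param layout A [make_chip_layout()] object.
#' @param sigma_bump Rim bump width in pixels; default `hole_radius / 4`.
#' @param floor Constant background level of the gradient magnitude, keeping
#'   cells weakly responsive away from the rims (arbitrary calibrated units).
#'
#' @return An object of class `field_proxy` with the layout, `sigma_bump` and
#'   `floor`; evaluate it with [field_eval()] or grid it with
#'   [field_grids()].
#' @export
field_proxy <- function(layout, sigma_bump = layout$hole_radius / 4,
                        floor = 0.1) {
  stopifnot(inherits(layout, "chip_layout"), sigma_bump > 0, floor >= 0)
  structure(list(layout = layout, sigma_bump = sigma_bump, floor = floor),
            class = "field_proxy")
}

#' Evaluate the field proxy at arbitrary points
#'
#' @param proxy A [field_proxy()] object.
#' @param xy n x 2 matrix of pixel coordinates (x, y).
#'
#' @return A list with `grad_e2` (numeric, >= 0), unit direction components
#'   `ux`, `uy` pointing towards the nearest hole rim (zero where undefined),
#'   `nearest_hole` (1-based hole index, ties broken towards the lower
#'   index), and `rho` (distance to the nearest hole centre).
#' @export
field_eval <- function(proxy, xy) {
  stopifnot(inherits(proxy, "field_proxy"))
  xy <- matrix(xy, ncol = 2)
  ctr <- proxy$layout$hole_centers
  R <- proxy$layout$hole_radius
  n <- nrow(xy)
  # distances to every hole centre: n x nholes
  dx <- outer(xy[, 1], ctr[, 1], "-")
  dy <- outer(xy[, 2], ctr[, 2], "-")
  dist <- sqrt(dx^2 + dy^2)
  grad <- rowSums(exp(-(dist - R)^2 / (2 * proxy$sigma_bump^2))) + proxy$floor
  rimdist <- abs(dist - R)
  nearest <- apply(rimdist, 1, which.min)   # which.min: lowest index on ties
  idx <- cbind(seq_len(n), nearest)
  rho <- dist[idx]
  # unit vector towards the rim of the nearest hole: outward if inside,
  # inward if outside; undefined at the exact centre (rho == 0)
  ux <- uy <- numeric(n)
  ok <- rho > 0
  sgn <- sign(R - rho)                       # +1 inside, -1 outside, 0 on rim
  ux[ok] <- sgn[ok] * dx[idx][ok] / rho[ok]
  uy[ok] <- sgn[ok] * dy[idx][ok] / rho[ok]
  list(grad_e2 = grad, ux = ux, uy = uy, nearest_hole = nearest, rho = rho)
}

#' Grid the field proxy over the full image
#'
#' @param proxy A [field_proxy()] object.
#' @return A list of matrices (`image_shape`): `grad_e2`, `ux`, `uy`.
#' @export
field_grids <- function(proxy) {
  sh <- proxy$layout$image_shape
  xs <- rep(seq_len(sh[2]) - 1, each = sh[1])
  ys <- rep(seq_len(sh[1]) - 1, times = sh[2])
  ev <- field_eval(proxy, cbind(xs, ys))
  list(grad_e2 = matrix(ev$grad_e2, sh[1], sh[2]),
       ux = matrix(ev$ux, sh[1], sh[2]),
       uy = matrix(ev$uy, sh[1], sh[2]))
}
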