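# Field-of-view mask: the valid circular observation region, built once
# from the first frame. Binarize -> fill enclosed holes -> morphological
# opening with a disk structuring element -> exclude the unstable top and
# bottom illumination bands -> keep the dominant connected component.

#' Build the field-of-view mask from the first frame
#'
#' @param frame Numeric matrix of 8-bit intensities (rows x cols).
#' @param disk_radius Radius (px) of the disk structuring element used for
#'   the morphological opening.
#' @param strip_rows Number of top and bottom rows excluded as unstable
#'   illumination bands.
#' @param threshold Either `"otsu"` (global Otsu threshold on the intensity
#'   histogram) or a numeric cut in \[0, 255\].
#' @return Object of class `fov_mask`: list with `mask` (logical matrix),
#'   and `provenance` (the intermediate fill/open images and settings).
#' @examples
#' lay <- make_chip_layout(1, 1, 100, 20, c(256, 256), fov_radius = 100)
#' fr <- render_frame(lay, noise_sigma = 0)
#' m <- make_fov_mask(fr)
#' contains(m, c(127.5, 127.5))
#' @export
make_fov_mask <- function(frame, disk_radius = 50, strip_rows = 10,
                          threshold = "otsu") {
  stopifnot(is.matrix(frame), length(frame) > 0, disk_radius >= 1)
  img <- frame / 255
  th <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  } else {
    threshold / 255
  }
  bin <- img > th
  if (all(bin) || !any(bin)) {
    stop("degenerate mask: binarization produced an all-",
         if (all(bin)) "foreground" else "background", " image")
  }
  fill <- EBImage::fillHull(EBImage::Image(bin * 1))
  brush <- EBImage::makeBrush(2 * disk_radius + 1, shape = "disc")
  open <- EBImage::opening(fill, brush)
  open <- EBImage::imageData(open) > 0.5
  mask <- open
  if (strip_rows > 0) {
    nr <- nrow(mask)
    mask[seq_len(min(strip_rows, nr)), ] <- FALSE
    mask[seq.int(max(1, nr - strip_rows + 1), nr), ] <- FALSE
  }
  if (!any(mask)) stop("degenerate mask: empty after opening/strip removal")
  # keep the single dominant connected component
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  tab <- tabulate(lab[lab > 0])
  mask <- lab == which.max(tab)
  structure(list(mask = mask,
                 provenance = list(I_fill = EBImage::imageData(fill) > 0.5,
                                   I_open = open,
                                   threshold = th * 255,
                                   disk_radius = disk_radius,
                                   strip_rows = strip_rows)),
            class = "fov_mask")
}

#' Point membership in the FoV mask
#'
#' @param mask A [make_fov_mask()] object (or plain logical matrix).
#' @param point Numeric `c(x, y)` in 0-based pixel coordinates.
#' @return `TRUE` iff the rounded pixel lies on the grid and the mask is
#'   true there; off-grid points are `FALSE`.
#' @export
contains <- function(mask, point) {
  contains_points(mask, matrix(point, ncol = 2))
}

#' Vectorised mask membership
#'
#' @param mask A [make_fov_mask()] object or logical matrix.
#' @param xy n x 2 matrix of (x, y), 0-based.
#' @return Logical vector.
#' @export
contains_points <- function(mask, xy) {
  m <- if (inherits(mask, "fov_mask")) mask$mask else mask
  xy <- matrix(xy, ncol = 2)
  col <- round(xy[, 1]) + 1
  row <- round(xy[, 2]) + 1
  ok <- is.finite(col) & is.finite(row) &
    col >= 1 & col <= ncol(m) & row >= 1 & row <= nrow(m)
  out <- logical(nrow(xy))
  out[ok] <- m[cbind(row[ok], col[ok])]
  out
}

#' @export
print.fov_mask <- function(x, ...) {
  cat("fov_mask:", nrow(x$mask), "x", ncol(x$mask), "-",
      sum(x$mask), "valid pixels (",
      round(100 * mean(x$mask), 1), "% )\n")
  invisible(x)
}
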