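# Image-stack and tabular I/O. Frames are 8-bit grayscale; stacks are
# either a single multi-page TIFF or a directory of numbered PNG/TIFF
# files. Detections and tracks travel as plain CSV with 0-based frames.

#' Read an 8-bit grayscale frame stack
#'
#' Accepts a multi-page TIFF file or a directory of numbered `.png` /
#' `.tif` / `.tiff` files (one frame each). Frame order follows the page
#' order (TIFF) or the numeric part of the file names (directory). All
#' frames must share one shape; the numbering must be gap-free. Inputs
#' deeper than 8 bits are rescaled to the 8-bit range with a warning
#' (detected for TIFF; PNG is rescaled silently by the decoder).
#'
#' @param path File or directory path.
#' @return List of numeric matrices with values in \[0, 255\], one per
#'   frame (index = frame + 1).
#' @export
read_frames <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0) stop("no PNG/TIFF frames found in ", path)
    num <- suppressWarnings(as.integer(gsub("\\D", "", basename(files))))
    if (any(is.na(num))) stop("frame file names must contain a frame number")
    files <- files[order(num)]
    num <- sort(num)
    if (!identical(num - num[1], seq_along(num) - 1L)) {
      stop("frame numbering has gaps: ",
           paste(utils::head(setdiff(seq(num[1], max(num)), num), 5),
                 collapse = ", "))
    }
    frames <- lapply(files, function(f) {
      a <- if (grepl("png$", f, ignore.case = TRUE)) {
        png::readPNG(f)
      } else {
        tiff::readTIFF(f)
      }
      if (length(dim(a)) == 3) a <- a[, , 1]
      a * 255
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bps <- attr(pages[[1]], "bits.per.sample")
    if (!is.null(bps) && bps > 8) {
      warning(bps, "-bit input rescaled to 8-bit")
    }
    frames <- lapply(pages, function(a) {
      if (length(dim(a)) == 3) a <- a[, , 1]
      a * 255
    })
  } else {
    stop("path does not exist: ", path)
  }
  shp <- dim(frames[[1]])
  bad <- which(!vapply(frames, function(f) identical(dim(f), shp), logical(1)))
  if (length(bad) > 0) {
    stop("frame ", bad[1] - 1, " has shape ",
         paste(dim(frames[[bad[1]]]), collapse = "x"),
         ", expected ", paste(shp, collapse = "x"))
  }
  frames
}

#' Write a frame stack as numbered 8-bit PNG files
#'
#' @param frames List of matrices in \[0, 255\].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix; files are `<prefix><frame>.png` with
#'   zero-padded 0-based frame numbers.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, dir, prefix = "frame_") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  width <- max(4, nchar(length(frames) - 1))
  paths <- vapply(seq_along(frames), function(i) {
    p <- file.path(dir, sprintf("%s%0*d.png", prefix, width, i - 1))
    png::writePNG(pmin(pmax(frames[[i]], 0), 255) / 255, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a detection stream from CSV
#'
#' @param path CSV with columns `frame`, `x`, `y`, `w`, `h` and optionally
#'   `score` (defaults to 1).
#' @return `detections` data.frame (adds `r = (w + h) / 4`).
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame", "x", "y", "w", "h")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("detection CSV missing columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(d$score)) d$score <- 1
  bbox_to_state(d$x, d$y, d$w, d$h, frame = d$frame, score = d$score)
}

#' Write a detection stream to CSV
#'
#' @param detections `detections` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_detections <- function(detections, path) {
  cols <- intersect(c("frame", "x", "y", "w", "h", "r", "score"),
                    names(detections))
  utils::write.csv(detections[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write tracks to CSV
#'
#' @param tracks Either a `track_set` (see [track_sequence()]) or a
#'   data.frame from [tracks_to_df()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(tracks, path) {
  df <- if (is.data.frame(tracks)) tracks else tracks_to_df(tracks)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read tracks from CSV
#'
#' @param path CSV with columns `cell_id`, `frame`, `x`, `y` and optionally
#'   `r`, `source`.
#' @return data.frame in [tracks_to_df()] layout.
#' @export
read_tracks <- function(path) {
  d <- utils::read.csv(path)
  miss <- setdiff(c("cell_id", "frame", "x", "y"), names(d))
  if (length(miss) > 0) {
    stop("track CSV missing columns: ", paste(miss, collapse = ", "))
  }
  d
}
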