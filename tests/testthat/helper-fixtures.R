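# Shared small fixtures; everything is computed, nothing is stored.

small_layout <- function() {
  make_chip_layout(3, 3, pitch = 84, hole_radius = 30,
                   image_shape = c(360L, 360L), fov_radius = 168)
}

# brute-force optimal assignment cardinality: maximum number of one-to-one
# pred-gt pairs with distance <= tol, by exhaustive enumeration (<= 6 objects)
brute_force_match_counts <- function(pred, gt, tol) {
  np <- nrow(pred); ng <- nrow(gt)
  if (np == 0 || ng == 0) return(list(tp = 0L, fp = np, fn = ng))
  d <- sqrt(outer(pred$x, gt$x, "-")^2 + outer(pred$y, gt$y, "-")^2)
  ok <- d <= tol
  best <- 0L
  # enumerate assignments of preds to gt slots (0 = unassigned)
  rec <- function(i, used, count) {
    if (count + (np - i + 1) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    for (j in seq_len(ng)) {
      if (!used[j] && ok[i, j]) {
        used[j] <- TRUE
        rec(i + 1, used, count + 1L)
        used[j] <- FALSE
      }
    }
    rec(i + 1, used, count)
  }
  rec(1L, logical(ng), 0L)
  list(tp = best, fp = np - best, fn = ng - best)
}

# fresh empty temporary directory
withr_like_tempdir <- function() {
  d <- tempfile("frames_")
  dir.create(d)
  d
}

# write a data.frame to a temporary CSV and return the path
tempfile_with <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}

# Monte-Carlo circle IoU oracle over the union bounding box
mc_circle_iou <- function(c1, c2, n = 1e7) {
  x0 <- min(c1[1] - c1[3], c2[1] - c2[3]); x1 <- max(c1[1] + c1[3], c2[1] + c2[3])
  y0 <- min(c1[2] - c1[3], c2[2] - c2[3]); y1 <- max(c1[2] + c1[3], c2[2] + c2[3])
  xs <- stats::runif(n, x0, x1); ys <- stats::runif(n, y0, y1)
  in1 <- (xs - c1[1])^2 + (ys - c1[2])^2 <= c1[3]^2
  in2 <- (xs - c2[1])^2 + (ys - c2[2])^2 <= c2[3]^2
  both <- sum(in1 & in2); either <- sum(in1 | in2)
  if (either == 0) 0 else both / either
}
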