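# Cell detection as centroid-radius states, a reference multiscale
# Laplacian-of-Gaussian blob detector for synthetic frames, and detection
# scoring. Any external detector can be plugged in by supplying a detection
# stream (CSV with frame, x, y, w, h, score); the state conversion and
# scoring below are detector-agnostic.

#' Convert a bounding box to a centroid-radius detection state
#'
#' The radius is derived from the box as `r = (w + h) / 4`, i.e. the mean
#' of the two half-extents.
#'
#' @param x,y Centroid coordinates (px, 0-based).
#' @param w,h Box width and height (px, > 0).
#' @param frame Frame index (0-based).
#' @param score Detection confidence in \[0, 1\].
#' @return One-row data.frame of class `detections` with columns `frame`,
#'   `x`, `y`, `w`, `h`, `r`, `score`.
#' @examples
#' bbox_to_state(0, 0, 24, 16)$r  # 10
#' @export
bbox_to_state <- function(x, y, w, h, frame = 0L, score = 1) {
  if (any(w <= 0) || any(h <= 0)) stop("box dimensions must be positive")
  out <- data.frame(frame = as.integer(frame), x = x, y = y, w = w, h = h,
                    r = (w + h) / 4, score = score)
  class(out) <- c("detections", "data.frame")
  out
}

#' Reference blob detector (multiscale Laplacian of Gaussian)
#'
#' Detects bright, roughly circular cells as scale-space maxima of the
#' scale-normalised negative Laplacian-of-Gaussian response. Maxima outside
#' the FoV mask are discarded; overlapping responses are suppressed
#' greedily by score. Deterministic for fixed inputs.
#'
#' @param frame Numeric matrix of intensities in \[0, 255\].
#' @param mask Optional [make_fov_mask()] object (or logical matrix)
#'   gating detections.
#' @param min_r,max_r Radius search range in px (`min_r < max_r`).
#' @param threshold Minimum normalised LoG response (intensity units).
#' @param frame_index Frame index recorded in the output.
#' @return `detections` data.frame (possibly zero rows).
#' @export
blob_detect <- function(frame, mask = NULL, min_r = 4, max_r = 12,
                        threshold = 25, frame_index = 0L) {
  stopifnot(is.matrix(frame), min_r < max_r)
  sigmas <- seq(min_r, max_r, by = 0.5) / sqrt(2)
  resp <- array(0, c(dim(frame), length(sigmas)))
  img <- EBImage::Image(frame)
  for (k in seq_along(sigmas)) {
    s <- sigmas[k]
    half <- ceiling(3.5 * s)
    ax <- seq(-half, half)
    g <- exp(-ax^2 / (2 * s^2))
    gdd <- (ax^2 / s^2 - 1) / s^2 * g        # 1-D second derivative kernel
    # separable LoG = gdd (x) g + g (x) gdd; scale-normalise by s^2, negate
    k1 <- outer(gdd, g) + outer(g, gdd)
    k1 <- -s^2 * k1 / sum(g)^2 * length(ax)  # keep response in intensity units
    k1 <- k1 / sum(abs(k1)) * 2               # normalise kernel mass
    resp[, , k] <- EBImage::imageData(
      EBImage::filter2(img, k1, boundary = "replicate"))
  }
  # local maxima over space (8-neighbourhood) and adjacent scales
  nr <- nrow(frame); nc <- ncol(frame)
  shift_max <- function(m) {
    p <- matrix(-Inf, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- m
    out <- matrix(-Inf, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- pmax(out, p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
    }
    out
  }
  cand <- NULL
  for (k in seq_along(sigmas)) {
    m <- resp[, , k]
    nb <- shift_max(m)
    if (k > 1) nb <- pmax(nb, resp[, , k - 1])
    if (k < length(sigmas)) nb <- pmax(nb, resp[, , k + 1])
    hit <- which(m >= nb & m > threshold, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      cand <- rbind(cand, cbind(hit, k = k, v = m[hit]))
    }
  }
  empty <- bbox_to_state(numeric(0), numeric(0), numeric(0), numeric(0),
                         frame = integer(0), score = numeric(0))
  if (is.null(cand) || nrow(cand) == 0) return(empty)
  x <- cand[, "col"] - 1; y <- cand[, "row"] - 1
  r <- sigmas[cand[, "k"]] * sqrt(2)
  v <- cand[, "v"]
  if (!is.null(mask)) {
    keep <- contains_points(mask, cbind(x, y))
    x <- x[keep]; y <- y[keep]; r <- r[keep]; v <- v[keep]
  }
  if (length(x) == 0) return(empty)
  # greedy non-maximum suppression by response
  ord <- order(-v)
  sel <- logical(length(x))
  for (i in ord) {
    si <- which(sel)
    if (length(si) > 0 &&
        any((x[i] - x[si])^2 + (y[i] - y[si])^2 < pmax(r[i], r[si])^2)) next
    sel[i] <- TRUE
  }
  bbox_to_state(x[sel], y[sel], 2 * r[sel], 2 * r[sel],
                frame = rep(as.integer(frame_index), sum(sel)),
                score = pmin(1, v[sel] / max(v)))
}

#' Match predicted detections to ground truth
#'
#' One-to-one matching within tolerance: pairs are first taken greedily by
#' ascending centroid distance, then completed to a maximum-cardinality
#' matching by augmenting paths on the within-tolerance graph, so the
#' counts equal the optimal bipartite assignment's counts (greedy alone
#' can under-match dense scenes). A pair is a true positive iff its
#' distance is at most `tol`.
#'
#' @param pred data.frame with `x`, `y` (predictions).
#' @param gt data.frame with `x`, `y` (ground truth).
#' @param tol Matching tolerance in px (> 0).
#' @return List with counts `tp`, `fp`, `fn` and the matched index pairs
#'   (`matches`, columns `pred`, `gt`).
#' @export
match_to_ground_truth <- function(pred, gt, tol) {
  stopifnot(tol > 0)
  np <- nrow(pred); ng <- nrow(gt)
  if (np == 0 || ng == 0) {
    return(list(tp = 0L, fp = np, fn = ng,
                matches = cbind(pred = integer(0), gt = integer(0))))
  }
  d <- sqrt(outer(pred$x, gt$x, "-")^2 + outer(pred$y, gt$y, "-")^2)
  ok <- d <= tol
  ord <- order(d)
  gt_of <- rep(NA_integer_, np)   # pred index -> matched gt index
  pd_of <- rep(NA_integer_, ng)   # gt index -> matched pred index
  for (k in ord) {
    if (d[k] > tol) break
    i <- (k - 1) %% np + 1
    j <- (k - 1) %/% np + 1
    if (!is.na(gt_of[i]) || !is.na(pd_of[j])) next
    gt_of[i] <- j; pd_of[j] <- i
  }
  # Kuhn-style augmentation: each unmatched pred searches an alternating
  # path to an unmatched gt, so the matching reaches maximum cardinality
  augment <- function(i, seen) {
    for (j in which(ok[i, ])) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (is.na(pd_of[j]) || Recall(pd_of[j], seen)) {
        gt_of[i] <<- j; pd_of[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in which(is.na(gt_of))) augment(i, logical(ng))
  mp <- which(!is.na(gt_of)); mg <- gt_of[mp]
  list(tp = length(mp), fp = np - length(mp), fn = ng - length(mp),
       matches = cbind(pred = mp, gt = mg))
}

#' Precision, recall and F-measure from detection counts
#'
#' @param tp,fp,fn Non-negative counts; both `tp + fp` and `tp + fn` must be
#'   positive for the ratios to be defined.
#' @return Object of class `detection_metrics`: list with the counts and
#'   exact `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)` and their
#'   harmonic mean `f_measure`. Values print rounded to 5 decimals.
#' @examples
#' detection_metrics(tp = 137, fp = 0, fn = 1)  # recall 0.99275
#' @export
detection_metrics <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp == 0 || tp + fn == 0) {
    stop("metrics not computable: tp + fp and tp + fn must both be positive")
  }
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f_measure = f),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf(
    "detection_metrics: TP=%d FP=%d FN=%d  precision=%.5f recall=%.5f F=%.5f\n",
    x$tp, x$fp, x$fn, round(x$precision, 5), round(x$recall, 5),
    round(x$f_measure, 5)))
  invisible(x)
}
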