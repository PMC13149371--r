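# DEP-induced rapid-motion identification from the frame-wise mean
# displacement of detected cells. Polarity switches of the applied field
# make the whole population jump at once; these frames show up as local
# maxima of the mean displacement series and gate the tracker's adaptive
# ROI/threshold regime.

#' Mean frame-to-frame displacement between two detection sets
#'
#' Correspondences are formed without identities, as mutual nearest
#' neighbours with distance at most `pair_cap`; the value is the mean
#' Euclidean displacement over those pairs.
#'
#' @param dets_t,dets_t1 data.frames with `x`, `y` for frames t and t+1.
#' @param pair_cap Maximum pairing distance in px.
#' @return List with `delta` (mean displacement, `NA` if no pairs) and `n`
#'   (number of pairs).
#' @export
frame_displacement <- function(dets_t, dets_t1, pair_cap = Inf) {
  n0 <- nrow(dets_t); n1 <- nrow(dets_t1)
  if (n0 == 0 || n1 == 0) return(list(delta = NA_real_, n = 0L))
  d <- sqrt(outer(dets_t$x, dets_t1$x, "-")^2 +
            outer(dets_t$y, dets_t1$y, "-")^2)
  f <- apply(d, 1, which.min)          # forward NN
  b <- apply(d, 2, which.min)          # backward NN
  i <- which(b[f] == seq_len(n0))      # mutual
  dd <- d[cbind(i, f[i])]
  keep <- dd <= pair_cap
  if (!any(keep)) return(list(delta = NA_real_, n = 0L))
  list(delta = mean(dd[keep]), n = sum(keep))
}

#' Rapid-motion frames from a displacement series
#'
#' A frame is rapid iff its displacement is a strict local maximum within
#' `window` frames on each side (among defined values) and reaches at
#' least `lam` times the global maximum of the series.
#'
#' @param delta Numeric displacement series; element `i` is the mean
#'   displacement between frames `i - 1` and `i` (0-based frame `i - 1`).
#'   `NA` gaps are allowed.
#' @param lam Threshold factor in \[0, 1\] relative to the series maximum.
#' @param window Half-width of the local-maximum neighbourhood in frames.
#' @return Sorted 0-based indices into `delta` of the rapid frames.
#' @examples
#' rapid_motion_frames(c(1, 1, 8, 1, 10, 1), lam = 0.5, window = 1) # 2, 4
#' @export
rapid_motion_frames <- function(delta, lam = 0.5, window = 5) {
  stopifnot(length(delta) >= 3, lam >= 0, window >= 1)
  gmax <- max(delta, na.rm = TRUE)
  n <- length(delta)
  out <- integer(0)
  for (i in seq_len(n)) {
    v <- delta[i]
    if (is.na(v) || v < lam * gmax) next
    nb <- delta[max(1, i - window):min(n, i + window)]
    nb <- nb[!is.na(nb)]
    if (sum(nb == v) == 1 && v == max(nb)) out <- c(out, i - 1L)
  }
  out
}

#' Merge rapid frames into intervals
#'
#' Frames whose halos overlap are merged into disjoint `[start, end]`
#' ranges.
#'
#' @param rapid_frames 0-based rapid frame indices.
#' @param halo Half-width of the influence region per rapid frame.
#' @return data.frame with `start`, `end` (0-based, inclusive).
#' @export
rapid_intervals <- function(rapid_frames, halo = 10) {
  if (length(rapid_frames) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  rf <- sort(unique(rapid_frames))
  start <- rf - halo; end <- rf + halo
  s <- start[1]; e <- end[1]
  out <- NULL
  for (i in seq_along(rf)[-1]) {
    if (start[i] <= e + 1) e <- max(e, end[i]) else {
      out <- rbind(out, c(s, e)); s <- start[i]; e <- end[i]
    }
  }
  out <- rbind(out, c(s, e))
  data.frame(start = pmax(out[, 1], 0), end = out[, 2])
}

#' Motion regime of a frame
#'
#' @param t 0-based frame index (vectorised).
#' @param rapid_frames 0-based rapid frame indices.
#' @param halo Frames on each side of a rapid frame treated as rapid
#'   (inclusive).
#' @return Character vector, `"rapid"` or `"stable"`.
#' @export
regime_of_frame <- function(t, rapid_frames, halo = 10) {
  if (length(rapid_frames) == 0) return(rep("stable", length(t)))
  rapid <- vapply(t, function(tt) any(abs(tt - rapid_frames) <= halo),
                  logical(1))
  ifelse(rapid, "rapid", "stable")
}

#' Motion profile of a detection stream
#'
#' Computes the per-frame mean displacement series, the rapid frames and
#' the merged rapid intervals for a whole detection stream.
#'
#' @param detections `detections` data.frame (columns `frame`, `x`, `y`).
#' @param pair_cap Pairing cap in px; default 4x the median detection
#'   radius when a radius column is present, else `Inf`.
#' @param lam,window,halo See [rapid_motion_frames()] and
#'   [rapid_intervals()].
#' @param total_frames Number of frames; default inferred.
#' @return Object of class `motion_profile`: list with `delta`, `n_pairs`,
#'   `rapid_frames`, `intervals`, `lam`, `halo`.
#' @export
motion_profile <- function(detections, pair_cap = NULL, lam = 0.5,
                           window = 5, halo = 10, total_frames = NULL) {
  if (is.null(pair_cap)) {
    pair_cap <- if (!is.null(detections$r)) {
      4 * stats::median(detections$r)
    } else Inf
  }
  nT <- if (is.null(total_frames)) max(detections$frame) + 1L else total_frames
  idx <- split(seq_len(nrow(detections)), factor(detections$frame,
                                                 levels = 0:(nT - 1)))
  delta <- rep(NA_real_, nT - 1)
  npair <- integer(nT - 1)
  for (t in seq_len(nT - 1)) {
    a <- detections[idx[[t]], , drop = FALSE]
    b <- detections[idx[[t + 1]], , drop = FALSE]
    fd <- frame_displacement(a, b, pair_cap)
    delta[t] <- fd$delta; npair[t] <- fd$n
  }
  rf <- rapid_motion_frames(delta, lam = lam, window = window)
  structure(list(delta = delta, n_pairs = npair, rapid_frames = rf,
                 intervals = rapid_intervals(rf, halo = halo),
                 lam = lam, window = window, halo = halo),
            class = "motion_profile")
}

#' @export
print.motion_profile <- function(x, ...) {
  cat("motion_profile:", length(x$delta), "steps,",
      length(x$rapid_frames), "rapid frames,",
      nrow(x$intervals), "intervals (lam =", x$lam, ")\n")
  invisible(x)
}
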