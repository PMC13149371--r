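# Motion-aware adaptive-ROI tracking.
#
# One track per first-frame detection. Per frame, each track proposes the
# detection minimising the Euclidean distance inside its regime-dependent
# ROI; the proposal is accepted only if it also passes the regime's
# displacement gate and the bounding-circle IoU threshold (argmin-first
# semantics: only the distance minimiser is tested against the IoU gate).
# On failure, candidates are searched up to `max_gap` subsequent frames;
# bridged frames are filled by linear interpolation. Rapid-motion intervals
# widen the ROI and relax the gates.

#' Exact intersection-over-union of two circles
#'
#' Computes the lens (circular-segment) intersection area analytically.
#'
#' @param c1,c2 Numeric `c(x, y, r)` with `r > 0`.
#' @return IoU in \[0, 1\]; 1 for identical circles, 0 when disjoint.
#' @examples
#' circle_iou(c(0, 0, 1), c(1, 0, 1))  # ~0.2430
#' @export
circle_iou <- function(c1, c2) {
  r1 <- c1[3]; r2 <- c2[3]
  stopifnot(r1 > 0, r2 > 0)
  d <- sqrt((c1[1] - c2[1])^2 + (c1[2] - c2[2])^2)
  a1 <- pi * r1^2; a2 <- pi * r2^2
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) {
    inter <- min(a1, a2)
  } else {
    q1 <- (d^2 + r1^2 - r2^2) / (2 * d * r1)
    q2 <- (d^2 + r2^2 - r1^2) / (2 * d * r2)
    q1 <- min(1, max(-1, q1)); q2 <- min(1, max(-1, q2))
    tri <- 0.5 * sqrt(max(0, (-d + r1 + r2) * (d + r1 - r2) *
                            (d - r1 + r2) * (d + r1 + r2)))
    inter <- r1^2 * acos(q1) + r2^2 * acos(q2) - tri
  }
  inter / (a1 + a2 - inter)
}

#' Vectorised circle IoU of paired circles
#'
#' @param x1,y1,r1,x2,y2,r2 Coordinate and radius vectors of equal length.
#' @return Numeric vector of IoU values.
#' @export
circle_iou_vec <- function(x1, y1, r1, x2, y2, r2) {
  d <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
  a1 <- pi * r1^2; a2 <- pi * r2^2
  inter <- numeric(length(d))
  contained <- d <= abs(r1 - r2)
  inter[contained] <- pmin(a1, a2)[contained]
  lens <- !contained & d < r1 + r2
  if (any(lens)) {
    dd <- d[lens]; rr1 <- r1[lens]; rr2 <- r2[lens]
    q1 <- pmin(1, pmax(-1, (dd^2 + rr1^2 - rr2^2) / (2 * dd * rr1)))
    q2 <- pmin(1, pmax(-1, (dd^2 + rr2^2 - rr1^2) / (2 * dd * rr2)))
    tri <- 0.5 * sqrt(pmax(0, (-dd + rr1 + rr2) * (dd + rr1 - rr2) *
                             (dd - rr1 + rr2) * (dd + rr1 + rr2)))
    inter[lens] <- rr1^2 * acos(q1) + rr2^2 * acos(q2) - tri
  }
  inter / (a1 + a2 - inter)
}

#' Tracker configuration
#'
#' ROI radii and displacement gates scale with each track's current radius;
#' IoU thresholds are absolute. Rapid-motion intervals use the larger ROI
#' and the relaxed gates.
#'
#' @param roi_stable,roi_rapid Search radii as multiples of the track
#'   radius (`roi_rapid >= roi_stable`).
#' @param dist_stable,dist_rapid Displacement gates, same units; default
#'   equal to the ROI radii.
#' @param iou_stable,iou_rapid Circle-IoU acceptance thresholds in
#'   \[0, 1\] (`iou_rapid <= iou_stable`).
#' @param max_gap Maximum number of subsequent frames searched (and
#'   bridged by interpolation) after a failed association.
#' @param first_frame_only If `TRUE`, tracks are created only from
#'   first-frame detections; later appearances never start new tracks.
#' @return Object of class `tracker_config`.
#' @export
tracker_config <- function(roi_stable = 3, roi_rapid = 6,
                           dist_stable = roi_stable, dist_rapid = roi_rapid,
                           iou_stable = 0.2, iou_rapid = 0.05,
                           max_gap = 10, first_frame_only = TRUE) {
  stopifnot(roi_rapid >= roi_stable, iou_rapid <= iou_stable, max_gap >= 1)
  structure(list(roi_stable = roi_stable, roi_rapid = roi_rapid,
                 dist_stable = dist_stable, dist_rapid = dist_rapid,
                 iou_stable = iou_stable, iou_rapid = iou_rapid,
                 max_gap = max_gap, first_frame_only = first_frame_only),
            class = "tracker_config")
}

#' Associate one track with a detection in the next frame
#'
#' Argmin-first semantics: the candidate is the detection minimising the
#' Euclidean distance to the track's last state among detections within
#' the regime's ROI radius (ties broken by lower detection index); it is
#' accepted iff its distance passes the regime's displacement gate and its
#' bounding-circle IoU with the last state passes the regime's threshold.
#'
#' @param state Numeric `c(x, y, r)`: the track's last known state.
#' @param dets data.frame with `x`, `y`, `r` of candidate detections.
#' @param regime `"stable"` or `"rapid"`.
#' @param config A [tracker_config()].
#' @return 1-based row index of the matched detection, or `NA` if none.
#' @export
associate <- function(state, dets, regime, config = tracker_config()) {
  if (is.null(dets) || nrow(dets) == 0) return(NA_integer_)
  rapid <- identical(regime, "rapid")
  roi <- (if (rapid) config$roi_rapid else config$roi_stable) * state[3]
  gate <- (if (rapid) config$dist_rapid else config$dist_stable) * state[3]
  tau <- if (rapid) config$iou_rapid else config$iou_stable
  d <- sqrt((dets$x - state[1])^2 + (dets$y - state[2])^2)
  inroi <- which(d <= roi)
  if (length(inroi) == 0) return(NA_integer_)
  i <- inroi[which.min(d[inroi])]      # which.min: lowest index on ties
  if (d[i] > gate) return(NA_integer_)
  iou <- circle_iou(state, c(dets$x[i], dets$y[i], dets$r[i]))
  if (iou < tau) return(NA_integer_)
  i
}

#' Search subsequent frames for a lost track
#'
#' Scans the frames after a failed association, up to `max_gap`, and
#' returns the first frame containing any detection inside the ROI centred
#' at the last known centroid, together with the nearest such detection
#' (ties broken by lower index).
#'
#' @param state `c(x, y, r)` last known state.
#' @param dets_by_frame List of detection data.frames indexed by
#'   `frame + 1`.
#' @param t_gap 0-based frame at which association failed.
#' @param regime Regime at `t_gap` (sets the ROI radius).
#' @param config A [tracker_config()].
#' @param claimed Optional list of logical vectors parallel to
#'   `dets_by_frame`, marking detections already assigned.
#' @return List `(frame, index)` or `NULL` if nothing is found within
#'   `max_gap` frames.
#' @export
recover_gap <- function(state, dets_by_frame, t_gap, regime = "stable",
                        config = tracker_config(), claimed = NULL) {
  rapid <- identical(regime, "rapid")
  roi <- (if (rapid) config$roi_rapid else config$roi_stable) * state[3]
  nT <- length(dets_by_frame)
  if (t_gap + 1 > nT - 1) return(NULL)
  for (f in seq.int(t_gap + 1, min(t_gap + config$max_gap, nT - 1))) {
    dets <- dets_by_frame[[f + 1]]
    if (is.null(dets) || nrow(dets) == 0) next
    free <- if (is.null(claimed)) rep(TRUE, nrow(dets)) else !claimed[[f + 1]]
    if (!any(free)) next
    d <- sqrt((dets$x - state[1])^2 + (dets$y - state[2])^2)
    d[!free] <- Inf
    i <- which.min(d)
    if (d[i] <= roi) return(list(frame = f, index = i))
  }
  NULL
}

#' Linearly interpolate track states across a gap
#'
#' @param s0,s1 Numeric `c(x, y, r)` states at frames `t0` and `t1`.
#' @param t0,t1 0-based frames bounding the gap (`t1 > t0`).
#' @return data.frame of interpolated states for frames `t0+1 ... t1-1`
#'   (zero rows when the gap is empty), with `source = "interpolated"`.
#' @export
interpolate_gap <- function(s0, s1, t0, t1) {
  stopifnot(t1 > t0)
  if (t1 - t0 == 1) {
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      r = numeric(0), source = character(0)))
  }
  tt <- seq.int(t0 + 1, t1 - 1)
  a <- (tt - t0) / (t1 - t0)
  data.frame(frame = tt,
             x = s0[1] + a * (s1[1] - s0[1]),
             y = s0[2] + a * (s1[2] - s0[2]),
             r = s0[3] + a * (s1[3] - s0[3]),
             source = "interpolated")
}

#' Reconstruct all tracks from a detection stream
#'
#' @param detections `detections` data.frame (`frame`, `x`, `y`, `r`).
#' @param rapid_frames 0-based rapid-motion frame indices (e.g. from
#'   [motion_profile()]).
#' @param mask Optional [make_fov_mask()]; only used downstream by
#'   [out_of_range_filter()], accepted here for interface symmetry.
#' @param config A [tracker_config()].
#' @param total_frames Sequence length; default inferred from the stream.
#' @param halo Rapid-interval half width (frames).
#' @return Object of class `track_set`: list with `tracks` (a list; each a
#'   list with `cell_id`, `states` data.frame `frame, x, y, r, source`,
#'   `last_frame`, `status`), `total_frames`, `conflicts` (data.frame log
#'   of contested detections).
#' @export
track_sequence <- function(detections, rapid_frames = integer(0),
                           mask = NULL, config = tracker_config(),
                           total_frames = NULL, halo = 10) {
  nT <- if (is.null(total_frames)) max(detections$frame) + 1L
        else as.integer(total_frames)
  idx <- split(seq_len(nrow(detections)),
               factor(detections$frame, levels = 0:(nT - 1)))
  dets_by_frame <- lapply(idx, function(i) {
    detections[i, c("x", "y", "r"), drop = FALSE]
  })
  first <- dets_by_frame[[1]]
  if (is.null(first) || nrow(first) == 0) {
    stop("empty first frame: no detections to initialise tracks")
  }
  regime <- regime_of_frame(0:(nT - 1), rapid_frames, halo = halo)
  n_tracks <- nrow(first)

  # state matrices: one row per frame; src 0 = none, 1 = detected, 2 = interp
  X <- matrix(NA_real_, nT, n_tracks); Y <- X; Rr <- X
  SRC <- matrix(0L, nT, n_tracks)
  X[1, ] <- first$x; Y[1, ] <- first$y; Rr[1, ] <- first$r
  SRC[1, ] <- 1L
  last_frame <- rep(0L, n_tracks)      # last known (detected) frame
  next_frame <- rep(1L, n_tracks)      # next frame each track looks at
  active <- rep(TRUE, n_tracks)

  claimed <- lapply(dets_by_frame, function(d) {
    if (is.null(d)) logical(0) else logical(nrow(d))
  })
  conflicts <- NULL

  for (f in seq_len(nT - 1)) {         # f is the 0-based target frame
    dets <- dets_by_frame[[f + 1]]
    for (q in seq_len(n_tracks)) {
      if (!active[q] || next_frame[q] != f) next
      state <- c(X[f, q], Y[f, q], Rr[f, q])
      free <- !claimed[[f + 1]]
      cand <- if (!is.null(dets) && any(free)) {
        dets[free, , drop = FALSE]
      } else NULL
      j <- associate(state, cand, regime[f + 1], config)
      if (!is.na(j)) {
        j_global <- which(free)[j]
        # log when a claimed detection would have been the distance argmin
        if (any(claimed[[f + 1]])) {
          dall <- sqrt((dets$x - state[1])^2 + (dets$y - state[2])^2)
          if (which.min(dall) != j_global &&
              claimed[[f + 1]][which.min(dall)]) {
            conflicts <- rbind(conflicts,
                               data.frame(frame = f, track = q - 1L,
                                          detection = which.min(dall) - 1L))
          }
        }
        claimed[[f + 1]][j_global] <- TRUE
        X[f + 1, q] <- dets$x[j_global]; Y[f + 1, q] <- dets$y[j_global]
        Rr[f + 1, q] <- dets$r[j_global]; SRC[f + 1, q] <- 1L
        last_frame[q] <- f; next_frame[q] <- f + 1L
      } else {
        rec <- recover_gap(state, dets_by_frame, f, regime[f + 1], config,
                           claimed)
        if (is.null(rec)) {
          active[q] <- FALSE           # terminated at last known state
        } else {
          g <- rec$frame
          dg <- dets_by_frame[[g + 1]]
          claimed[[g + 1]][rec$index] <- TRUE
          s1 <- c(dg$x[rec$index], dg$y[rec$index], dg$r[rec$index])
          fill <- interpolate_gap(state, s1, f - 1, g)
          if (nrow(fill) > 0) {
            rows <- fill$frame + 1
            X[rows, q] <- fill$x; Y[rows, q] <- fill$y; Rr[rows, q] <- fill$r
            SRC[rows, q] <- 2L
          }
          X[g + 1, q] <- s1[1]; Y[g + 1, q] <- s1[2]; Rr[g + 1, q] <- s1[3]
          SRC[g + 1, q] <- 1L
          last_frame[q] <- g; next_frame[q] <- g + 1L
        }
      }
    }
  }

  tracks <- lapply(seq_len(n_tracks), function(q) {
    have <- which(SRC[, q] > 0L)
    list(cell_id = q - 1L,
         states = data.frame(
           frame = have - 1L, x = X[have, q], y = Y[have, q],
           r = Rr[have, q],
           source = c("detected", "interpolated")[SRC[have, q]]),
         last_frame = last_frame[q],
         status = "active")
  })
  structure(list(tracks = tracks, total_frames = nT,
                 conflicts = if (is.null(conflicts)) {
                   data.frame(frame = integer(0), track = integer(0),
                              detection = integer(0))
                 } else conflicts),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  lens <- vapply(x$tracks, function(t) nrow(t$states), integer(1))
  cat("track_set:", length(x$tracks), "tracks over", x$total_frames,
      "frames; lengths", min(lens), "-", max(lens), ";",
      nrow(x$conflicts), "conflicts\n")
  invisible(x)
}

#' Flatten a track set (or ground truth) to a long data.frame
#' @param tracks A `track_set` or `gt_tracks` object.
#' @return data.frame with `cell_id`, `frame`, `x`, `y`, `r` (and `source`
#'   for tracker output).
#' @export
tracks_to_df <- function(tracks) {
  if (inherits(tracks, "gt_tracks")) return(as.data.frame(tracks))
  stopifnot(inherits(tracks, "track_set"))
  do.call(rbind, lapply(tracks$tracks, function(t) {
    cbind(cell_id = t$cell_id, t$states)
  }))
}

#' Partition tracks by temporal completeness and spatial validity
#'
#' A track is out of range iff it is shorter than the full sequence or any
#' of its state centroids leaves the FoV mask. Out-of-range tracks are
#' excluded from crossover-frequency analysis.
#'
#' @param track_set A [track_sequence()] result.
#' @param total_frames Full sequence length `T`; defaults to the track
#'   set's.
#' @param mask Optional [make_fov_mask()].
#' @return The track set with per-track `status` set to `"valid"` or
#'   `"out_of_range"`, plus elements `valid` and `out_of_range` holding
#'   the 0-based track ids of each class.
#' @export
out_of_range_filter <- function(track_set, total_frames = NULL, mask = NULL) {
  stopifnot(inherits(track_set, "track_set"))
  nT <- if (is.null(total_frames)) track_set$total_frames else total_frames
  valid <- out <- integer(0)
  for (q in seq_along(track_set$tracks)) {
    tr <- track_set$tracks[[q]]
    full <- nrow(tr$states) == nT
    inmask <- if (is.null(mask)) TRUE else {
      all(contains_points(mask, cbind(tr$states$x, tr$states$y)))
    }
    if (full && inmask) {
      track_set$tracks[[q]]$status <- "valid"
      valid <- c(valid, tr$cell_id)
    } else {
      track_set$tracks[[q]]$status <- "out_of_range"
      out <- c(out, tr$cell_id)
    }
  }
  track_set$valid <- valid
  track_set$out_of_range <- out
  track_set
}

#' Overlap-based identity validation
#'
#' Detects pairs of tracks whose bounding circles overlap beyond
#' `tau_overlap` for at least `min_consecutive` consecutive frames, and
#' re-evaluates identities across each event: the suffixes after the
#' overlap run are swapped when that strictly reduces the total
#' across-junction displacement. Pairs that remain coincident to the end
#' of the sequence are flagged as merged.
#'
#' @param track_set A [track_sequence()] result (run after
#'   [out_of_range_filter()] or before; all tracks are examined).
#' @param tau_overlap IoU threshold above which overlap is "excessive".
#' @param min_consecutive Minimum run length in frames.
#' @return The track set with corrected states; element `merge_events` is
#'   a data.frame log (`track_a`, `track_b`, `start`, `end`, `action`).
#' @export
overlap_identity_check <- function(track_set, tau_overlap = 0.4,
                                   min_consecutive = 3) {
  stopifnot(inherits(track_set, "track_set"))
  n <- length(track_set$tracks)
  events <- NULL
  if (n >= 2) {
    for (a in seq_len(n - 1)) for (b in seq.int(a + 1, n)) {
      ta <- track_set$tracks[[a]]$states
      tb <- track_set$tracks[[b]]$states
      common <- intersect(ta$frame, tb$frame)
      if (length(common) < min_consecutive) next
      ia <- match(common, ta$frame); ib <- match(common, tb$frame)
      iou <- circle_iou_vec(ta$x[ia], ta$y[ia], ta$r[ia],
                            tb$x[ib], tb$y[ib], tb$r[ib])
      over <- iou > tau_overlap
      r <- rle(over)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      runs <- which(r$values & r$lengths >= min_consecutive)
      for (k in runs) {
        f0 <- common[starts[k]]; f1 <- common[ends[k]]
        if (f1 >= min(max(ta$frame), max(tb$frame))) {
          events <- rbind(events, data.frame(
            track_a = a - 1L, track_b = b - 1L, start = f0, end = f1,
            action = "merged"))
          track_set$tracks[[a]]$status <- "merged"
          track_set$tracks[[b]]$status <- "merged"
          next
        }
        # junction cost: displacement from the last overlap frame to the
        # next frame under current vs swapped identities
        ja0 <- which(ta$frame == f1); ja1 <- which(ta$frame > f1)[1]
        jb0 <- which(tb$frame == f1); jb1 <- which(tb$frame > f1)[1]
        if (is.na(ja1) || is.na(jb1)) next
        keep <- sqrt((ta$x[ja1] - ta$x[ja0])^2 + (ta$y[ja1] - ta$y[ja0])^2) +
                sqrt((tb$x[jb1] - tb$x[jb0])^2 + (tb$y[jb1] - tb$y[jb0])^2)
        swap <- sqrt((tb$x[jb1] - ta$x[ja0])^2 + (tb$y[jb1] - ta$y[ja0])^2) +
                sqrt((ta$x[ja1] - tb$x[jb0])^2 + (ta$y[ja1] - tb$y[jb0])^2)
        if (swap < keep) {
          sa <- ta[ta$frame > f1, ]; sb <- tb[tb$frame > f1, ]
          ta <- rbind(ta[ta$frame <= f1, ], sb)
          tb <- rbind(tb[tb$frame <= f1, ], sa)
          track_set$tracks[[a]]$states <- ta
          track_set$tracks[[b]]$states <- tb
          la <- max(ta$frame[ta$source == "detected"])
          lb <- max(tb$frame[tb$source == "detected"])
          track_set$tracks[[a]]$last_frame <- la
          track_set$tracks[[b]]$last_frame <- lb
          events <- rbind(events, data.frame(
            track_a = a - 1L, track_b = b - 1L, start = f0, end = f1,
            action = "swapped"))
        }
      }
    }
  }
  track_set$merge_events <- if (is.null(events)) {
    data.frame(track_a = integer(0), track_b = integer(0),
               start = integer(0), end = integer(0), action = character(0))
  } else events
  track_set
}
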