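# Tracking evaluation against ground truth: multiple-object tracking
# accuracy (MOTA) with the standard per-frame greedy matching and identity
# bookkeeping, plus a per-frame track retention curve.

# greedy one-to-one matching by ascending distance with per-ground-truth
# tolerance; returns matched index pairs
.match_greedy <- function(px, py, gx, gy, tol) {
  np <- length(px); ng <- length(gx)
  if (np == 0 || ng == 0) {
    return(cbind(pred = integer(0), gt = integer(0)))
  }
  tol <- rep_len(tol, ng)
  d <- sqrt(outer(px, gx, "-")^2 + outer(py, gy, "-")^2)
  ord <- order(d)
  used_p <- logical(np); used_g <- logical(ng)
  mp <- mg <- integer(0)
  for (k in ord) {
    i <- (k - 1) %% np + 1
    j <- (k - 1) %/% np + 1
    if (d[k] > tol[j]) next
    if (used_p[i] || used_g[j]) next
    used_p[i] <- TRUE; used_g[j] <- TRUE
    mp <- c(mp, i); mg <- c(mg, j)
  }
  cbind(pred = mp, gt = mg)
}

#' Multiple-object tracking accuracy
#'
#' Per frame, hypotheses are matched one-to-one to in-mask ground-truth
#' objects by ascending centroid distance, each ground-truth object
#' accepting matches within its own radius (`match_tol` overrides with a
#' global tolerance). A ground-truth object matched to a different track
#' identity than in its previous matched frame counts as an identity
#' switch (CLEAR convention). MOTA is
#' `1 - (sum FN + FP + IDSW) / (sum G_t)` with `G_t` the number of in-mask
#' ground-truth objects in frame t.
#'
#' @param gt data.frame with `cell_id`, `frame`, `x`, `y` and optionally
#'   `r` - ground-truth states, 0-based frames.
#' @param tracks data.frame with `cell_id`, `frame`, `x`, `y` - tracker
#'   output (e.g. [tracks_to_df()]).
#' @param match_tol Optional global matching tolerance in px; default is
#'   each ground-truth cell's own radius (5 px when `gt$r` is absent).
#' @param mask Optional [make_fov_mask()] object; ground-truth states
#'   outside the mask are excluded from `G_t` and from FN (not
#'   observable).
#' @return Object of class `mota_result`: list with `mota`, `fn`, `fp`,
#'   `id_switches`, `n_gt`, `per_frame` (data.frame `frame`, `fn`, `fp`,
#'   `idsw`, `g`).
#' @examples
#' gt <- data.frame(cell_id = 0, frame = 0:9, x = 1:10, y = 0, r = 3)
#' mota(gt, gt)$mota  # 1
#' @export
mota <- function(gt, tracks, match_tol = NULL, mask = NULL) {
  if (!is.null(mask)) {
    gt <- gt[contains_points(mask, cbind(gt$x, gt$y)), , drop = FALSE]
  }
  if (nrow(gt) == 0) stop("empty ground truth")
  frames <- sort(unique(c(gt$frame, tracks$frame)))
  gt_by <- split(seq_len(nrow(gt)), factor(gt$frame, levels = frames))
  tr_by <- split(seq_len(nrow(tracks)), factor(tracks$frame, levels = frames))
  last_id <- list()   # gt cell_id -> track cell_id of last match
  per <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    g <- gt[gt_by[[fi]], , drop = FALSE]
    h <- tracks[tr_by[[fi]], , drop = FALSE]
    tol <- if (!is.null(match_tol)) match_tol
           else if (!is.null(g$r)) g$r else 5
    m <- .match_greedy(h$x, h$y, g$x, g$y, tol)
    idsw <- 0L
    for (k in seq_len(nrow(m))) {
      gid <- as.character(g$cell_id[m[k, "gt"]])
      tid <- h$cell_id[m[k, "pred"]]
      prev <- last_id[[gid]]
      if (!is.null(prev) && prev != tid) idsw <- idsw + 1L
      last_id[[gid]] <- tid
    }
    per[[fi]] <- data.frame(frame = frames[fi], fn = nrow(g) - nrow(m),
                            fp = nrow(h) - nrow(m), idsw = idsw,
                            g = nrow(g))
  }
  per <- do.call(rbind, per)
  n_gt <- sum(per$g)
  structure(list(
    mota = 1 - (sum(per$fn) + sum(per$fp) + sum(per$idsw)) / n_gt,
    fn = sum(per$fn), fp = sum(per$fp), id_switches = sum(per$idsw),
    n_gt = n_gt, per_frame = per), class = "mota_result")
}

#' @export
print.mota_result <- function(x, ...) {
  cat(sprintf("mota_result: MOTA=%.5f (FN=%d FP=%d IDSW=%d over %d objects)\n",
              x$mota, x$fn, x$fp, x$id_switches, x$n_gt))
  invisible(x)
}

#' Track retention curve
#'
#' Fraction of initial tracks still successfully maintained at each frame:
#' the value at frame t is the share of tracks whose last successfully
#' associated (detected, not interpolated) frame is at least t, relative
#' to the initial track count. Monotone non-increasing, starts at 1.
#'
#' @param tracks A `track_set` (see [track_sequence()]) or a data.frame in
#'   [tracks_to_df()] layout (rows with `source == "detected"` count as
#'   associated; without a `source` column every state counts).
#' @param total_frames Sequence length; default the track set's.
#' @return data.frame with `frame` (0-based), `n_retained`, `fraction`.
#' @examples
#' # half the tracks end at T/2 -> curve steps 1 to 0.5 there
#' @export
retention_curve <- function(tracks, total_frames = NULL) {
  if (inherits(tracks, "track_set")) {
    if (is.null(total_frames)) total_frames <- tracks$total_frames
    last <- vapply(tracks$tracks, function(t) {
      max(t$states$frame[t$states$source == "detected"])
    }, numeric(1))
  } else {
    if (is.null(total_frames)) total_frames <- max(tracks$frame) + 1
    if (!is.null(tracks$source)) {
      tracks <- tracks[tracks$source == "detected", , drop = FALSE]
    }
    last <- tapply(tracks$frame, tracks$cell_id, max)
  }
  n0 <- length(last)
  if (n0 == 0) stop("no tracks")
  fr <- 0:(total_frames - 1)
  n_ret <- vapply(fr, function(t) sum(last >= t), integer(1))
  data.frame(frame = fr, n_retained = n_ret, fraction = n_ret / n0)
}
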