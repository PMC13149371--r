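#' Frequency-modulation schedule
#'
#' A piecewise description of the applied AC frequency over time: an ordered
#' list of contiguous, non-overlapping segments, each either static (constant
#' frequency) or a linear sweep. Segment membership uses the half-open
#' convention `[t_start, t_end)`; a query exactly on a boundary returns the
#' later segment's value, and the final end time is included.
#'
#' @param segments data.frame with columns `t_start`, `t_end` (seconds),
#'   `kind` ("static" or "sweep"), `f_start`, `f_end` (Hz). For static
#'   segments `f_end` may be `NA` and is set to `f_start`.
#' @param fps Acquisition frame rate (frames/s).
#' @return Object of class `freq_schedule`.
#' @seealso [dep_protocol()] for the default three-step measurement protocol.
#' @export
freq_schedule <- function(segments, fps = 10) {
  stopifnot(is.data.frame(segments), fps > 0,
            all(c("t_start", "t_end", "kind", "f_start") %in% names(segments)))
  if (is.null(segments$f_end)) segments$f_end <- NA_real_
  segments$f_end <- ifelse(segments$kind == "static",
                           segments$f_start, segments$f_end)
  segments <- segments[order(segments$t_start), , drop = FALSE]
  if (any(segments$t_end <= segments$t_start)) {
    stop("segments must have positive duration")
  }
  n <- nrow(segments)
  if (n > 1 && any(abs(segments$t_start[-1] - segments$t_end[-n]) > 1e-9)) {
    stop("segments must be contiguous and non-overlapping")
  }
  if (any(!is.finite(segments$f_start)) || any(!is.finite(segments$f_end)) ||
      any(segments$f_start <= 0) || any(segments$f_end <= 0)) {
    stop("frequencies must be positive and finite")
  }
  rownames(segments) <- NULL
  structure(list(segments = segments, fps = fps), class = "freq_schedule")
}

#' Default three-step DEP measurement protocol
#'
#' Builds the stimulation schedule used throughout the package: two
#' bracketing sweep steps and one static-frequency step, each preceded by
#' trap holds at 1 kHz (nDEP trap) or 41 kHz (pDEP trap).
#'
#' * Step 1: trap 1 kHz, sweep 1 to 41 kHz at +800 Hz/s; trap 41 kHz, sweep
#'   41 to 1 kHz at -800 Hz/s.
#' * Step 2: twelve trap/test pairs alternating nDEP and pDEP traps with
#'   static test frequencies 20, 1.0, 30, 1.5, 40, 2.0, 50, 2.5, 60, 3.0,
#'   70, 3.5 kHz.
#' * Step 3: repeats Step 1.
#'
#' Trap holds last `trap_s` and static tests `test_s`; the sweeps take 50 s
#' at 800 Hz/s. With the defaults the protocol spans exactly 1320 s, i.e.
#' 13,200 frames at 10 frames/s.
#'
#' @param trap_s Duration of each trap hold in seconds.
#' @param test_s Duration of each static test segment in seconds.
#' @param fps Frame rate.
#' @return A [freq_schedule()]; rows carry a `label` column naming the
#'   protocol step.
#' @export
dep_protocol <- function(trap_s = 40, test_s = 40, fps = 10) {
  rows <- list(); t0 <- 0
  add <- function(dur, f0, f1, kind, label) {
    rows[[length(rows) + 1]] <<- data.frame(
      t_start = t0, t_end = t0 + dur, kind = kind,
      f_start = f0, f_end = f1, label = label)
    t0 <<- t0 + dur
  }
  sweep_s <- (41e3 - 1e3) / 800
  sweep_step <- function(step) {
    add(trap_s, 1e3, 1e3, "static", paste0(step, "-trap-n"))
    add(sweep_s, 1e3, 41e3, "sweep", paste0(step, "-sweep-up"))
    add(trap_s, 41e3, 41e3, "static", paste0(step, "-trap-p"))
    add(sweep_s, 41e3, 1e3, "sweep", paste0(step, "-sweep-down"))
  }
  sweep_step("s1")
  tests <- c(20, 1.0, 30, 1.5, 40, 2.0, 50, 2.5, 60, 3.0, 70, 3.5) * 1e3
  traps <- rep(c(1e3, 41e3), 6)
  for (i in seq_along(tests)) {
    add(trap_s, traps[i], traps[i], "static", sprintf("s2-trap-%02d", i))
    add(test_s, tests[i], tests[i], "static", sprintf("s2-test-%02d", i))
  }
  sweep_step("s3")
  freq_schedule(do.call(rbind, rows), fps = fps)
}

#' Applied frequency at a time point
#'
#' @param schedule A [freq_schedule()].
#' @param t Time in seconds (vectorised); must lie within the schedule span.
#' @return Frequency in Hz. Static segments return their frequency; sweep
#'   segments interpolate linearly.
#' @examples
#' sch <- freq_schedule(data.frame(t_start = 0, t_end = 50, kind = "sweep",
#'                                 f_start = 1e3, f_end = 41e3))
#' freq_at(sch, 25)  # 21000
#' @export
freq_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "freq_schedule"))
  seg <- schedule$segments
  span <- c(seg$t_start[1], seg$t_end[nrow(seg)])
  if (any(t < span[1] - 1e-9) || any(t > span[2] + 1e-9)) {
    stop("time outside schedule span [", span[1], ", ", span[2], "]")
  }
  i <- findInterval(t, seg$t_start)       # half-open: boundary -> later segment
  i[i < 1] <- 1L
  frac <- (t - seg$t_start[i]) / (seg$t_end[i] - seg$t_start[i])
  frac <- pmin(frac, 1)
  seg$f_start[i] + (seg$f_end[i] - seg$f_start[i]) * frac
}

#' Number of frames spanned by a schedule
#' @param schedule A [freq_schedule()].
#' @return Integer frame count (duration times fps).
#' @export
schedule_n_frames <- function(schedule) {
  seg <- schedule$segments
  as.integer(round((seg$t_end[nrow(seg)] - seg$t_start[1]) * schedule$fps))
}

#' Frame indices of a schedule segment
#'
#' @param schedule A [freq_schedule()].
#' @param i Segment row index.
#' @return 0-based frame indices whose acquisition times fall inside the
#'   segment (half-open).
#' @export
segment_frames <- function(schedule, i) {
  seg <- schedule$segments[i, ]
  fps <- schedule$fps
  fr <- seq.int(ceiling(seg$t_start * fps - 1e-9), ceiling(seg$t_end * fps - 1e-9) - 1)
  fr[fr >= 0]
}

#' @export
print.freq_schedule <- function(x, ...) {
  cat("freq_schedule:", nrow(x$segments), "segments,",
      x$segments$t_end[nrow(x$segments)], "s at", x$fps, "fps (",
      schedule_n_frames(x), "frames )\n")
  invisible(x)
}
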