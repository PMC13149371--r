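# Crossover-frequency estimation from reconstructed trajectories, by two
# complementary routes:
#
# * Intensity route: a trapped cell's site is located by robust
#   (Mahalanobis-gated) clustering of its positions under a static trap
#   frequency; during the subsequent sweep the mean image intensity at the
#   site is monitored and the crossover is read off at the first frame
#   whose intensity deviates from the trapped baseline by more than
#   k_sigma standard deviations.
#
# * Velocity route: under static test frequencies, the signed velocity of
#   the cell crossing a ring region of nearly constant field gradient is
#   proportional to Re[CM](f) / k with mobility v / r^2; a four-parameter
#   logistic fitted to mobility vs frequency gives the zero crossing.

#' Robust trapped-site estimate from a trajectory window
#'
#' Iteratively fits a mean and covariance to the window positions,
#' discards points whose Mahalanobis distance exceeds the chi-square(2)
#' quantile `gate_p`, and refits until the inlier set is stable.
#'
#' @param track_states data.frame with `x`, `y` (states inside a
#'   static-frequency window; at least 10 rows).
#' @param gate_p Chi-square gate probability.
#' @param max_iter Iteration cap.
#' @return Object of class `trapped_site`: list with `center` (x, y),
#'   `covariance` (2 x 2), `gate` (Mahalanobis distance threshold),
#'   `n_used`, `valid`.
#' @export
trapped_site <- function(track_states, gate_p = 0.99, max_iter = 20) {
  P <- cbind(track_states$x, track_states$y)
  if (nrow(P) < 10) stop("trapped_site needs at least 10 states")
  gate <- stats::qchisq(gate_p, df = 2)
  keep <- rep(TRUE, nrow(P))
  for (it in seq_len(max_iter)) {
    mu <- colMeans(P[keep, , drop = FALSE])
    S <- stats::cov(P[keep, , drop = FALSE])
    # guard a degenerate (near-singular) covariance with a tiny ridge
    S_r <- S + diag(1e-9, 2)
    if (!all(is.finite(S_r)) || det(S_r) <= 0) {
      return(structure(list(center = mu, covariance = S, gate = sqrt(gate),
                            n_used = sum(keep), valid = FALSE),
                       class = "trapped_site"))
    }
    d2 <- stats::mahalanobis(P, mu, S_r)
    new_keep <- d2 <= gate
    if (!any(new_keep)) break
    if (identical(new_keep, keep)) {
      return(structure(list(center = mu, covariance = S, gate = sqrt(gate),
                            n_used = sum(keep), valid = TRUE),
                       class = "trapped_site"))
    }
    keep <- new_keep
  }
  structure(list(center = colMeans(P[keep, , drop = FALSE]),
                 covariance = stats::cov(P[keep, , drop = FALSE]),
                 gate = sqrt(gate), n_used = sum(keep), valid = FALSE),
            class = "trapped_site")
}

#' Mean intensity over a probe disc, per frame
#'
#' @param frame_source Either a `function(frame, window)` returning a pixel
#'   matrix for the requested crop (see [make_frame_source()]) or a list of
#'   full-frame matrices indexed by `frame + 1`.
#' @param site A [trapped_site()] (or list with `center`).
#' @param probe_radius Probe disc radius in px.
#' @param frames 0-based frame indices to probe.
#' @return Numeric vector of mean intensities (off-grid pixels excluded),
#'   named by frame.
#' @export
intensity_trace <- function(frame_source, site, probe_radius, frames) {
  cx <- site$center[1]; cy <- site$center[2]
  x0 <- floor(cx - probe_radius); x1 <- ceiling(cx + probe_radius)
  y0 <- floor(cy - probe_radius); y1 <- ceiling(cy + probe_radius)
  xs <- seq.int(x0, x1); ys <- seq.int(y0, y1)
  indisc <- outer((ys - cy)^2, (xs - cx)^2, "+") <= probe_radius^2
  is_fun <- is.function(frame_source)
  out <- vapply(frames, function(t) {
    patch <- if (is_fun) {
      frame_source(t, window = c(x0, x1, y0, y1))
    } else {
      fr <- frame_source[[t + 1]]
      ix <- xs[xs >= 0 & xs <= ncol(fr) - 1]
      iy <- ys[ys >= 0 & ys <= nrow(fr) - 1]
      p <- matrix(NA_real_, length(ys), length(xs))
      p[match(iy, ys), match(ix, xs)] <- fr[iy + 1, ix + 1]
      p
    }
    if (is_fun && !all(dim(patch) == c(length(ys), length(xs)))) {
      # frame source clipped the window at the image border: pad
      p <- matrix(NA_real_, length(ys), length(xs))
      ix <- xs[xs >= 0]; iy <- ys[ys >= 0]
      p[match(iy[seq_len(nrow(patch))], ys),
        match(ix[seq_len(ncol(patch))], xs)] <- patch
      patch <- p
    }
    mean(patch[indisc], na.rm = TRUE)
  }, numeric(1))
  names(out) <- frames
  out
}

#' Crossover frequency from a trapped-intensity trace
#'
#' The baseline mean and standard deviation are taken over
#' `baseline_frames` (typically the tail of the trap hold preceding the
#' sweep); the crossover is the applied frequency at the first sweep frame
#' whose absolute intensity deviation exceeds `k_sigma` baseline standard
#' deviations.
#'
#' @param trace Named numeric vector from [intensity_trace()] covering the
#'   baseline and the sweep frames.
#' @param schedule A [freq_schedule()].
#' @param baseline_frames 0-based frame indices of the baseline window.
#' @param sweep_frames 0-based frame indices of the sweep segment (in
#'   temporal order).
#' @param k_sigma Deviation threshold in baseline standard deviations.
#' @param min_run Number of consecutive frames the deviation must stay
#'   above threshold. A single-frame test at 3 sigma fires spuriously
#'   about once per 370 frames; a genuine departure is sustained, so
#'   requiring a short run removes noise triggers without adding lag (the
#'   first frame of the run is reported).
#' @return Object of class `fco_estimate`: list with `fco` (Hz or `NA`),
#'   `method = "intensity"`, `valid`, `diagnostics` (baseline stats and
#'   trigger frame).
#' @export
intensity_fco <- function(trace, schedule, baseline_frames, sweep_frames,
                          k_sigma = 3, min_run = 5) {
  bl <- trace[as.character(baseline_frames)]
  sw <- trace[as.character(sweep_frames)]
  mu <- mean(bl, na.rm = TRUE)
  sd0 <- stats::sd(bl, na.rm = TRUE)
  mk <- function(fco, valid, trigger) {
    structure(list(fco = fco, method = "intensity", valid = valid,
                   diagnostics = list(baseline_mean = mu, baseline_sd = sd0,
                                      trigger_frame = trigger,
                                      k_sigma = k_sigma)),
              class = "fco_estimate")
  }
  if (!is.finite(sd0) || sd0 == 0) return(mk(NA_real_, FALSE, NA_integer_))
  over <- abs(sw - mu) > k_sigma * sd0
  over[is.na(over)] <- FALSE
  r <- rle(over)
  runs <- which(r$values & r$lengths >= min_run)
  if (length(runs) == 0) return(mk(NA_real_, FALSE, NA_integer_))
  hit <- cumsum(r$lengths)[runs[1]] - r$lengths[runs[1]] + 1
  tf <- sweep_frames[hit]
  mk(freq_at(schedule, tf / schedule$fps), TRUE, tf)
}

#' Ring region for transit-velocity sampling
#'
#' An annulus in the hole interior, midway between the centre trap and the
#' rim, through which a cell released by a trap must transit. The band is
#' specified as fixed fractions of the hole radius; a wide band gives
#' multi-frame transits (a robust velocity sample), at the cost of some
#' field-gradient variation across it, which is reported as the
#' coefficient of variation diagnostic `grad_cv`.
#'
#' @param proxy A [field_proxy()].
#' @param hole 1-based hole index.
#' @param frac Inner and outer band radii as fractions of the hole radius.
#' @return Object of class `ring_region`: list with `center`, `r_in`,
#'   `r_out`, `rim_radius`, `grad_e2_ref`, `grad_cv`.
#' @export
select_ring <- function(proxy, hole = 1, frac = c(0.35, 0.65)) {
  stopifnot(length(frac) == 2, frac[1] > 0, frac[1] < frac[2], frac[2] < 1)
  lay <- proxy$layout
  R <- lay$hole_radius
  ctr <- lay$hole_centers[hole, ]
  gr <- function(rho) exp(-(rho - R)^2 / (2 * proxy$sigma_bump^2)) + proxy$floor
  rho <- seq(frac[1] * R, frac[2] * R, length.out = 25)
  v <- gr(rho)
  structure(list(center = c(x = unname(ctr[1]), y = unname(ctr[2])),
                 r_in = frac[1] * R, r_out = frac[2] * R, rim_radius = R,
                 grad_e2_ref = mean(v),
                 grad_cv = stats::sd(v) / mean(v)),
            class = "ring_region")
}

#' Signed transit velocity through a ring region
#'
#' The velocity is the least-squares slope of the cell's radial distance
#' from the hole centre over its in-ring states (equivalent to, but less
#' noise-sensitive than, the endpoint difference divided by the transit
#' time); the sign is positive when the cell moves towards the high-field
#' rim and negative towards the low-field interior.
#'
#' @param track_states data.frame with `frame`, `x`, `y` (already
#'   restricted to the segment of interest).
#' @param ring A [select_ring()] object (fields `center`, `r_in`, `r_out`,
#'   `rim_radius`).
#' @param fps Frame rate.
#' @return Signed velocity in px/s, or `NA` if the track never has two
#'   in-ring states (not crossing).
#' @export
ring_velocity <- function(track_states, ring, fps = 10) {
  rad <- sqrt((track_states$x - ring$center[["x"]])^2 +
              (track_states$y - ring$center[["y"]])^2)
  inr <- which(rad >= ring$r_in & rad <= ring$r_out)
  if (length(inr) < 2) return(NA_real_)
  tt <- track_states$frame[inr] / fps
  if (max(tt) - min(tt) <= 0) return(NA_real_)
  # slope of radial distance vs time: > 0 towards the high-field rim
  stats::cov(tt, rad[inr]) / stats::var(tt)
}

#' Re[CM] from a measured velocity (absolute units)
#'
#' Evaluates the drag/DEP force balance
#' `Re[CM] = 3 eta v / (r^2 eps_medium grad|E|^2)`.
#'
#' @param v Cell velocity, m/s (signed).
#' @param r_cell Cell radius, m.
#' @param eta Medium viscosity, Pa s.
#' @param eps_medium Absolute medium permittivity, F/m.
#' @param grad_e2 Gradient of the squared field, V^2/m^3.
#' @return Dimensionless Re\[CM\]; sign equals the sign of `v`.
#' @export
recm_from_velocity <- function(v, r_cell, eta, eps_medium, grad_e2) {
  if (any(c(r_cell, eta, eps_medium, grad_e2) <= 0)) {
    stop("r_cell, eta, eps_medium and grad_e2 must be positive")
  }
  3 * eta * v / (r_cell^2 * eps_medium * grad_e2)
}

#' Zero crossing of a mobility-frequency relation
#'
#' Fits the four-parameter logistic
#' `g(x) = L1 + (L2 - L1) / (1 + exp(-k (x - x0)))`
#' to mobility samples versus frequency (on a log10 frequency axis by
#' default) and returns its unique root. The fit is initialised from the
#' sign-change bracket of the samples.
#'
#' @param f Frequencies in Hz.
#' @param mobility Radius-normalised signed velocities `v / r^2`.
#' @param scale `"log"` (fit on log10 f; default) or `"linear"`.
#' @return Object of class `fco_estimate` with `method = "velocity"`,
#'   `fco` in Hz, `valid`, and fit diagnostics. Invalid when fewer than 4
#'   samples, when all samples share one sign, or when the fitted plateaus
#'   do not bracket zero.
#' @examples
#' f <- seq(5e3, 35e3, by = 2.5e3)
#' y <- -0.5 + 1.5 / (1 + exp(-0.2e-3 * (f - 20e3)))
#' fit_zero_crossing(f, y, scale = "linear")$fco  # 20e3 - log(2)/0.2e-3/1e3
#' @export
fit_zero_crossing <- function(f, mobility, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  ok <- is.finite(f) & is.finite(mobility)
  f <- f[ok]; mobility <- mobility[ok]
  mk <- function(fco, valid, diag = list()) {
    structure(list(fco = fco, method = "velocity", valid = valid,
                   diagnostics = diag),
              class = "fco_estimate")
  }
  if (length(f) < 4 || !any(mobility > 0) || !any(mobility < 0)) {
    return(mk(NA_real_, FALSE,
              list(reason = "need >= 4 samples spanning both signs")))
  }
  x <- if (scale == "log") log10(f) else f
  y <- mobility
  xn <- x[y < 0]; xp <- x[y > 0]
  x0i <- (max(xn) + min(xp)) / 2
  ki <- 4 / max(min(xp) - max(xn), diff(range(x)) / 50)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ L1 + (L2 - L1) / (1 + exp(-k * (x - x0))),
                      start = list(L1 = min(y), L2 = max(y), k = ki,
                                   x0 = x0i),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(mk(NA_real_, FALSE, list(reason = "fit failed")))
  p <- as.list(stats::coef(fit))
  if (p$L1 * p$L2 >= 0 || p$k <= 0) {
    return(mk(NA_real_, FALSE,
              list(reason = "no crossover in tested range", coef = p)))
  }
  xr <- p$x0 - log(-p$L2 / p$L1) / p$k    # analytic root of the logistic
  fco <- if (scale == "log") 10^xr else xr
  mk(fco, TRUE, list(coef = p, scale = scale, n = length(y),
                     rss = sum(stats::resid(fit)^2)))
}

#' Population summary of crossover estimates
#'
#' @param estimates data.frame with columns `fco`, `method`, `valid` (e.g.
#'   from [estimate_fco()]), or a list of `fco_estimate` objects.
#' @param breaks Histogram break specification (passed to [hist()]).
#' @return List keyed by method: `n_valid`, `n_invalid`, `mean`, `sd`,
#'   `median`, `iqr`, `hist` (counts and breaks).
#' @export
population_summary <- function(estimates, breaks = "Sturges") {
  if (!is.data.frame(estimates)) {
    estimates <- do.call(rbind, lapply(estimates, function(e) {
      data.frame(fco = e$fco, method = e$method, valid = e$valid)
    }))
  }
  out <- list()
  for (m in unique(estimates$method)) {
    sub <- estimates[estimates$method == m, ]
    v <- sub$fco[sub$valid & is.finite(sub$fco)]
    h <- if (length(v) > 0) {
      hh <- graphics::hist(v, breaks = breaks, plot = FALSE)
      list(counts = hh$counts, breaks = hh$breaks)
    } else list(counts = integer(0), breaks = numeric(0))
    out[[m]] <- list(
      n_valid = length(v), n_invalid = nrow(sub) - length(v),
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) stats::sd(v) else 0,
      median = if (length(v)) stats::median(v) else NA_real_,
      iqr = if (length(v)) stats::IQR(v) else NA_real_,
      hist = h)
  }
  out
}

#' Crossover frequency of one cell via the trapped-intensity route
#'
#' For every sweep segment of the schedule that is preceded by a static
#' trap hold, the cell's trapped site is located from its positions in the
#' last `baseline_n` frames of the hold, the probe-disc intensity is traced
#' through the hold tail and the sweep, and the departure frequency is read
#' off with [intensity_fco()]. The reported crossover is the mean over the
#' per-sweep estimates (up- and down-sweep trigger biases largely cancel).
#'
#' @param track_states data.frame with `frame`, `x`, `y` and (optionally)
#'   `r` for one cell, covering the schedule span.
#' @param frame_source `function(frame, window)` returning pixel crops, as
#'   built by [make_frame_source()], or a list of full frames.
#' @param schedule A [freq_schedule()] whose segments carry `kind`.
#' @param probe_radius Probe disc radius in px; default the median track
#'   radius (or 8 px without a radius column). A probe larger than the
#'   cell is insensitive: the disc mean only changes once the cell starts
#'   leaving the disc, which delays the trigger by several px of travel.
#' @param k_sigma Trigger threshold in baseline standard deviations.
#' @param min_run Trigger persistence in frames (see [intensity_fco()]).
#' @param baseline_n Trap-hold tail length (frames) used as baseline.
#' @return `fco_estimate` (`method = "intensity"`); `diagnostics$sweeps`
#'   holds the per-sweep estimates.
#' @export
estimate_fco_intensity <- function(track_states, frame_source, schedule,
                                   probe_radius = NULL, k_sigma = 3,
                                   min_run = 5, baseline_n = 50) {
  seg <- schedule$segments
  sweeps <- which(seg$kind == "sweep")
  sweeps <- sweeps[sweeps > 1 & seg$kind[pmax(sweeps - 1, 1)] == "static"]
  if (length(sweeps) == 0) stop("schedule has no trap-then-sweep pair")
  if (is.null(probe_radius)) {
    probe_radius <- if (!is.null(track_states$r)) {
      stats::median(track_states$r)
    } else 8
  }
  per <- lapply(sweeps, function(i) {
    bl <- utils::tail(segment_frames(schedule, i - 1), baseline_n)
    sw <- segment_frames(schedule, i)
    st <- track_states[track_states$frame %in% bl, , drop = FALSE]
    if (nrow(st) < 10) return(NULL)
    site <- trapped_site(st)
    tr <- intensity_trace(frame_source, site, probe_radius, c(bl, sw))
    est <- intensity_fco(tr, schedule, bl, sw, k_sigma = k_sigma,
                         min_run = min_run)
    list(segment = i, site = site, estimate = est)
  })
  per <- Filter(Negate(is.null), per)
  vals <- vapply(per, function(p) p$estimate$fco, numeric(1))
  ok <- vapply(per, function(p) p$estimate$valid, logical(1))
  structure(list(fco = if (any(ok)) mean(vals[ok]) else NA_real_,
                 method = "intensity", valid = any(ok),
                 diagnostics = list(sweeps = per, n_sweeps_used = sum(ok),
                                    probe_radius = probe_radius,
                                    k_sigma = k_sigma)),
            class = "fco_estimate")
}

#' Crossover frequency of one cell via the transit-velocity route
#'
#' For every static test segment the signed ring-transit velocity of the
#' cell is measured with [ring_velocity()], normalised by the squared cell
#' radius into a mobility, and the mobility-frequency relation is fitted
#' with [fit_zero_crossing()].
#'
#' @param track_states data.frame with `frame`, `x`, `y`, `r` for one cell.
#' @param schedule A [freq_schedule()].
#' @param ring A [select_ring()] region (the cell's home electrode hole).
#' @param segments Static segment row indices to sample; default: segments
#'   labelled `"test"` when a `label` column exists, else every static
#'   segment.
#' @param scale Frequency axis for the logistic fit (see
#'   [fit_zero_crossing()]).
#' @return `fco_estimate` (`method = "velocity"`); `diagnostics$samples`
#'   holds the (frequency, mobility) pairs.
#' @export
estimate_fco_velocity <- function(track_states, schedule, ring,
                                  segments = NULL, scale = "log") {
  seg <- schedule$segments
  if (is.null(segments)) {
    segments <- if (!is.null(seg$label)) {
      which(seg$kind == "static" & grepl("test", seg$label))
    } else integer(0)
    if (length(segments) == 0) segments <- which(seg$kind == "static")
  }
  r_track <- stats::median(track_states$r)
  if (!is.finite(r_track) || r_track <= 0) {
    stop("track needs a positive median radius for mobility normalisation")
  }
  sam <- do.call(rbind, lapply(segments, function(i) {
    fr <- segment_frames(schedule, i)
    st <- track_states[track_states$frame %in% fr, , drop = FALSE]
    if (nrow(st) < 2) return(NULL)
    v <- ring_velocity(st, ring, fps = schedule$fps)
    if (!is.finite(v)) return(NULL)
    data.frame(segment = i, f = seg$f_start[i], v = v,
               mobility = v / r_track^2)
  }))
  if (is.null(sam) || nrow(sam) < 4) {
    return(structure(list(fco = NA_real_, method = "velocity", valid = FALSE,
                          diagnostics = list(samples = sam,
                                             reason = "fewer than 4 ring transits")),
                     class = "fco_estimate"))
  }
  est <- fit_zero_crossing(sam$f, sam$mobility, scale = scale)
  est$diagnostics$samples <- sam
  est
}

#' @export
print.fco_estimate <- function(x, ...) {
  cat(sprintf("fco_estimate (%s): %s\n", x$method,
              if (x$valid) sprintf("%.1f Hz", x$fco) else "invalid"))
  invisible(x)
}
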