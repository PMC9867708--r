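#' Detrend a luminescence trace
#'
#' Removes the slow baseline with a centered moving average of width
#' `window` (default 24 h, one full cycle, so the oscillation itself
#' averages out of the baseline). Returns both the subtracted trace (used
#' for amplitudes) and the ratio trace `counts / baseline` ("relative
#' luminescence", the conventional display for destabilized-luciferase
#' reporters). Half a window at each end has no centered average and is
#' flagged as edge, unless `extend_edges` fills it in: the interior
#' moving average — already free of the oscillation — is extrapolated into
#' the edges by a quadratic fitted to it, which trades a little baseline
#' bias at the extremes for a usable full-length trace. Segment-based
#' estimators (see [treatment_phase_shift()]) rely on this to avoid losing
#' half a window of every short segment.
#'
#' @param trace a [luminescence_trace].
#' @param window moving-average width, hours; must exceed `2 * dt`.
#' @param extend_edges fill the edge baseline by quadratic extrapolation of
#'   the interior moving average and clear the edge mask (default FALSE).
#' @return A `detrended_trace` list: `t`, `counts`, `baseline`, `detrended`,
#'   `relative`, `edge` (logical), `dt`.
#' @export
detrend_trace <- function(trace, window = 24, extend_edges = FALSE) {
  stopifnot(inherits(trace, "luminescence_trace"))
  dt <- trace$dt
  if (window <= 2 * dt) stop("window must exceed 2 * dt")
  if (max(trace$t) - min(trace$t) < window)
    stop("trace shorter than the detrending window")
  k <- round(window / dt)
  if (k %% 2 == 0) k <- k + 1   # centered average needs an odd width
  ma <- as.numeric(stats::filter(trace$counts, rep(1 / k, k), sides = 2))
  edge <- is.na(ma)
  if (extend_edges && any(edge)) {
    X <- cbind(1, trace$t, trace$t^2)
    co <- stats::lm.fit(X[!edge, , drop = FALSE], ma[!edge])$coefficients
    ma[edge] <- as.numeric(X[edge, , drop = FALSE] %*% co)
    edge[] <- FALSE
  }
  structure(list(t = trace$t, counts = trace$counts, baseline = ma,
                 detrended = trace$counts - ma,
                 relative = trace$counts / ma,
                 edge = edge, dt = dt),
            class = "detrended_trace")
}

#' Detect oscillation peaks in a detrended trace
#'
#' Boxcar-smooths the detrended trace (2 h by default, enough to suppress
#' 10-min sampling noise without displacing 22-24-h peaks) and takes local
#' maxima separated by at least `min_separation`; when two candidates fall
#' within `min_separation` the higher is kept (ties go to the earlier one).
#' The first `exclude_before` hours are dropped from the statistics: the
#' trace is transient right after synchronization.
#'
#' Each raw maximum is then refined to sub-sample precision:
#' \describe{
#'   \item{cosine (default)}{a fixed-period cosine with first-order damping
#'     terms (`tau cos`, `tau sin`, the linearization of an exponentially
#'     decaying envelope) is least-squares fitted over up to one cycle each
#'     side of the raw peak, and the local acrophase is the refined peak.
#'     This pools a full cycle of samples per peak, so peak times stay
#'     accurate at 10-min sampling even with noise at 10-20\% of the
#'     oscillation amplitude. Peaks whose usable (non-edge) window is
#'     shorter than `min_window_frac` of a half cycle on either side cannot
#'     be refined reliably and are dropped;
#'     [estimate_period_amplitude()] accounts for any skipped cycle.}
#'   \item{quadratic}{least-squares parabola over `refine_halfwidth` hours
#'     around the raw maximum (a cosine is locally quadratic).}
#'   \item{none}{raw sample times of the smoothed maxima.}
#' }
#'
#' @param x a `detrended_trace` from [detrend_trace()].
#' @param min_separation minimum peak spacing, hours (default 18, safely
#'   below one circadian cycle); must be at least `2 * dt`.
#' @param smooth_window boxcar width for pre-smoothing, hours.
#' @param exclude_before drop peaks earlier than this, hours (default 12).
#' @param refine refinement method, see above.
#' @param refine_halfwidth half width of the quadratic refinement window,
#'   hours.
#' @param min_window_frac minimum usable fraction of a half cycle per side
#'   for cosine refinement.
#' @return Numeric vector of refined peak times, hours, increasing.
#' @export
detect_peaks <- function(x, min_separation = 18, smooth_window = 2,
                         exclude_before = 12,
                         refine = c("cosine", "quadratic", "none"),
                         refine_halfwidth = 3, min_window_frac = 0.75) {
  refine <- match.arg(refine)
  stopifnot(inherits(x, "detrended_trace"))
  dt <- x$dt
  if (min_separation < 2 * dt) stop("min_separation must be at least 2 * dt")
  k <- max(1, round(smooth_window / dt))
  if (k %% 2 == 0) k <- k + 1
  s <- if (k > 1) as.numeric(stats::filter(x$detrended, rep(1 / k, k), sides = 2))
       else x$detrended
  s[x$edge] <- NA
  n <- length(s)
  cand <- which(!is.na(s[-c(1, n)]) & !is.na(s[-c(n - 1, n)]) & !is.na(s[-c(1, 2)]) &
                s[-c(1, n)] > s[-c(n - 1, n)] & s[-c(1, n)] >= s[-c(1, 2)]) + 1L
  cand <- cand[x$t[cand] >= exclude_before]
  if (length(cand) == 0) return(numeric(0))
  # enforce separation: keep by height, tie -> earlier
  o <- order(-s[cand], x$t[cand])
  kept <- integer(0)
  for (i in cand[o]) {
    if (all(abs(x$t[i] - x$t[kept]) >= min_separation)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  raw <- x$t[kept]
  if (refine == "none" || length(kept) == 0) return(raw)
  if (refine == "quadratic") {
    # least-squares quadratic vertex around each raw maximum
    ref_q <- function(i) {
      win <- which(abs(x$t - x$t[i]) <= refine_halfwidth & !is.na(s))
      if (length(win) < 5) return(x$t[i])
      tt <- x$t[win] - x$t[i]
      co <- stats::lm.fit(cbind(1, tt, tt^2), s[win])$coefficients
      if (!is.finite(co[3]) || co[3] >= 0) return(x$t[i])
      vertex <- -co[2] / (2 * co[3])
      x$t[i] + max(-refine_halfwidth, min(refine_halfwidth, vertex))
    }
    return(vapply(kept, ref_q, numeric(1)))
  }
  # cosine refinement: local acrophase of a fixed-period fit with
  # first-order damping regressors, over a symmetric window
  P0 <- if (length(raw) >= 2) mean(diff(raw)) else 24
  w <- 2 * pi / P0
  ok <- which(!x$edge)
  lo <- x$t[ok[1]]; hi <- x$t[ok[length(ok)]]
  out <- vapply(raw, function(p0) {
    hw <- min(P0, p0 - lo, hi - p0)
    if (hw < min_window_frac * P0 / 2) return(NA_real_)
    win <- which(abs(x$t - p0) <= hw & !x$edge)
    tau <- x$t[win] - p0
    X <- cbind(1, cos(w * x$t[win]), sin(w * x$t[win]),
               tau * cos(w * x$t[win]), tau * sin(w * x$t[win]))
    b <- stats::lm.fit(X, x$detrended[win])$coefficients
    if (any(!is.finite(b[2:3])) || (b[2] == 0 && b[3] == 0)) return(p0)
    phi <- atan2(b[3], b[2]) / w
    phi + round((p0 - phi) / P0) * P0
  }, numeric(1))
  out[!is.na(out)]
}

#' Period and per-cycle amplitude from detected peaks
#'
#' Period is the mean interval between successive peaks. When a peak was
#' dropped during refinement (see [detect_peaks()]) an interval can span
#' more than one cycle; each interval's cycle count is inferred from the
#' median spacing, so the estimate is total elapsed time over total cycles.
#' When the detrended trace is supplied, each cycle's amplitude is half the
#' distance from the peak to the following trough (the detrended minimum
#' before the next peak), which tracks amplitude decay cycle by cycle in
#' damped recordings.
#'
#' @param peaks increasing peak times, hours (>= 2).
#' @param x optional `detrended_trace` for amplitude estimation.
#' @return A `trace_rhythm` list: `period`, `peak_times`, `amplitudes`
#'   (NULL without `x`), `n_peaks`.
#' @examples
#' estimate_period_amplitude(c(10, 32, 54))$period   # 22
#' @export
estimate_period_amplitude <- function(peaks, x = NULL) {
  if (length(peaks) < 2) stop("period estimation needs at least 2 peaks")
  if (is.unsorted(peaks, strictly = TRUE)) stop("peaks must be strictly increasing")
  d <- diff(peaks)
  cycles <- pmax(1, round(d / stats::median(d)))
  period <- sum(d) / sum(cycles)
  amplitudes <- NULL
  if (!is.null(x)) {
    stopifnot(inherits(x, "detrended_trace"))
    amplitudes <- numeric(0)
    for (i in seq_len(length(peaks) - 1)) {
      seg <- which(x$t >= peaks[i] & x$t <= peaks[i + 1] & !x$edge)
      if (length(seg) < 3) next
      ip <- which.min(abs(x$t - peaks[i]))
      amplitudes <- c(amplitudes, (x$detrended[ip] - min(x$detrended[seg])) / 2)
    }
  }
  structure(list(period = period, peak_times = peaks,
                 amplitudes = amplitudes, n_peaks = length(peaks)),
            class = "trace_rhythm")
}

#' Treatment-induced phase shift from peak times
#'
#' Fits the free-running rhythm from the peak spacings, extrapolates the
#' expected post-treatment peak times from the last pre-treatment peak, and
#' reports the circular difference between observed and expected
#' post-treatment peaks. The treatment is modeled as a pure phase reset:
#' the period is assumed unchanged, so intervals on both sides of the
#' treatment (never across it) are pooled into the period estimate, and the
#' per-peak shifts are combined by a circular mean. Negative shift = phase
#' advance (observed peak earlier than expected); an exactly antiphase
#' shift is reported as `+period/2` with the antiphase flag.
#'
#' @param peaks detected peak times, hours.
#' @param treatment_time hours; >= 2 peaks before it and >= 1 after it are
#'   required.
#' @return A list: `shift_h`, `antiphase`, `pre_period` (the pooled period
#'   estimate), `expected_peak`, `observed_peak` (first post-treatment).
#' @examples
#' phase_shift_from_peaks(c(20, 44, 58), treatment_time = 48)$shift_h  # -10
#' @export
phase_shift_from_peaks <- function(peaks, treatment_time) {
  pre <- peaks[peaks < treatment_time]
  post <- peaks[peaks >= treatment_time]
  if (length(pre) < 2) stop("need at least 2 pre-treatment peaks")
  if (length(post) < 1) stop("need at least 1 post-treatment peak")
  d <- c(diff(pre), if (length(post) >= 2) diff(post))
  period <- sum(d) / sum(pmax(1, round(d / stats::median(d))))
  # anchor the extrapolation on the least-squares line through the
  # pre-treatment peaks, averaging their individual timing errors
  kpre <- round((pre - pre[1]) / period)
  last_pre <- mean(pre - kpre * period) + kpre[length(kpre)] * period
  k <- pmax(1, round((post - last_pre) / period))
  expected <- last_pre + k * period
  sh <- circular_phase_shift(expected, post, period = period)
  ang <- 2 * pi * sh$shift_h / period
  shift <- atan2(mean(sin(ang)), mean(cos(ang))) * period / (2 * pi)
  # fold the circular mean back into (-period/2, period/2]
  shift <- ((shift + period / 2) %% period) - period / 2
  antiphase <- FALSE
  if (shift == -period / 2) { shift <- period / 2; antiphase <- TRUE }
  list(shift_h = shift, antiphase = antiphase || shift == period / 2,
       pre_period = period, expected_peak = expected[1],
       observed_peak = post[1])
}

# refine raw peak times by the acrophase of a pure fixed-period cosine
# fitted over the largest symmetric window that fits inside the usable
# (non-edge) span; peaks with under min_halfwidth of symmetric data are
# dropped — a phase fitted on a sliver of a cycle is worse than no peak.
# No damping regressors: in sub-cycle windows they are collinear with the
# sine term and would blow up the phase variance.
refine_cosine_local <- function(x, raw, period, min_halfwidth = 3) {
  if (length(raw) == 0) return(raw)
  ok <- which(!x$edge)
  lo <- x$t[ok[1]]; hi <- x$t[ok[length(ok)]]
  w <- 2 * pi / period
  out <- vapply(raw, function(p0) {
    hw <- min(period / 2, p0 - lo, hi - p0)
    if (hw < min_halfwidth) return(NA_real_)
    win <- which(abs(x$t - p0) <= hw & !x$edge)
    b <- stats::lm.fit(cbind(1, cos(w * x$t[win]), sin(w * x$t[win])),
                       x$detrended[win])$coefficients
    if (any(!is.finite(b[2:3])) || (b[2] == 0 && b[3] == 0)) return(p0)
    phi <- atan2(b[3], b[2]) / w
    refined <- phi + round((p0 - phi) / period) * period
    # a refinement that teleports the peak a quarter cycle away is not a
    # refinement of this maximum but a spurious candidate: drop it
    if (abs(refined - p0) > period / 4) return(NA_real_)
    refined
  }, numeric(1))
  out[!is.na(out)]
}

#' Treatment phase shift straight from a raw trace
#'
#' Pipeline: [detrend_trace()] + [detect_peaks()] +
#' [phase_shift_from_peaks()]. The trace is split at `treatment_time` and
#' each side is detrended on its own — a moving-average baseline computed
#' across the perturbation would smear the phase jump into the neighboring
#' cycles and bias the peaks on both sides. Each segment is detrended with
#' `extend_edges = TRUE` so no samples are lost to edge masking, and peak
#' times are refined by the acrophase of a local fixed-period cosine fit
#' over the largest symmetric window that fits the segment, which keeps
#' sub-hour accuracy on segments only a couple of cycles long.
#'
#' @param trace a [luminescence_trace].
#' @param treatment_time hours.
#' @param window,min_separation,smooth_window,exclude_before passed through.
#' @return As [phase_shift_from_peaks()], plus `peaks`.
#' @export
treatment_phase_shift <- function(trace, treatment_time, window = 24,
                                  min_separation = 18, smooth_window = 2,
                                  exclude_before = 12) {
  pre_idx <- trace$t < treatment_time
  if (sum(pre_idx) < 3 || sum(!pre_idx) < 3)
    stop("treatment_time must fall inside the recording")
  pre <- luminescence_trace(trace$t[pre_idx], trace$counts[pre_idx])
  post <- luminescence_trace(trace$t[!pre_idx], trace$counts[!pre_idx])
  dpre <- detrend_trace(pre, window = window, extend_edges = TRUE)
  dpost <- detrend_trace(post, window = window, extend_edges = TRUE)
  raw_pre <- detect_peaks(dpre, min_separation = min_separation,
                          smooth_window = smooth_window,
                          exclude_before = exclude_before, refine = "none")
  raw_post <- detect_peaks(dpost, min_separation = min_separation,
                           smooth_window = smooth_window,
                           exclude_before = treatment_time + 2,
                           refine = "none")
  d0 <- c(diff(raw_pre), diff(raw_post))
  period0 <- if (length(d0) > 0) mean(d0) else 24
  pre_peaks <- refine_cosine_local(dpre, raw_pre, period0)
  post_peaks <- refine_cosine_local(dpost, raw_post, period0)
  # refined peaks must stay inside their own segment
  peaks <- c(pre_peaks[pre_peaks < treatment_time],
             post_peaks[post_peaks >= treatment_time])
  out <- phase_shift_from_peaks(peaks, treatment_time)
  out$peaks <- peaks
  out
}
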