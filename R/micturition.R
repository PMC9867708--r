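#' Fit the stain-area to volume standard curve
#'
#' Ordinary least squares of voided volume on stained area, the calibration
#' used to convert aVSOP stains (filter-paper urine marks) to microliters.
#' Calibration pairs should span the 10-800 ul working range. A fit with
#' r^2 below `r2_min` (default 0.9) is refused: a poor standard curve
#' corrupts every downstream volume.
#'
#' @param pairs data frame with columns `area_cm2` and `volume_ul` (or two
#'   unnamed columns in that order).
#' @param r2_min minimum acceptable r^2.
#' @return A `standard_curve` list: `slope` (ul/cm^2), `intercept` (ul),
#'   `r2`, `valid_range` (= c(10, 800) ul), `n`.
#' @examples
#' fit_standard_curve(simulate_calibration_pairs(slope = 5, n = 10))
#' @export
fit_standard_curve <- function(pairs, r2_min = 0.9) {
  if (!all(c("area_cm2", "volume_ul") %in% names(pairs))) {
    if (ncol(pairs) < 2) stop("calibration needs (area, volume) pairs")
    names(pairs)[1:2] <- c("area_cm2", "volume_ul")
  }
  if (nrow(pairs) < 2) stop("at least 2 calibration pairs are required")
  if (stats::var(pairs$area_cm2) == 0)
    stop("calibration areas are all identical; the curve is undefined")
  fit <- stats::lm(volume_ul ~ area_cm2, data = pairs)
  tss <- sum((pairs$volume_ul - mean(pairs$volume_ul))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(stats::residuals(fit)^2) / tss
  if (r2 < r2_min)
    stop(sprintf("standard curve r^2 = %.3f is below the acceptance threshold %.2f; recalibrate", r2, r2_min))
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("standard curve slope must be positive")
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, valid_range = c(10, 800), n = nrow(pairs)),
            class = "standard_curve")
}

#' Convert raw stains to time-stamped void events
#'
#' Stain position along the paper encodes time (the paper advances at
#' `paper_speed`, 10 cm/h by default) and stain area encodes volume via the
#' standard curve. Volumes outside the curve's 10-800 ul calibration range
#' are flagged `extrapolated` but retained.
#'
#' @param raw data frame with columns `position_cm` and `area_cm2`
#'   (optionally `subject`).
#' @param curve a `standard_curve`.
#' @param paper_speed cm/h, default 10.
#' @param start_zt ZT hours at paper start, default 14 (dark onset).
#' @return A data frame of events: `t_h` (hours after start), `zt`,
#'   `volume_ul`, `extrapolated`, plus any `subject` column; attribute
#'   `start_zt` records the time origin.
#' @export
stain_to_event <- function(raw, curve, paper_speed = 10, start_zt = 14) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!all(c("position_cm", "area_cm2") %in% names(raw)))
    stop("raw stains need columns position_cm and area_cm2")
  if (paper_speed <= 0) stop("paper_speed must be positive")
  if (any(raw$position_cm < 0)) stop("stain positions must be non-negative")
  if (any(raw$area_cm2 < 0)) stop("stain areas must be non-negative")
  t_h <- raw$position_cm / paper_speed
  vol <- curve$slope * raw$area_cm2 + curve$intercept
  out <- data.frame(t_h = t_h, zt = (start_zt + t_h) %% 24, volume_ul = vol,
                    extrapolated = vol < curve$valid_range[1] |
                                   vol > curve$valid_range[2])
  if ("subject" %in% names(raw)) out$subject <- raw$subject
  out <- out[order(out$t_h), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "start_zt") <- start_zt
  out
}

#' 8-h bin layout anchored to dark onset
#'
#' The default bins tile the day in three 8-h windows of +/- `half_width`
#' hours around ZT14 (dark onset), ZT22 and ZT6: [ZT10, 18), [ZT18, 2) and
#' [ZT2, 10). Bins are half-open on the right, so an event exactly on an
#' edge belongs to the later bin.
#'
#' @param centers bin centers, ZT hours.
#' @param half_width hours each side of a center.
#' @return A `bin_spec` list with `centers`, `half_width`, `labels`.
#' @export
bin_spec <- function(centers = c(14, 22, 6), half_width = 4) {
  if (half_width <= 0) stop("half_width must be positive")
  centers <- centers %% 24
  lo <- (centers - half_width) %% 24
  width <- 2 * half_width
  if (length(centers) > 1) {
    # reject overlapping windows on the circle
    for (i in seq_along(centers)) for (j in seq_along(centers)) {
      if (i == j) next
      d <- abs(((centers[i] - centers[j] + 12) %% 24) - 12)
      if (d < width) stop("bins overlap")
    }
  }
  structure(list(centers = centers, half_width = half_width,
                 lower = lo, labels = paste0("ZT", centers)),
            class = "bin_spec")
}

#' Assign void events to diurnal bins and days
#'
#' Each event's ZT is placed in the bin whose half-open window contains it;
#' events falling outside every bin (possible with non-tiling custom bins)
#' get `NA`. Days are counted from dark onset (ZT14): the behavioral day of
#' a nocturnal animal starts when the lights go out, which is also where the
#' summaries are graphed from.
#'
#' @param events data frame with `t_h` and either `zt` or attribute
#'   `start_zt` (as produced by [stain_to_event()] or
#'   [simulate_void_events()]).
#' @param bins a [bin_spec].
#' @param cycle a [light_cycle]; its dark onset anchors the day counter.
#' @param start_zt recording-start ZT; taken from the events attribute when
#'   absent.
#' @return The events with `bin` (factor) and `day` (integer, 1-based from
#'   the first dark onset) columns added.
#' @export
bin_events <- function(events, bins = bin_spec(), cycle = light_cycle(),
                       start_zt = attr(events, "start_zt")) {
  stopifnot(inherits(bins, "bin_spec"))
  if (is.null(start_zt)) stop("start_zt is needed to place events in ZT")
  zt <- if ("zt" %in% names(events)) events$zt else (start_zt + events$t_h) %% 24
  width <- 2 * bins$half_width
  lab <- rep(NA_character_, length(zt))
  for (b in seq_along(bins$centers)) {
    off <- (zt - bins$lower[b]) %% 24
    lab[off >= 0 & off < width] <- bins$labels[b]
  }
  abs_zt <- start_zt + events$t_h
  day <- floor((abs_zt - cycle$dark_onset_zt) / 24) + 1L
  out <- events
  out$zt <- zt
  out$bin <- factor(lab, levels = bins$labels)
  out$day <- as.integer(day)
  attr(out, "start_zt") <- start_zt
  attr(out, "bin_spec") <- bins
  out
}

#' Per-bin micturition summary
#'
#' For every (subject x) day x bin cell: number of voids, total voided
#' volume, mean volume per micturition, and voided volume per hour (total
#' divided by the bin width — the elapsed time when recording is complete).
#' Empty cells are kept with `n = 0` and `NA` means so they are visibly
#' flagged rather than silently dropped.
#'
#' @param events binned events from [bin_events()].
#' @param bin_width_h denominator for volume per hour; defaults to the bin
#'   width of the attached [bin_spec] (8 h for the defaults).
#' @return A data frame: (`subject`,) `day`, `bin`, `n_voids`, `total_ul`,
#'   `mean_ul_per_void`, `ul_per_h`, `empty`.
#' @export
summarize_bins <- function(events, bin_width_h = NULL) {
  if (!all(c("bin", "day") %in% names(events)))
    stop("events must be binned first (see bin_events)")
  bins <- attr(events, "bin_spec")
  if (is.null(bin_width_h))
    bin_width_h <- if (is.null(bins)) 8 else 2 * bins$half_width
  has_subject <- "subject" %in% names(events)
  key <- if (has_subject)
    list(subject = events$subject, day = events$day, bin = events$bin)
  else list(day = events$day, bin = events$bin)
  grid <- expand.grid(lapply(rev(key), function(x) sort(unique(x))),
                      stringsAsFactors = FALSE)
  names(grid) <- rev(names(key))
  grid <- grid[, names(key), drop = FALSE]
  agg_n <- stats::aggregate(events$volume_ul, by = key, FUN = length)
  agg_s <- stats::aggregate(events$volume_ul, by = key, FUN = sum)
  m <- merge(grid, cbind(agg_n[names(key)], n_voids = agg_n$x,
                         total_ul = agg_s$x),
             by = names(key), all.x = TRUE)
  m$n_voids[is.na(m$n_voids)] <- 0L
  m$total_ul[is.na(m$total_ul)] <- 0
  m$mean_ul_per_void <- ifelse(m$n_voids > 0, m$total_ul / m$n_voids, NA_real_)
  m$ul_per_h <- m$total_ul / bin_width_h
  m$empty <- m$n_voids == 0
  o <- do.call(order, m[names(key)])
  m <- m[o, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Normalize bin summaries to a reference bin
#'
#' Expresses each bin's mean volume per micturition as a ratio to the same
#' subject-day's reference bin (ZT6, mid light phase, by default), so the
#' reference is identically 1 and the dark-phase drop in functional bladder
#' capacity appears as ratios below 1.
#'
#' @param summary data frame from [summarize_bins()].
#' @param reference_bin bin label, default `"ZT6"`.
#' @return The summary with a `ratio` column added.
#' @export
normalize_to_reference <- function(summary, reference_bin = "ZT6") {
  if (!reference_bin %in% as.character(summary$bin))
    stop("reference bin ", reference_bin, " not present in the summary")
  has_subject <- "subject" %in% names(summary)
  key <- if (has_subject) interaction(summary$subject, summary$day)
         else factor(summary$day)
  ref_rows <- summary$bin == reference_bin
  ref_val <- summary$mean_ul_per_void[ref_rows]
  names(ref_val) <- as.character(key[ref_rows])
  if (anyNA(ref_val) || any(ref_val == 0))
    stop("empty reference bin: ratios are undefined for at least one subject-day")
  summary$ratio <- summary$mean_ul_per_void / ref_val[as.character(key)]
  summary
}

#' Recover the capacity modulation fraction from a bin ratio
#'
#' Inverts the bladder model behind [simulate_void_events()]. With capacity
#' `C(zt) = mesor * (1 + m * cos(2*pi*(zt - acrophase)/24))` and production
#' rate `P(zt)`, voids occur at rate `P/C`, so the expected volume per void
#' within a bin is the production-weighted harmonic mean of capacity,
#' `int(P) / int(P/C)` over the bin. The ratio of this expectation between
#' the test and reference bins is monotone in `m`; the function solves for
#' `m` numerically. The production modulation must be supplied (the
#' simulator defaults are assumed) because a diurnal production rhythm
#' skews when voids sample the capacity curve.
#'
#' @param ratio observed mean-volume-per-void ratio (test / reference).
#' @param bin_center,reference_center ZT hours (defaults 14 and 6).
#' @param capacity_acrophase ZT hours of peak capacity (default 6).
#' @param half_width bin half width, hours.
#' @param production_modulation,production_acrophase diurnal production
#'   settings (defaults as in [void_sim_config()]).
#' @return The modulation fraction estimate in [0, 1).
#' @examples
#' modulation_from_bin_ratio(1)   # a ratio of 1 means no modulation
#' @export
modulation_from_bin_ratio <- function(ratio, bin_center = 14,
                                      reference_center = 6,
                                      capacity_acrophase = 6,
                                      half_width = 4,
                                      production_modulation = 0.3,
                                      production_acrophase = 19) {
  w <- 2 * pi / 24
  prod <- function(zt) 1 + production_modulation * cos(w * (zt - production_acrophase))
  expected <- function(center, m) {
    lo <- center - half_width; hi <- center + half_width
    P <- stats::integrate(prod, lo, hi)$value
    R <- stats::integrate(function(z)
      prod(z) / (1 + m * cos(w * (z - capacity_acrophase))), lo, hi)$value
    P / R
  }
  f <- function(m) expected(bin_center, m) / expected(reference_center, m) - ratio
  if (abs(f(0)) < 1e-12) return(0)
  if (f(0) * f(0.999) > 0) {
    # no root in [0, 1): a noisy ratio on the m = 0 side clamps to 0
    if (abs(f(0)) <= abs(f(0.999))) return(0)
    stop("observed ratio is outside the range reachable by any modulation in [0, 1)")
  }
  stats::uniroot(f, c(0, 0.999), tol = 1e-9)$root
}

#' Test for a diurnal light-dark difference in voided volume per micturition
#'
#' Days are first averaged within each subject x bin cell; the cell means
#' then enter a two-way ANOVA with bin and subject as factors (subject as a
#' block, one observation per cell, so the bin-by-subject interaction is
#' the residual — the classical repeated-measures layout). Bin-vs-reference
#' contrasts on the residual variance follow, with multiplicity adjustment.
#' The rhythm is flagged present when any non-reference bin differs from
#' the reference at the adjusted level `alpha`.
#'
#' @param summary data frame from [summarize_bins()] with a `subject` column
#'   (>= 2 subjects) and >= 2 bins.
#' @param reference_bin bin label, default `"ZT6"`.
#' @param alpha significance level.
#' @param method multiplicity adjustment, `"sidak"` (default) or
#'   `"bonferroni"`.
#' @return A list: `rhythm_present`, `anova` (the [two_way_anova()] table),
#'   `contrasts` (per-bin difference, t, raw and adjusted p).
#' @export
diurnal_rhythm_flag <- function(summary, reference_bin = "ZT6", alpha = 0.05,
                                method = c("sidak", "bonferroni")) {
  method <- match.arg(method)
  if (!"subject" %in% names(summary)) stop("summary needs a subject column")
  summary <- summary[!summary$empty, , drop = FALSE]
  bins <- unique(as.character(summary$bin))
  if (length(bins) < 2) stop("need at least 2 bins to test a diurnal difference")
  if (length(unique(summary$subject)) < 2) stop("need at least 2 subjects")
  if (!reference_bin %in% bins) stop("reference bin absent from the summary")
  cell <- stats::aggregate(mean_ul_per_void ~ subject + bin, data = summary,
                           FUN = mean)
  aov_tab <- two_way_anova(cell$mean_ul_per_void,
                           factor_group = cell$subject,
                           factor_time = cell$bin,
                           interaction = FALSE)
  res <- aov_tab[aov_tab$effect == "residual", ]
  mse <- res$mean_sq; dfr <- res$df
  ref <- cell$mean_ul_per_void[cell$bin == reference_bin]
  others <- setdiff(bins, reference_bin)
  tt <- vapply(others, function(b) {
    y <- cell$mean_ul_per_void[cell$bin == b]
    (mean(y) - mean(ref)) / sqrt(mse * (1 / length(y) + 1 / length(ref)))
  }, numeric(1))
  p_raw <- 2 * stats::pt(abs(tt), df = dfr, lower.tail = FALSE)
  p_adj <- posthoc_adjust(p_raw, method = method, m = length(others))
  contrasts <- data.frame(bin = others, t = tt, p_raw = p_raw, p_adj = p_adj,
                          stringsAsFactors = FALSE)
  list(rhythm_present = any(p_adj < alpha), anova = aov_tab,
       contrasts = contrasts)
}
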