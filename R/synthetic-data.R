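#' Per-gene rhythm specification
#'
#' Ground-truth parameters of one simulated diurnal gene: a cosine with
#' midline `mesor`, half peak-to-trough `amplitude`, peak time `acrophase`
#' (ZT hours) and `period` (hours), plus the noise level used when the gene
#' is sampled.
#'
#' @param mesor midline expression level (> 0).
#' @param amplitude half peak-to-trough range (>= 0); 0 gives a flat gene.
#' @param acrophase ZT hours of the fitted peak; reduced mod `period`.
#' @param period rhythm period in hours, default 24.
#' @param noise_sd standard deviation of the sampling noise, expression units.
#' @return A `rhythm_spec` list.
#' @examples
#' rhythm_spec(mesor = 100, amplitude = 50, acrophase = 12)
#' @export
rhythm_spec <- function(mesor, amplitude, acrophase, period = 24, noise_sd = 0) {
  if (mesor <= 0) stop("mesor must be positive")
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (period <= 0) stop("period must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(mesor = mesor, amplitude = amplitude,
                 acrophase = acrophase %% period,
                 period = period, noise_sd = noise_sd),
            class = "rhythm_spec")
}

#' Configuration for the expression time-course simulator
#'
#' Emulates the deposited bladder RNA-seq design: animals sampled every 4 h
#' over one day (ZT 4, 8, 12, 16, 20, 24) with 3 replicates per time point.
#' Rhythmic genes follow cosine profiles; arrhythmic genes are flat at their
#' mesor. Unless explicit `rhythm_specs` are supplied, mesors are drawn
#' uniformly from `mesor_range`, acrophases from `acrophase_range`, and the
#' amplitude of each rhythmic gene is set so that its fitted peak/trough
#' ratio equals `amplitude_fold` (A = M (f-1)/(f+1)).
#'
#' @param n_rhythmic,n_arrhythmic gene counts.
#' @param timepoints sampled ZT hours, strictly increasing within one cycle.
#' @param replicates replicates per time point (>= 1).
#' @param rhythm_specs optional list of [rhythm_spec] objects, one per
#'   rhythmic gene, overriding the sampling ranges.
#' @param mesor_range,acrophase_range uniform sampling ranges.
#' @param amplitude_fold target fitted peak/trough ratio of rhythmic genes.
#' @param noise_sd_frac noise sd as a fraction of each gene's mesor.
#' @param noise_model `"additive"` Gaussian on the linear scale (default) or
#'   `"lognormal"` multiplicative with log-sd `noise_sd_frac`.
#' @param period rhythm period in hours.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return An `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_rhythmic, n_arrhythmic,
                                  timepoints = c(4, 8, 12, 16, 20, 24),
                                  replicates = 3,
                                  rhythm_specs = NULL,
                                  mesor_range = c(50, 150),
                                  amplitude_fold = 3,
                                  acrophase_range = c(0, 24),
                                  noise_sd_frac = 0.1,
                                  noise_model = c("additive", "lognormal"),
                                  period = 24,
                                  seed = NULL) {
  if (length(timepoints) == 0) stop("timepoints must not be empty")
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  if (diff(range(timepoints)) >= period)
    stop("timepoints must lie within one cycle")
  if (replicates < 1) stop("replicates must be >= 1")
  if (n_rhythmic < 0 || n_arrhythmic < 0) stop("gene counts must be non-negative")
  if (any(mesor_range <= 0)) stop("mesor must be positive")
  if (amplitude_fold < 1) stop("amplitude_fold must be >= 1")
  if (!is.null(rhythm_specs)) {
    if (length(rhythm_specs) != n_rhythmic)
      stop("rhythm_specs must supply one spec per rhythmic gene")
    stopifnot(all(vapply(rhythm_specs, inherits, logical(1), "rhythm_spec")))
  }
  structure(list(n_rhythmic = n_rhythmic, n_arrhythmic = n_arrhythmic,
                 timepoints = timepoints, replicates = replicates,
                 rhythm_specs = rhythm_specs,
                 mesor_range = mesor_range, amplitude_fold = amplitude_fold,
                 acrophase_range = acrophase_range,
                 noise_sd_frac = noise_sd_frac,
                 noise_model = match.arg(noise_model),
                 period = period, seed = seed),
            class = "expression_sim_config")
}

#' Simulate an expression time course with known rhythmicity truth
#'
#' Rhythmic gene g sampled at ZT t has mean
#' `mesor_g + amplitude_g * cos(2*pi*(t - acrophase_g)/period_g)`; arrhythmic
#' genes sit at their mesor. Noise is additive Gaussian (default) or
#' multiplicative lognormal.
#'
#' @param config an [expression_sim_config].
#' @return A list with `matrix` (a [timecourse]) and `truth`, a data frame
#'   with one row per gene: `gene`, `mesor`, `amplitude`, `acrophase`,
#'   `period`, `noise_sd`, `rhythmic`.
#' @examples
#' sim <- simulate_expression_timecourse(
#'   expression_sim_config(n_rhythmic = 5, n_arrhythmic = 5, seed = 1))
#' table(sim$truth$rhythmic)
#' @export
simulate_expression_timecourse <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_rhythmic + config$n_arrhythmic
  if (n == 0) stop("no genes to simulate")

  if (!is.null(config$rhythm_specs)) {
    specs <- config$rhythm_specs
    mesor <- vapply(specs, `[[`, numeric(1), "mesor")
    amplitude <- vapply(specs, `[[`, numeric(1), "amplitude")
    acrophase <- vapply(specs, `[[`, numeric(1), "acrophase")
    period <- vapply(specs, `[[`, numeric(1), "period")
    noise_sd <- vapply(specs, `[[`, numeric(1), "noise_sd")
  } else {
    mesor <- stats::runif(config$n_rhythmic, config$mesor_range[1], config$mesor_range[2])
    f <- config$amplitude_fold
    amplitude <- mesor * (f - 1) / (f + 1)
    acrophase <- stats::runif(config$n_rhythmic,
                              config$acrophase_range[1], config$acrophase_range[2])
    period <- rep(config$period, config$n_rhythmic)
    noise_sd <- config$noise_sd_frac * mesor
  }
  if (config$n_arrhythmic > 0) {
    m0 <- stats::runif(config$n_arrhythmic, config$mesor_range[1], config$mesor_range[2])
    mesor <- c(mesor, m0)
    amplitude <- c(amplitude, rep(0, config$n_arrhythmic))
    acrophase <- c(acrophase, rep(NA_real_, config$n_arrhythmic))
    period <- c(period, rep(config$period, config$n_arrhythmic))
    noise_sd <- c(noise_sd, config$noise_sd_frac * m0)
  }

  zt <- rep(config$timepoints, each = config$replicates)
  rep_idx <- rep(seq_len(config$replicates), times = length(config$timepoints))
  ph <- ifelse(is.na(acrophase), 0, acrophase)
  mu <- outer(seq_len(n), seq_along(zt), function(i, j) {
    mesor[i] + amplitude[i] * cos(2 * pi * (zt[j] - ph[i]) / period[i])
  })
  vals <- switch(config$noise_model,
    additive  = mu + matrix(stats::rnorm(length(mu), sd = rep(noise_sd, ncol(mu))),
                            nrow = n),
    lognormal = mu * exp(matrix(stats::rnorm(length(mu),
                                             sd = rep(config$noise_sd_frac, length(mu))),
                                nrow = n)))
  gene_ids <- paste0("gene", seq_len(n))
  rownames(vals) <- gene_ids
  colnames(vals) <- paste0("ZT", zt, "_rep", rep_idx)
  truth <- data.frame(gene = gene_ids, mesor = mesor, amplitude = amplitude,
                      acrophase = acrophase, period = period, noise_sd = noise_sd,
                      rhythmic = rep(c(TRUE, FALSE),
                                     c(config$n_rhythmic, config$n_arrhythmic)),
                      stringsAsFactors = FALSE)
  list(matrix = timecourse(vals, sample_zt = zt, replicate_index = rep_idx),
       truth = truth)
}

#' Configuration for the bioluminescence trace simulator
#'
#' Emulates photon-count recordings from a luciferase clock reporter after
#' serum-shock synchronization: sampling every 10 min for several days, a
#' damped cosine on top of a slowly drifting baseline. An optional
#' perturbation at `perturbation_time` advances the oscillation phase by
#' `perturbation_phase_shift` hours (positive = peaks occur earlier), the
#' in-silico analogue of a treatment pulse.
#'
#' @param duration recording length, hours (>= 2 periods).
#' @param dt sampling interval, hours (default 1/6 h = 10 min).
#' @param period oscillation period, hours.
#' @param amplitude initial oscillation amplitude, counts.
#' @param baseline baseline counts at t = 0.
#' @param baseline_trend baseline slope, counts/h.
#' @param damping_rate exponential amplitude decay, per hour (>= 0).
#' @param phase acrophase at t = 0, hours.
#' @param noise_sd additive Gaussian noise, counts.
#' @param perturbation_time hours; `NULL` for an unperturbed trace.
#' @param perturbation_phase_shift hours of phase advance applied from
#'   `perturbation_time` on.
#' @param seed integer seed.
#' @return A `trace_sim_config` list.
#' @export
trace_sim_config <- function(duration = 96, dt = 1 / 6, period = 24,
                             amplitude = 100, baseline = 500,
                             baseline_trend = 0, damping_rate = 0,
                             phase = 0, noise_sd = 0,
                             perturbation_time = NULL,
                             perturbation_phase_shift = 0,
                             seed = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (period <= 0) stop("period must be positive")
  if (duration < 2 * period)
    stop("duration must cover at least two periods for the rhythm to be defined")
  if (damping_rate < 0) stop("damping_rate must be non-negative")
  structure(list(duration = duration, dt = dt, period = period,
                 amplitude = amplitude, baseline = baseline,
                 baseline_trend = baseline_trend, damping_rate = damping_rate,
                 phase = phase, noise_sd = noise_sd,
                 perturbation_time = perturbation_time,
                 perturbation_phase_shift = perturbation_phase_shift,
                 seed = seed),
            class = "trace_sim_config")
}

#' Evenly sampled luminescence trace
#'
#' @param t hours since synchronization, strictly increasing, constant step.
#' @param counts photon counts per measurement window.
#' @return A `luminescence_trace` list with elements `t`, `counts`, `dt`.
#' @export
luminescence_trace <- function(t, counts) {
  if (length(t) != length(counts)) stop("t and counts must have equal length")
  if (length(t) < 2) stop("a trace needs at least two samples")
  d <- diff(t)
  if (any(d <= 0)) stop("t must be strictly increasing")
  if (diff(range(d)) > 1e-9) stop("sampling must be even (constant dt)")
  structure(list(t = as.numeric(t), counts = as.numeric(counts), dt = d[1]),
            class = "luminescence_trace")
}

#' Simulate a reporter luminescence trace with known peak times
#'
#' counts(t) = baseline + trend * t +
#' exp(-damping * t) * A * cos(2 pi (t - phase(t)) / period) + noise, where the
#' acrophase is advanced by `perturbation_phase_shift` hours from
#' `perturbation_time` on.
#'
#' @param config a [trace_sim_config].
#' @return A list with `trace` (a [luminescence_trace]) and `truth`: `period`,
#'   `peak_times` (noise-free peak hours within the recording) and the
#'   perturbation settings.
#' @examples
#' sim <- simulate_luminescence_trace(trace_sim_config(period = 22, seed = 1))
#' diff(sim$truth$peak_times)   # all 22 h
#' @export
simulate_luminescence_trace <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  t <- seq(0, config$duration, by = config$dt)
  phase_eff <- rep(config$phase, length(t))
  pt <- config$perturbation_time
  if (!is.null(pt)) {
    phase_eff[t >= pt] <- config$phase - config$perturbation_phase_shift
  }
  osc <- exp(-config$damping_rate * t) * config$amplitude *
    cos(2 * pi * (t - phase_eff) / config$period)
  counts <- config$baseline + config$baseline_trend * t + osc +
    stats::rnorm(length(t), sd = config$noise_sd)

  peaks_from <- function(phi, lo, hi) {
    k <- seq(ceiling((lo - phi) / config$period), floor((hi - phi) / config$period))
    phi + k * config$period
  }
  if (is.null(pt)) {
    peak_times <- peaks_from(config$phase %% config$period, 0, config$duration)
  } else {
    phi2 <- (config$phase - config$perturbation_phase_shift) %% config$period
    peak_times <- c(peaks_from(config$phase %% config$period, 0, pt - 1e-9),
                    peaks_from(phi2, pt, config$duration))
  }
  list(trace = luminescence_trace(t, counts),
       truth = list(period = config$period, peak_times = peak_times,
                    perturbation_time = pt,
                    perturbation_phase_shift = config$perturbation_phase_shift))
}

#' Configuration for the voiding-event simulator
#'
#' A minimal bladder model behind the aVSOP analytics: urine is produced at
#' a (diurnally modulated) rate and a void of the current functional
#' capacity is emitted whenever the accumulated volume reaches it. Capacity
#' follows `capacity_mesor * (1 + capacity_modulation *
#' cos(2*pi*(zt - capacity_acrophase)/24))` with the default acrophase at
#' ZT6, i.e. capacity is high in the light (inactive) phase and low in the
#' dark (active) phase, mirroring the behavioral phenotype the analytics are
#' built to detect. Production peaks in the dark phase by default
#' (acrophase ZT19), so total output per hour rises during activity.
#'
#' @param days number of simulated days.
#' @param cycle a [light_cycle].
#' @param production_rate mean urine production, ul/h.
#' @param production_modulation diurnal modulation fraction of production
#'   in [0, 1).
#' @param production_acrophase ZT hours of peak production.
#' @param capacity_mesor mean functional capacity, ul.
#' @param capacity_modulation modulation fraction in [0, 1); the invariant
#'   `capacity_mesor * (1 - capacity_modulation) > 0` must hold.
#' @param capacity_acrophase ZT hours of peak capacity (default 6).
#' @param event_jitter_sd Gaussian jitter on each recorded void volume, ul;
#'   volumes are floored at 10 ul, the lower end of the stain calibration
#'   range.
#' @param start_zt ZT at recording start; default 14 (dark onset), the
#'   anchor the summaries are graphed from.
#' @param sim_dt integration step, hours.
#' @param seed integer seed.
#' @return A `void_sim_config` list.
#' @export
void_sim_config <- function(days = 3, cycle = light_cycle(),
                            production_rate = 60,
                            production_modulation = 0.3,
                            production_acrophase = 19,
                            capacity_mesor = 250,
                            capacity_modulation = 0.4,
                            capacity_acrophase = 6,
                            event_jitter_sd = 0,
                            start_zt = 14,
                            sim_dt = 0.01,
                            seed = NULL) {
  if (days <= 0) stop("days must be positive")
  if (production_rate <= 0 && production_modulation == 0)
    stop("production rate must be positive over the cycle")
  if (production_modulation < 0 || production_modulation >= 1)
    stop("production_modulation must be in [0, 1)")
  if (capacity_modulation < 0 || capacity_modulation >= 1)
    stop("capacity_modulation must be in [0, 1)")
  if (capacity_mesor * (1 - capacity_modulation) <= 0)
    stop("capacity must stay positive over the cycle")
  if (production_rate * (1 - production_modulation) <= 0)
    stop("production rate must stay positive over the cycle")
  structure(list(days = days, cycle = cycle,
                 production_rate = production_rate,
                 production_modulation = production_modulation,
                 production_acrophase = production_acrophase,
                 capacity_mesor = capacity_mesor,
                 capacity_modulation = capacity_modulation,
                 capacity_acrophase = capacity_acrophase,
                 event_jitter_sd = event_jitter_sd,
                 start_zt = start_zt, sim_dt = sim_dt, seed = seed),
            class = "void_sim_config")
}

#' Simulate a voiding-event stream with known capacity truth
#'
#' Integrates the production rate on a fine grid and emits a void whenever
#' the accumulated volume reaches the instantaneous capacity. The recorded
#' volume is the capacity plus jitter (floored at 10 ul); the voided amount
#' is removed from the bladder, so total recorded volume matches integrated
#' production to within one capacity.
#'
#' @param config a [void_sim_config].
#' @return A list with `events` (data frame `t_h`, `zt`, `volume_ul`, with
#'   attribute `start_zt`) and `truth`: the configured capacity parameters
#'   and `expected_volume_per_void`, the bin-averaged capacity at the
#'   default ZT14/ZT22/ZT6 bins.
#' @examples
#' sim <- simulate_void_events(void_sim_config(days = 1, seed = 1))
#' nrow(sim$events)
#' @export
simulate_void_events <- function(config) {
  stopifnot(inherits(config, "void_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  w <- 2 * pi / 24
  t <- seq(config$sim_dt, config$days * 24, by = config$sim_dt)
  zt <- (config$start_zt + t) %% 24
  prod_rate <- config$production_rate *
    (1 + config$production_modulation * cos(w * (zt - config$production_acrophase)))
  capacity <- config$capacity_mesor *
    (1 + config$capacity_modulation * cos(w * (zt - config$capacity_acrophase)))
  filled <- cumsum(prod_rate * config$sim_dt)

  t_ev <- numeric(0); vol_ev <- numeric(0)
  emitted <- 0
  i <- 1L
  n <- length(t)
  while (i <= n) {
    j <- which(filled[i:n] - emitted >= capacity[i:n])
    if (length(j) == 0) break
    i <- i + j[1] - 1L
    vol <- capacity[i]
    if (config$event_jitter_sd > 0)
      vol <- max(10, vol + stats::rnorm(1, sd = config$event_jitter_sd))
    t_ev <- c(t_ev, t[i])
    vol_ev <- c(vol_ev, vol)
    emitted <- emitted + vol
    i <- i + 1L
  }
  events <- data.frame(t_h = t_ev, zt = (config$start_zt + t_ev) %% 24,
                       volume_ul = vol_ev)
  attr(events, "start_zt") <- config$start_zt

  # expected volume per void per default bin: voids occur at rate P/C, so
  # the expectation is the production-weighted harmonic mean of capacity
  centers <- c(14, 22, 6)
  expected <- vapply(centers, function(cc) {
    off <- (zt - (cc - 4)) %% 24
    inb <- off >= 0 & off < 8
    sum(prod_rate[inb]) / sum(prod_rate[inb] / capacity[inb])
  }, numeric(1))
  names(expected) <- paste0("ZT", centers)
  list(events = events,
       truth = list(capacity_mesor = config$capacity_mesor,
                    capacity_modulation = config$capacity_modulation,
                    capacity_acrophase = config$capacity_acrophase,
                    total_production = filled[n],
                    expected_volume_per_void = expected))
}


#' Simulate stain-area / volume calibration pairs
#'
#' Generates (area, volume) pairs for the aVSOP standard curve with target
#' volumes spanning the 10-800 ul calibration range:
#' `volume = slope * area + intercept + noise`.
#'
#' @param slope ul per cm^2.
#' @param intercept ul.
#' @param n number of pairs (>= 2).
#' @param noise_sd Gaussian noise on volume, ul.
#' @param seed integer seed.
#' @param volume_range target volume span, default c(10, 800) ul.
#' @return A data frame with columns `area_cm2`, `volume_ul`.
#' @examples
#' simulate_calibration_pairs(slope = 5, intercept = 0, n = 5)
#' @export
simulate_calibration_pairs <- function(slope, intercept = 0, n = 20,
                                       noise_sd = 0, seed = NULL,
                                       volume_range = c(10, 800)) {
  if (n < 2) stop("at least 2 calibration pairs are required")
  if (slope <= 0) stop("slope must be positive")
  if (!is.null(seed)) set.seed(seed)
  target <- seq(volume_range[1], volume_range[2], length.out = n)
  area <- (target - intercept) / slope
  if (any(area < 0)) stop("intercept/slope combination implies negative areas")
  volume <- slope * area + intercept + stats::rnorm(n, sd = noise_sd)
  data.frame(area_cm2 = area, volume_ul = volume)
}
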