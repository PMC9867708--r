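#' Peak and trough timing of a gene time course
#'
#' In `"fitted"` mode the peak is the cosinor acrophase and the trough sits
#' half a period later; in `"argmax"` mode peak and trough are the sampled
#' ZTs with the largest and smallest time-point means, ties resolved to the
#' earlier ZT. The argmax mode is only as sharp as the sampling grid (4 h in
#' the emulated design), but makes no shape assumption.
#'
#' @param fit a `cosinor_fit` (for `mode = "fitted"`).
#' @param means time-point means (for `mode = "argmax"`).
#' @param zt sampled ZT hours matching `means`.
#' @param mode `"fitted"` or `"argmax"`.
#' @param period hours, default 24.
#' @return A list: `peak_zt`, `trough_zt` (both in [0, period)), `source`.
#' @examples
#' zt <- rep(c(4, 8, 12, 16, 20, 24), each = 3)
#' fit <- cosinor_fit(2 + cos(2 * pi * (zt - 12) / 24), zt)
#' acrophase_peak(fit)                       # peak 12, trough 0
#' acrophase_peak(means = c(1, 2, 3, 3, 2, 1),
#'                zt = c(4, 8, 12, 16, 20, 24), mode = "argmax")  # peak 12
#' @export
acrophase_peak <- function(fit = NULL, means = NULL, zt = NULL,
                           mode = c("fitted", "argmax"), period = 24) {
  mode <- match.arg(mode)
  if (mode == "fitted") {
    if (is.null(fit)) stop("fitted mode needs a cosinor_fit")
    stopifnot(inherits(fit, "cosinor_fit"))
    if (fit$amplitude == 0 || is.na(fit$acrophase))
      stop("flat fit (amplitude 0): peak timing is undefined")
    peak <- fit$acrophase %% period
    trough <- (fit$acrophase + period / 2) %% period
  } else {
    if (is.null(means) || is.null(zt)) stop("argmax mode needs means and zt")
    if (length(means) != length(zt)) stop("means and zt must have equal length")
    if (length(zt) < 3) stop("argmax mode needs at least 3 time points")
    o <- order(zt)
    means <- means[o]; zt <- zt[o]
    peak <- zt[which.max(means)] %% period   # which.max takes the first = earliest
    trough <- zt[which.min(means)] %% period
  }
  list(peak_zt = peak, trough_zt = trough, source = mode)
}

#' Signed circular phase difference
#'
#' Shortest signed difference `test - ref` on the circle, in
#' `(-period/2, period/2]` hours. Negative values are phase advances (the
#' test peak occurs earlier than the reference peak); exactly antiphase
#' differences are reported as `+period/2` with the antiphase flag set.
#'
#' @param phase_ref,phase_test peak times, hours (any real; vectors recycle).
#' @param period hours (> 0), default 24.
#' @return A data frame with `shift_h` and `antiphase`.
#' @examples
#' circular_phase_shift(16, 12)$shift_h   # -4: a 4-h advance
#' circular_phase_shift(2, 22)$shift_h    # -4: wraps past midnight
#' circular_phase_shift(4, 16)            # +12, antiphase
#' @export
circular_phase_shift <- function(phase_ref, phase_test, period = 24) {
  if (period <= 0) stop("period must be positive")
  if (any(!is.finite(phase_ref)) || any(!is.finite(phase_test)))
    stop("phases must be finite")
  d <- (phase_test - phase_ref) %% period
  d <- ifelse(d > period / 2, d - period, d)
  data.frame(shift_h = d, antiphase = d == period / 2)
}

#' Per-gene phase shifts between two screened conditions
#'
#' Joins the cosinor fits of a reference and a test condition (e.g. vehicle
#' vs treatment) and reports the signed circular shift of each gene's
#' acrophase. By default only genes called rhythmic in the reference screen
#' are compared — genes whose reference rhythm is absent have no defined
#' phase to shift from.
#'
#' @param screen_ref,screen_test data frames from [screen_rhythmic_genes()].
#' @param rhythmic_only restrict to genes with `called == TRUE` in the
#'   reference screen (default TRUE).
#' @param period hours, default 24.
#' @return A data frame: `gene`, `peak_ref_zt`, `peak_test_zt`, `shift_h`,
#'   `antiphase`. Negative `shift_h` = phase advance.
#' @export
phase_shift_table <- function(screen_ref, screen_test, rhythmic_only = TRUE,
                              period = 24) {
  keep <- if (rhythmic_only) screen_ref$called else
    !is.na(screen_ref$acrophase_h)
  genes <- screen_ref$gene[keep]
  i <- match(genes, screen_test$gene)
  ref <- screen_ref$acrophase_h[keep]
  test <- screen_test$acrophase_h[i]
  ok <- !is.na(ref) & !is.na(test)
  sh <- circular_phase_shift(ref[ok], test[ok], period = period)
  data.frame(gene = genes[ok],
             peak_ref_zt = ref[ok], peak_test_zt = test[ok],
             shift_h = sh$shift_h, antiphase = sh$antiphase,
             stringsAsFactors = FALSE)
}
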