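#' Quantile-normalize an expression time course
#'
#' Forces every sample (column) to the same empirical distribution: each
#' column's sorted values become the across-column mean of sorted values,
#' while within-column ranks are preserved. Ties share the average of the
#' tied ranks' reference values. The computation is delegated to
#' [limma::normalizeQuantiles()].
#'
#' @param x a [timecourse] or a numeric matrix (genes x samples).
#' @return An object of the same type with normalized values.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' quantile_normalize(m)   # both columns become 2.5, 3.5, 4.5
#' @export
quantile_normalize <- function(x) {
  v <- if (inherits(x, "timecourse")) x$values else as.matrix(x)
  if (ncol(v) < 2) stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(out) <- dimnames(v)
  if (inherits(x, "timecourse")) {
    timecourse(out, sample_zt = x$sample_zt,
               replicate_index = x$replicate_index, gene_ids = x$gene_ids)
  } else {
    out
  }
}

#' Cosinor fit of a single time course
#'
#' Least-squares fit of `y = M + A cos(2*pi*(t - phi)/period)` via the linear
#' reparameterization on `{cos(2*pi*t/period), sin(2*pi*t/period)}`. The
#' rhythmicity statistic `maxcorr` is the Pearson correlation between fitted
#' and observed values — identically the maximum, over all acrophases, of the
#' correlation between the series and a cosine template (MaxCorr). Replicates
#' enter as individual samples so within-time-point scatter counts against
#' the fit; set `average_replicates = TRUE` to fit time-point means instead.
#'
#' @param y numeric observations.
#' @param zt ZT hours per observation.
#' @param period fitted period, hours (default 24; the single-cycle design
#'   cannot resolve period, so it is fixed, not estimated).
#' @param average_replicates collapse replicates to ZT means before fitting.
#' @return A `cosinor_fit` list: `mesor`, `amplitude`, `acrophase` (hours in
#'   [0, period), `NA` for a flat fit), `maxcorr` in [0, 1] (0 for a constant
#'   or flat series), `fold` (fitted peak/trough ratio, see
#'   [amplitude_fold()]), `period`, `n`.
#' @examples
#' zt <- rep(c(4, 8, 12, 16, 20, 24), each = 3)
#' y <- 2 + cos(2 * pi * (zt - 12) / 24)
#' fit <- cosinor_fit(y, zt)
#' c(fit$mesor, fit$amplitude, fit$acrophase, fit$maxcorr)
#' @export
cosinor_fit <- function(y, zt, period = 24, average_replicates = FALSE) {
  if (length(y) != length(zt)) stop("y and zt must have equal length")
  if (anyNA(y) || anyNA(zt)) stop("missing values are not supported")
  if (average_replicates) {
    y <- tapply(y, zt, mean)
    zt <- as.numeric(names(y))
    y <- as.numeric(y)
  }
  if (length(y) < 4) stop("cosinor fit needs at least 4 samples")
  if (length(unique(zt %% period)) < 3)
    stop("cosinor fit needs at least 3 distinct time points (design matrix is rank-deficient otherwise)")
  w <- 2 * pi / period
  X <- cbind(1, cos(w * zt), sin(w * zt))
  beta <- stats::lm.fit(X, y)$coefficients
  mesor <- beta[[1]]
  A <- sqrt(beta[[2]]^2 + beta[[3]]^2)
  fitted <- as.numeric(X %*% beta)
  if (stats::sd(y) == 0 || A < 1e-12) {
    r <- 0
    acrophase <- NA_real_
    A <- 0
  } else {
    acrophase <- (atan2(beta[[3]], beta[[2]]) / w) %% period
    r <- suppressWarnings(stats::cor(fitted, y))
    if (is.na(r)) r <- 0
    r <- min(max(r, 0), 1)
  }
  # a non-positive mesor implies a non-positive fitted trough: fold is Inf
  fold <- if (mesor < 0 && A > 0) Inf else amplitude_fold(max(mesor, 0), A)
  structure(list(mesor = mesor, amplitude = A, acrophase = acrophase,
                 maxcorr = r, fold = fold,
                 period = period, n = length(y)),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("<cosinor_fit> mesor %.4g, amplitude %.4g, acrophase %s h, MaxCorr %.3f, fold %.3g\n",
              x$mesor, x$amplitude,
              if (is.na(x$acrophase)) "NA" else sprintf("%.2f", x$acrophase),
              x$maxcorr, x$fold))
  invisible(x)
}

#' Fitted peak/trough amplitude fold
#'
#' The "amplitude fold" of a cosinor fit is the ratio of the fitted peak to
#' the fitted trough, `(M + A) / (M - A)`. When the trough is non-positive
#' (`M <= A`) the fold is infinite; a flat fit (`A = 0`) has fold 1.
#'
#' @param fit a `cosinor_fit`, or the mesor when `amplitude` is given.
#' @param amplitude amplitude, when `fit` is the mesor.
#' @return The fold, a number >= 1 or `Inf`.
#' @examples
#' amplitude_fold(2, 1)   # 3
#' amplitude_fold(5, 1)   # 1.5, the screening boundary
#' amplitude_fold(1, 1)   # Inf
#' @export
amplitude_fold <- function(fit, amplitude = NULL) {
  if (inherits(fit, "cosinor_fit")) {
    M <- fit$mesor; A <- fit$amplitude
  } else {
    M <- fit; A <- amplitude
  }
  if (is.null(A)) stop("amplitude is required")
  if (M < 0) stop("mesor must be non-negative")
  if (A < 0) stop("amplitude must be non-negative")
  if (A == 0) return(1)
  if (M <= A) return(Inf)
  (M + A) / (M - A)
}

#' Rhythmicity calling criterion
#'
#' The screening rule for diurnally rhythmic genes: MaxCorr to the cosine
#' fit greater than `maxcorr_min` (default 0.85) AND fitted amplitude fold
#' greater than `fold_min` (default 1.5). Both inequalities are strict.
#'
#' @param maxcorr_min MaxCorr threshold in (0, 1].
#' @param fold_min amplitude-fold threshold (>= 1).
#' @param period fitted period, hours.
#' @return A `rhythm_criterion` list.
#' @export
rhythm_criterion <- function(maxcorr_min = 0.85, fold_min = 1.5, period = 24) {
  if (maxcorr_min <= 0 || maxcorr_min > 1) stop("maxcorr_min must be in (0, 1]")
  if (fold_min < 1) stop("fold_min must be >= 1")
  if (period <= 0) stop("period must be positive")
  structure(list(maxcorr_min = maxcorr_min, fold_min = fold_min, period = period),
            class = "rhythm_criterion")
}

#' Screen a time course for rhythmic genes
#'
#' Fits a fixed-period cosinor to every gene and calls it rhythmic when
#' MaxCorr and amplitude fold both exceed the criterion thresholds (strictly).
#' Per-gene fitting errors are recorded in the `error` column rather than
#' aborting the screen.
#'
#' @param x a [timecourse] (normalize first, e.g. with
#'   [quantile_normalize()]).
#' @param criterion a [rhythm_criterion].
#' @param average_replicates passed to [cosinor_fit()].
#' @param fold_mode `"fitted"` (default) uses the fitted peak/trough ratio;
#'   `"observed"` uses max/min of the ZT means instead.
#' @return A data frame with one row per gene: `gene`, `mesor`, `amplitude`,
#'   `acrophase_h`, `maxcorr`, `fold`, `called`, `error`.
#' @examples
#' sim <- simulate_expression_timecourse(
#'   expression_sim_config(n_rhythmic = 3, n_arrhythmic = 3,
#'                         noise_sd_frac = 0.05, seed = 1))
#' calls <- screen_rhythmic_genes(sim$matrix)
#' sum(calls$called)
#' @export
screen_rhythmic_genes <- function(x, criterion = rhythm_criterion(),
                                  average_replicates = FALSE,
                                  fold_mode = c("fitted", "observed")) {
  stopifnot(inherits(x, "timecourse"), inherits(criterion, "rhythm_criterion"))
  fold_mode <- match.arg(fold_mode)
  n <- nrow(x$values)
  out <- data.frame(gene = x$gene_ids,
                    mesor = NA_real_, amplitude = NA_real_,
                    acrophase_h = NA_real_, maxcorr = NA_real_,
                    fold = NA_real_, called = FALSE,
                    error = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      cosinor_fit(x$values[i, ], x$sample_zt, period = criterion$period,
                  average_replicates = average_replicates),
      error = function(e) e)
    if (inherits(fit, "error")) {
      out$error[i] <- conditionMessage(fit)
      next
    }
    f <- if (fold_mode == "observed") {
      mu <- tapply(x$values[i, ], x$sample_zt, mean)
      if (min(mu) <= 0) Inf else max(mu) / min(mu)
    } else {
      fit$fold
    }
    out$mesor[i] <- fit$mesor
    out$amplitude[i] <- fit$amplitude
    out$acrophase_h[i] <- fit$acrophase
    out$maxcorr[i] <- fit$maxcorr
    out$fold[i] <- f
    out$called[i] <- fit$maxcorr > criterion$maxcorr_min && f > criterion$fold_min
  }
  out
}

#' Brute-force MaxCorr over a dense acrophase grid
#'
#' Independent reference for the cosinor MaxCorr: the maximum Pearson
#' correlation between the series and `cos(2*pi*(t - phi)/period)` over a
#' dense grid of acrophases. Equal (up to the grid step) to
#' `cosinor_fit()$maxcorr`; kept as a slow oracle, not the screening path.
#'
#' @param y,zt observations and their ZT hours.
#' @param period template period, hours.
#' @param grid_step acrophase grid step, hours (default 0.01).
#' @return The maximum correlation (clipped at 0).
#' @export
maxcorr_grid <- function(y, zt, period = 24, grid_step = 0.01) {
  phis <- seq(0, period - grid_step, by = grid_step)
  w <- 2 * pi / period
  # correlation of y with cos(w (t - phi)) for all phis at once
  cy <- y - mean(y)
  sy <- sqrt(sum(cy^2))
  if (sy == 0) return(0)
  C <- cos(w * zt); S <- sin(w * zt)
  cosphi <- cos(w * phis); sinphi <- sin(w * phis)
  best <- -Inf
  for (k in seq_along(phis)) {
    tem <- cosphi[k] * C + sinphi[k] * S
    ct <- tem - mean(tem)
    st <- sqrt(sum(ct^2))
    if (st == 0) next
    best <- max(best, sum(cy * ct) / (sy * st))
  }
  max(best, 0)
}

#' Differentially expressed genes across time points
#'
#' Retains a gene when the ratio of its largest to smallest time-point mean
#' exceeds `fold_min` (default 2.0) AND a one-way ANOVA across time points
#' gives `p < alpha` (default 0.05); both strict. A zero minimum mean is
#' floored at `mean_floor` (with a message) so the fold is defined.
#'
#' @param x a [timecourse] with >= 2 replicates per time point.
#' @param fold_min fold-change threshold.
#' @param alpha ANOVA p-value threshold.
#' @param mean_floor floor applied to a non-positive minimum time-point mean.
#' @return A data frame: `gene`, `fold`, `p`, `retained`.
#' @export
de_filter <- function(x, fold_min = 2.0, alpha = 0.05, mean_floor = 1e-6) {
  stopifnot(inherits(x, "timecourse"))
  if (min(table(x$sample_zt)) < 2)
    stop("de_filter needs at least 2 replicates per time point")
  ztf <- factor(x$sample_zt)
  n <- nrow(x$values)
  fold <- p <- numeric(n)
  floored <- FALSE
  for (i in seq_len(n)) {
    y <- x$values[i, ]
    mu <- tapply(y, ztf, mean)
    lo <- min(mu)
    if (lo <= 0) { lo <- mean_floor; floored <- TRUE }
    fold[i] <- max(mu) / lo
    p[i] <- if (stats::var(y) == 0) 1 else
      suppressWarnings(stats::anova(stats::lm(y ~ ztf))[["Pr(>F)"]][1])
  }
  if (floored) message("de_filter: non-positive minimum mean floored at ", mean_floor)
  data.frame(gene = x$gene_ids, fold = fold, p = p,
             retained = fold > fold_min & p < alpha,
             stringsAsFactors = FALSE)
}

#' Sample PCA scores
#'
#' Principal-component scores of the samples (columns) of an expression
#' matrix, from the SVD of the gene-centered data. Component signs are fixed
#' by making each component's largest-magnitude gene loading positive, so
#' scores are reproducible across platforms.
#'
#' @param x a [timecourse] or numeric matrix (genes x samples).
#' @param n_components number of components to return (default all).
#' @return A list: `scores` (samples x components), `loadings`
#'   (genes x components), `sdev`, `var_explained`.
#' @export
pca_scores <- function(x, n_components = NULL) {
  v <- if (inherits(x, "timecourse")) x$values else as.matrix(x)
  if (ncol(v) < 2) stop("PCA needs at least 2 samples")
  X <- scale(t(v), center = TRUE, scale = FALSE)  # samples x genes
  s <- svd(X)
  k <- if (is.null(n_components)) length(s$d) else min(n_components, length(s$d))
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
  loadings <- s$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- colnames(v)
  rownames(loadings) <- rownames(v)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  sdev <- s$d / sqrt(max(1, nrow(X) - 1))
  list(scores = scores, loadings = loadings, sdev = sdev[seq_len(k)],
       var_explained = (s$d^2 / sum(s$d^2))[seq_len(k)])
}
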