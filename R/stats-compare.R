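#' Two-factor analysis of variance
#'
#' Classical two-way ANOVA with (optionally) the interaction, as used for
#' group-by-time comparisons of expression and voiding summaries. Balanced
#' layouts get sequential (Type I) sums of squares, which are then
#' order-independent and satisfy the exact decomposition
#' `SS_A + SS_B (+ SS_AB) + SS_res = SS_total`; unbalanced layouts fall back
#' to Type II sums of squares via [car::Anova()] (with a message), where the
#' decomposition identity no longer holds.
#'
#' @param values numeric response.
#' @param factor_group,factor_time the two factors (coerced with `factor()`).
#' @param interaction include the interaction term (default TRUE; requires
#'   replication within cells).
#' @return An `anova_table` data frame: `effect` (`group`, `time`,
#'   `group:time`, `residual`), `sum_sq`, `df`, `mean_sq`, `F`, `p`.
#' @examples
#' g <- rep(c("a", "b"), each = 4); zt <- rep(c(4, 16), times = 4)
#' two_way_anova(rnorm(8), g, zt)
#' @export
two_way_anova <- function(values, factor_group, factor_time, interaction = TRUE) {
  A <- factor(factor_group); B <- factor(factor_time)
  if (length(values) != length(A) || length(values) != length(B))
    stop("values and factors must have equal length")
  if (nlevels(A) < 2 || nlevels(B) < 2) stop("both factors need at least 2 levels")
  counts <- table(A, B)
  if (any(counts == 0)) stop("empty cell: every factor combination needs at least one observation")
  form <- if (interaction) values ~ A * B else values ~ A + B
  fit <- stats::lm(form)
  balanced <- length(unique(counts)) == 1
  if (balanced) {
    tab <- stats::anova(fit)
  } else {
    message("unbalanced layout: using Type II sums of squares")
    tab <- car::Anova(fit, type = 2)
  }
  eff <- rownames(tab)
  eff[eff == "A"] <- "group"; eff[eff == "B"] <- "time"
  eff[eff == "A:B"] <- "group:time"; eff[eff == "Residuals"] <- "residual"
  out <- data.frame(effect = eff,
                    sum_sq = tab[["Sum Sq"]],
                    df = tab[["Df"]],
                    stringsAsFactors = FALSE)
  out$mean_sq <- out$sum_sq / out$df
  out$F <- c(tab[["F value"]])
  out$p <- c(tab[["Pr(>F)"]])
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Multiple-comparison adjustment of p-values
#'
#' The post hoc adjustments used throughout the package's comparisons:
#' \describe{
#'   \item{sidak}{`p' = 1 - (1 - p)^m` for `m` comparisons.}
#'   \item{bonferroni}{`p' = min(1, m * p)`.}
#'   \item{tukey}{all-pairwise honest significant difference: the adjusted p
#'     of a pairwise t statistic is the studentized-range tail probability
#'     `ptukey(sqrt(2) |t|, k, df)` for `k` group means.}
#'   \item{dunnett}{many-to-one comparisons against a common control: the
#'     two-sided family-wise p of each t statistic under the equicorrelated
#'     (rho = 0.5 for equal group sizes) multivariate t, evaluated by Monte
#'     Carlo with a fixed internal seed (10^6 draws, accurate to about
#'     1e-3).}
#' }
#'
#' @param p raw p-values (sidak, bonferroni).
#' @param method adjustment method.
#' @param m number of comparisons in the family (defaults to `length(p)` for
#'   sidak/bonferroni and `length(statistic)` for dunnett).
#' @param statistic t statistics (tukey, dunnett).
#' @param df residual degrees of freedom (tukey, dunnett).
#' @param k number of group means being compared (tukey).
#' @param rho common correlation of the Dunnett contrasts, default 0.5.
#' @param mc_draws,mc_seed Monte-Carlo settings for dunnett.
#' @return Adjusted p-values, capped at 1.
#' @examples
#' posthoc_adjust(0.01, method = "sidak", m = 6)   # 1 - 0.99^6
#' @export
posthoc_adjust <- function(p = NULL,
                           method = c("sidak", "bonferroni", "tukey", "dunnett"),
                           m = NULL, statistic = NULL, df = NULL, k = NULL,
                           rho = 0.5, mc_draws = 1e6, mc_seed = 1L) {
  method <- match.arg(method)
  if (method %in% c("sidak", "bonferroni")) {
    if (is.null(p)) stop("sidak/bonferroni need raw p-values")
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    if (is.null(m)) m <- length(p)
    if (m < 1) stop("m must be at least 1")
    return(switch(method,
                  sidak = 1 - (1 - p)^m,
                  bonferroni = pmin(1, m * p)))
  }
  if (is.null(statistic) || is.null(df))
    stop(method, " needs t statistics and residual df")
  if (method == "tukey") {
    if (is.null(k)) stop("tukey needs the number of group means k")
    return(stats::ptukey(sqrt(2) * abs(statistic), nmeans = k, df = df,
                         lower.tail = FALSE))
  }
  # dunnett: family-wise two-sided p under equicorrelated multivariate t
  if (is.null(m)) m <- length(statistic)
  if (m < 1) stop("m must be at least 1")
  maxabs <- dunnett_maxabs_sample(m = m, df = df, rho = rho,
                                  n = mc_draws, seed = mc_seed)
  vapply(abs(statistic), function(ti) mean(maxabs >= ti), numeric(1))
}

# Monte-Carlo sample of max_j |T_j| for m equicorrelated t variables.
# The rho-equicorrelated normals are built from one shared and m private
# standard normals; dividing by a common chi scale gives the multivariate t.
dunnett_maxabs_sample <- function(m, df, rho = 0.5, n = 1e6, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  z0 <- stats::rnorm(n)
  s <- sqrt(stats::rchisq(n, df) / df)
  mx <- rep(-Inf, n)
  a <- sqrt(rho); b <- sqrt(1 - rho)
  for (j in seq_len(m)) {
    mx <- pmax(mx, abs(a * z0 + b * stats::rnorm(n)))
  }
  mx / s
}

#' Relative expression by the delta-delta-Ct method
#'
#' qPCR relative quantification: `dCt = Ct_target - Ct_reference` (the
#' reference being a stable housekeeping gene such as 18S rRNA),
#' `ddCt = dCt - dCt_calibrator`, relative expression `2^(-ddCt)`. The
#' calibrator sample normalizes to exactly 1.
#'
#' @param ct_target Ct values of the gene of interest.
#' @param ct_reference Ct values of the housekeeping reference (e.g. 18S),
#'   same length.
#' @param calibrator_delta_ct the calibrator sample's `dCt` (scalar), or
#'   `NULL` to use the first sample as calibrator.
#' @return Relative expression values (dimensionless fold changes).
#' @examples
#' ddct_relative_expression(c(25, 24), c(10, 10), calibrator_delta_ct = 15)
#' # 1 (the calibrator itself) and 2 (one cycle earlier = twofold)
#' @export
ddct_relative_expression <- function(ct_target, ct_reference,
                                     calibrator_delta_ct = NULL) {
  if (length(ct_target) != length(ct_reference))
    stop("target and reference Ct vectors must have equal length")
  if (anyNA(ct_reference) || any(!is.finite(ct_reference)))
    stop("missing or non-finite reference Ct")
  if (anyNA(ct_target) || any(!is.finite(ct_target)))
    stop("missing or non-finite target Ct")
  dct <- ct_target - ct_reference
  if (is.null(calibrator_delta_ct)) calibrator_delta_ct <- dct[1]
  2^-(dct - calibrator_delta_ct)
}
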