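test_that("quantile normalization equalizes column distributions and keeps ranks", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point
  m2 <- cbind(x = c(3, 1, 7), y = c(3, 1, 7))
  expect_equal(quantile_normalize(m2), m2)

  # property: all sorted columns equal the common reference; ranks preserved
  set.seed(11)
  m3 <- matrix(rlnorm(300), nrow = 50, ncol = 6)
  qn3 <- quantile_normalize(m3)
  ref <- sort(qn3[, 1])
  for (j in 2:6) expect_equal(sort(qn3[, j]), ref, tolerance = 1e-12)
  for (j in 1:6) expect_equal(order(qn3[, j]), order(m3[, j]))

  expect_error(quantile_normalize(m3[, 1, drop = FALSE]), "2 samples")
})

test_that("cosinor fit recovers an exact cosine and degrades sanely", {
  zt <- zt_design()
  y <- 2 + cos(2 * pi * (zt - 12) / 24)
  fit <- cosinor_fit(y, zt)
  expect_equal(fit$mesor, 2, tolerance = 1e-9)
  expect_equal(fit$amplitude, 1, tolerance = 1e-9)
  expect_equal(fit$acrophase, 12, tolerance = 1e-9)
  expect_equal(fit$maxcorr, 1, tolerance = 1e-9)
  expect_equal(fit$fold, 3, tolerance = 1e-9)

  # constant series: no rhythm by definition
  flat <- cosinor_fit(rep(5, length(zt)), zt)
  expect_equal(flat$maxcorr, 0)
  expect_true(is.na(flat$acrophase))
  expect_equal(flat$fold, 1)

  expect_error(cosinor_fit(1:3, c(4, 8, 12)), "4 samples")
  expect_error(cosinor_fit(1:4, c(4, 4, 8, 8)), "3 distinct")
})

test_that("closed-form MaxCorr equals the dense phase-grid maximum", {
  zt <- zt_design()
  set.seed(21)
  for (i in 1:20) {
    y <- rnorm(length(zt), sd = runif(1, 0.5, 3)) +
      runif(1, 0, 2) * cos(2 * pi * (zt - runif(1, 0, 24)) / 24)
    expect_equal(cosinor_fit(y, zt)$maxcorr, maxcorr_grid(y, zt),
                 tolerance = 1e-3)
  }
})

test_that("acrophase is recovered exactly on noiseless rhythmic genes", {
  zt <- zt_design()
  set.seed(31)
  for (i in 1:25) {
    phi <- runif(1, 0, 24)
    fit <- cosinor_fit(10 + 3 * cos(2 * pi * (zt - phi) / 24), zt)
    d <- abs(fit$acrophase - phi) %% 24
    expect_lt(min(d, 24 - d), 1e-6)
  }
})

test_that("MaxCorr is scale-invariant while the fold shifts with the baseline", {
  zt <- zt_design()
  set.seed(41)
  y <- 10 + 3 * cos(2 * pi * (zt - 8) / 24) + rnorm(length(zt))
  f1 <- cosinor_fit(y, zt)
  f2 <- cosinor_fit(7 * y, zt)       # positive scaling
  f3 <- cosinor_fit(y + 50, zt)      # additive shift
  expect_equal(f1$maxcorr, f2$maxcorr, tolerance = 1e-12)
  expect_equal(f1$fold, f2$fold, tolerance = 1e-9)
  expect_equal(f1$maxcorr, f3$maxcorr, tolerance = 1e-12)
  expect_lt(f3$fold, f1$fold)
})

test_that("rising noise never raises the median MaxCorr of a rhythmic panel", {
  med <- vapply(c(0.05, 0.25, 0.6), function(ns) {
    sim <- simulate_expression_timecourse(
      expression_sim_config(30, 0, noise_sd_frac = ns, seed = 99))
    median(screen_rhythmic_genes(sim$matrix)$maxcorr)
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
})

test_that("amplitude fold follows the fitted peak/trough ratio", {
  expect_equal(amplitude_fold(2, 1), 3)
  expect_equal(amplitude_fold(5, 1), 1.5)  # the criterion boundary
  expect_equal(amplitude_fold(1, 1), Inf)  # non-positive trough
  expect_equal(amplitude_fold(0.5, 1), Inf)
  expect_equal(amplitude_fold(4, 0), 1)    # flat fit
  expect_error(amplitude_fold(-1, 0.5), "mesor")
})

test_that("the screen calls clean cosines and rejects flat genes", {
  spec <- rhythm_spec(mesor = 2, amplitude = 1, acrophase = 12)
  sim <- simulate_expression_timecourse(expression_sim_config(
    1, 1, rhythm_specs = list(spec), noise_sd_frac = 0, seed = 1))
  calls <- screen_rhythmic_genes(sim$matrix)
  expect_identical(calls$called, c(TRUE, FALSE))
  # a fold sitting exactly on the boundary is NOT called (strict inequality)
  b <- rhythm_spec(mesor = 5, amplitude = 1, acrophase = 6)
  simb <- simulate_expression_timecourse(expression_sim_config(
    1, 0, rhythm_specs = list(b), noise_sd_frac = 0, seed = 1))
  cb <- screen_rhythmic_genes(simb$matrix)
  expect_equal(cb$fold, 1.5, tolerance = 1e-9)
  expect_false(cb$called)
})

test_that("de_filter applies the fold and ANOVA thresholds strictly", {
  zt <- zt_design()
  up <- ifelse(zt == 24, 4, 1) + rep(c(-1, 0, 1) * 1e-6, times = 6)
  flat <- rep(2, length(zt))
  near <- ifelse(zt == 24, 1.9, 1) + rep(c(-1, 0, 1) * 1e-6, times = 6)
  tc <- timecourse(rbind(up, flat, near), zt, gene_ids = c("up", "flat", "near"))
  res <- de_filter(tc)
  expect_true(res$retained[res$gene == "up"])
  expect_false(res$retained[res$gene == "flat"])
  expect_false(res$retained[res$gene == "near"])  # fold 1.9 < 2.0
})

test_that("PCA scores match the covariance eigendecomposition", {
  # two samples symmetric about the mean land at +/- c on PC1
  m <- cbind(s1 = c(1, 2, 3), s2 = c(3, 2, 1))
  p <- pca_scores(m)
  expect_equal(p$scores[1, 1], -p$scores[2, 1], tolerance = 1e-12)

  set.seed(55)
  m2 <- matrix(rnorm(60), nrow = 10, ncol = 6)
  p2 <- pca_scores(m2)
  # orthogonality: score covariance is diagonal
  cv <- crossprod(scale(p2$scores, center = TRUE, scale = FALSE)) / 5
  expect_equal(cv - diag(diag(cv)), matrix(0, 6, 6), tolerance = 1e-8,
               ignore_attr = TRUE)
  # eigendecomposition oracle: nonzero spectrum of the gene-space covariance
  ev <- eigen(stats::cov(t(m2)))$values
  expect_equal(p2$sdev[1:5]^2, ev[1:5], tolerance = 1e-8)
  expect_error(pca_scores(m2[, 1, drop = FALSE]), "2 samples")
})
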