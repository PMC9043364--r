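# Thermal denaturation: spectra-to-ratio reduction, four-parameter
# logistic fitting, the sigmoidality gate and group ANOVA.

test_that("ratio_from_spectra: flat spectra, nearest-grid rule, blanks", {
  tt <- seq(5, 90, by = 5)
  wl <- 310:410
  flat <- spectrum_series(tt, wl, matrix(1, length(tt), length(wl)))
  expect_equal(ratio_from_spectra(flat)$ratio, rep(1, length(tt)))
  # nearest-grid rule: 328.4 nm uses the 328 nm column
  ints <- matrix(1, length(tt), length(wl))
  ints[, wl == 328] <- 2
  s <- spectrum_series(tt, wl, ints)
  expect_equal(ratio_from_spectra(s, lam_num = 328.4)$ratio,
               rep(2, length(tt)))
  # blank subtraction happens before the ratio
  blank <- spectrum_series(tt, wl, matrix(0.5, length(tt), length(wl)))
  ints2 <- matrix(1.5, length(tt), length(wl))
  s2 <- spectrum_series(tt, wl, ints2)
  expect_equal(ratio_from_spectra(s2, blank = blank)$ratio,
               rep(1, length(tt)))
  expect_error(ratio_from_spectra(flat, lam_num = 500), "outside")
  ints3 <- ints2; ints3[, wl == 352] <- -1
  expect_error(ratio_from_spectra(spectrum_series(tt, wl, ints3)),
               "denominator")
})

test_that("two-state mixtures give a monotone ratio between basis ratios", {
  s <- gen_melt(list(y0 = 1.2, a = -0.45, b = 0.35, x0 = 60),
                spectral = TRUE)
  cu <- ratio_from_spectra(s)
  expect_true(all(diff(cu$ratio) < 0))
  expect_true(all(cu$ratio > 0.7) && all(cu$ratio < 1.25))
})

test_that("noise-free logistic curves refit to the exact parameters", {
  tt <- seq(5, 90, by = 2.5)
  # each printed melting temperature as ground-truth inflection
  for (x0 in study_tms) {
    cu <- melt_curve(tt, melt_sigmoid(tt, 1.20, -0.45, 0.35, x0))
    fit <- melt_fit(cu)
    expect_true(fit$sigmoidal)
    expect_lt(abs(fit$Tm - x0), 0.05)
  }
  # round-trip any parameter set with b * range > 5, to 0.1% relative
  sets <- list(c(1.0, 0.6, 0.2, 40), c(2.0, -1.0, 0.1, 55),
               c(0.8, 0.3, 0.9, 70))
  for (p in sets) {
    cu <- melt_curve(tt, melt_sigmoid(tt, p[1], p[2], p[3], p[4]))
    fit <- melt_fit(cu)
    expect_equal(unname(coef(fit)), p, tolerance = 1e-3)
    # the model value at x0 is exactly y0 + a/2
    expect_equal(predict(fit, coef(fit)[["x0"]]),
                 coef(fit)[["y0"]] + coef(fit)[["a"]] / 2,
                 tolerance = 1e-12)
  }
})

test_that("logistic symmetry and affine invariance of the inflection", {
  x <- seq(5, 90, by = 2.5)
  # negating a and b around the complementary offset leaves values fixed
  expect_equal(melt_sigmoid(x, 1.2, -0.45, 0.35, 67.3),
               melt_sigmoid(x, 1.2 - 0.45, 0.45, -0.35, 67.3),
               tolerance = 1e-12)
  # affine rescaling of the ratio axis leaves the fitted Tm unchanged
  cu <- melt_curve(x, melt_sigmoid(x, 1.2, -0.45, 0.35, 67.3))
  cu2 <- melt_curve(x, 0.2 + 3 * cu$ratio)
  expect_equal(melt_fit(cu2)$Tm, melt_fit(cu)$Tm, tolerance = 1e-6)
})

test_that("the sigmoidality gate rejects what it should", {
  tt <- seq(5, 90, by = 2.5)
  # clean logistic passes
  fit <- melt_fit(melt_curve(tt, melt_sigmoid(tt, 1.2, -0.45, 0.35, 67.3)))
  expect_true(fit$sigmoidal)
  expect_length(fit$reasons, 0)
  # strictly linear data: no transition to locate
  lin <- melt_fit(melt_curve(tt, 1 + 0.002 * tt))
  expect_false(lin$sigmoidal)
  expect_true(is.na(lin$Tm))
  # inflection outside the sampled range
  out <- melt_fit(melt_curve(tt, melt_sigmoid(tt, 1.2, -0.45, 0.15, 120)))
  expect_false(out$sigmoidal)
  expect_true(any(grepl("outside range", out$reasons)))
  # pure noise around a constant is rejected with the amplitude reason
  set.seed(11)
  rejected <- 0L
  amp_reason <- 0L
  for (i in 1:20) {
    nf <- melt_fit(melt_curve(tt, 1.2 + rnorm(length(tt), 0, 0.05)))
    if (!nf$sigmoidal) {
      rejected <- rejected + 1L
      if (any(grepl("amplitude", nf$reasons))) amp_reason <- amp_reason + 1L
    }
  }
  expect_gte(rejected, 18L)
  expect_gte(amp_reason, 1L)
})

test_that("melt ANOVA matches aov and handles degenerate groups", {
  # hand-computable two-group case: F = 8, p ~ 0.106
  res <- melt_anova(list(c(1, 2), c(3, 4)))
  expect_equal(res$F, 8)
  expect_equal(res$p, 0.10557, tolerance = 1e-4)
  # cross-check against stats::aov on a richer design
  g <- list(c(67.1, 67.3, 67.5), c(56.7, 56.9, 57.1), c(71.2, 71.4, 71.6))
  res2 <- melt_anova(g)
  df <- data.frame(y = unlist(g), f = factor(rep(1:3, each = 3)))
  ref <- summary(stats::aov(y ~ f, df))[[1]]
  expect_equal(res2$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(res2$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  # destabilizing mutation: clearly separated replicate Tm groups
  expect_lt(melt_anova(list(exact_replicates(67.3, 0.2),
                            exact_replicates(56.9, 0.2)))$p, 0.05)
  # degenerate: identical groups
  same <- melt_anova(list(c(5, 5), c(5, 5)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
})
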