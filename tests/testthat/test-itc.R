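# Single-site ITC model: equilibrium solver, forward heat model,
# blank subtraction, fitting and thermodynamic decomposition.

test_that("bound-concentration solver handles limits and matches bisection", {
  # no partner present
  expect_equal(solve_bound_concentration(0, 1e-4, 1e-6), 0)
  expect_equal(solve_bound_concentration(1e-4, 0, 1e-6), 0)
  # no-binding limit: Kd = 1e6 M leaves ~Mt*Xt/Kd = 1e-14 bound
  weak <- solve_bound_concentration(1e-4, 1e-4, 1e6)
  expect_lt(weak, 1e-13)
  expect_gt(weak, 1e-15)
  # frozen bisection value for the equimolar moderate-affinity case
  expect_equal(solve_bound_concentration(8e-5, 8e-5, 1.3e-6),
               7.043126720185e-05, tolerance = 1e-10)
  # oracle agreement across a log grid of Kd and concentrations
  for (Kd in 10^seq(-9, -3, by = 2)) {
    for (Mt in c(1e-6, 1e-4, 1e-3)) {
      for (Xt in c(1e-6, 5e-5, 1e-3)) {
        expect_equal(solve_bound_concentration(Mt, Xt, Kd),
                     bisect_bound(Mt, Xt, Kd),
                     tolerance = 1e-10,
                     label = sprintf("Kd=%g Mt=%g Xt=%g", Kd, Mt, Xt))
      }
    }
  }
  # bound by both totals
  mx <- solve_bound_concentration(8e-5, 8e-4, 1.3e-6, n = 0.9)
  expect_lte(mx, 0.9 * 8e-5)
  expect_error(solve_bound_concentration(1e-4, 1e-4, -1), "Kd")
})

test_that("forward heat model obeys trivial limits and the frozen oracle", {
  design <- itc_design(V0 = 1.85e-4, M0 = 8e-5, X0 = 8e-4)
  # no enthalpy, no heat
  expect_equal(predict_injection_heats(thermo_params(1e-6, 0), design),
               rep(0, 22))
  # stoichiometric (tight-binding) limit: early heats carry dH per mole
  q <- predict_injection_heats(thermo_params(1e-12, -89), design)
  moles <- design$inj_volumes * design$X0 * 1e9
  expect_equal(q[1:5] / moles[1:5], rep(-89, 5), tolerance = 0.02)
  # full 22-injection vector frozen from the bisection oracle
  frozen <- c(-139.82863769, -139.09073671, -138.01555507, -136.36171948,
              -133.65321600, -128.89170061, -119.94235404, -102.93418751,
              -75.50940720, -46.00891116, -25.82044409, -14.99918838,
              -9.36278500, -6.24890874, -4.39904567, -3.22615281,
              -2.44083703, -1.89073114, -1.49055492, -1.18996274,
              -0.95784268, -0.77420168)
  expect_equal(predict_injection_heats(thermo_params(1.3e-6, -89), design),
               frozen, tolerance = 1e-8)
  # temperature mismatch is rejected
  expect_error(
    predict_injection_heats(thermo_params(1e-6, -50, T = 310), design),
    "temperature mismatch")
})

test_that("heat bookkeeping: conservation and saturation", {
  design <- itc_design(V0 = 1.85e-4, M0 = 5e-5, X0 = 1.8e-3)
  tp <- thermo_params(1e-6, -80)
  q <- predict_injection_heats(tp, design)
  tot <- readerbind:::.itc_totals(design)
  mx <- solve_bound_concentration(tot$Mt, tot$Xt, tp$Kd)
  Q <- tp$dH * design$V0 * mx * 1e9
  nq <- length(q)
  # sum of increments without the displacement term telescopes to Q_N;
  # with it the difference is bounded by (sum v_i / V0) * max |Q|
  expect_lte(abs(sum(q) - Q[nq]),
             sum(design$inj_volumes) / design$V0 * max(abs(Q)))
  # saturation: cumulative heat per mole of macromolecule approaches
  # n*dH (within 2% at molar ratio >= 5 for c >= 50)
  expect_gte(tot$Xt[nq] / tot$Mt[nq], 5)
  expect_gte(tp$n * design$M0 / tp$Kd, 50)
  norm_heat <- Q[nq] / (design$V0 * tot$Mt[nq] * 1e9)
  expect_equal(norm_heat, tp$n * tp$dH, tolerance = 0.02)
})

test_that("blank subtraction is linear and shape-checked", {
  design <- itc_design(M0 = 1e-4, X0 = 8e-4)
  iso <- itc_isotherm(design, predict_injection_heats(
    thermo_params(1.3e-6, -89), design))
  expect_equal(subtract_blank(iso, itc_isotherm(design, rep(0, 22)))$heats,
               iso$heats)
  expect_equal(subtract_blank(iso, 3)$heats, iso$heats - 3)
  expect_equal(subtract_blank(iso, iso)$heats, rep(0, 22))
  short <- itc_isotherm(itc_design(M0 = 1e-4, X0 = 8e-4,
                                   inj_volumes = rep(2e-6, 10)),
                        rep(1, 10))
  expect_error(subtract_blank(iso, short), "injection counts")
})

test_that("noise-free fits recover ground truth for any c in [5, 1000]", {
  design <- itc_design(M0 = 1e-4, X0 = 8e-4)
  cases <- list(list(Kd = 2e-5, dH = -60, n = 1.0),    # c = 5
                list(Kd = 2e-6, dH = -89, n = 0.9),    # c = 45
                list(Kd = 1e-7, dH = -120, n = 1.08))  # c = 1080-ish
  for (cs in cases) {
    tp <- thermo_params(cs$Kd, cs$dH, cs$n)
    iso <- itc_isotherm(design, predict_injection_heats(tp, design))
    fit <- itc_fit(iso, free_n = TRUE)
    expect_true(fit$converged)
    expect_equal(coef(fit)[["Kd"]], cs$Kd, tolerance = 0.005)
    expect_equal(coef(fit)[["dH"]], cs$dH, tolerance = 0.005)
    expect_equal(coef(fit)[["n"]], cs$n, tolerance = 0.005)
    # derived state functions are self-consistent to 1e-9 kJ/mol
    p <- fit$params
    expect_equal(p$TdS, p$dH - p$dG, tolerance = 1e-12)
    expect_equal(p$dS, 1000 * p$TdS / p$T, tolerance = 1e-12)
  }
})

test_that("fixed-n fits, weak binding and degenerate input are flagged", {
  design <- itc_design(M0 = 1e-4, X0 = 8e-4)
  iso <- itc_isotherm(design, predict_injection_heats(
    thermo_params(1.3e-6, -89), design))
  fit <- itc_fit(iso, free_n = FALSE)
  expect_true(fit$converged)
  expect_identical(coef(fit)[["n"]], 1)
  expect_equal(coef(fit)[["Kd"]], 1.3e-6, tolerance = 1e-3)

  # c-value < 1: mirrors constructs where no accurate Kd was obtainable
  weak <- itc_isotherm(design, predict_injection_heats(
    thermo_params(5e-4, -89), design))
  wfit <- itc_fit(weak, free_n = FALSE)
  expect_true(wfit$weak_binding)
  expect_match(wfit$message, "weak-binding")

  # all-zero heats: no signal
  zfit <- itc_fit(itc_isotherm(design, rep(0, 22)))
  expect_false(zfit$converged)
  expect_match(zfit$message, "no signal")

  # discard_first drops the first injection from the fit
  iso2 <- iso
  iso2$heats[1] <- iso2$heats[1] * 0.5   # classic short first injection
  fit2 <- itc_fit(iso2, free_n = TRUE, discard_first = TRUE)
  expect_equal(coef(fit2)[["Kd"]], 1.3e-6, tolerance = 1e-3)
})

test_that("fit methods: predict, residuals, simulate, summary", {
  design <- itc_design(M0 = 1e-4, X0 = 8e-4)
  iso <- itc_isotherm(design, predict_injection_heats(
    thermo_params(1.3e-6, -89), design))
  fit <- itc_fit(iso, free_n = FALSE)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(residuals(fit), iso$heats - fitted(fit))
  sims <- simulate(fit, nsim = 2, seed = 7, noise_sigma = 1)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$heats, sims[[2]]$heats))
  out <- utils::capture.output(print(summary(fit)))
  expect_true(any(grepl("Kd_uM", out)))
})

test_that("derived state functions reproduce printed entropies", {
  expect_equal(derive_state_functions(1, -50)$dG, 0)
  expect_equal(derive_state_functions(1, -50)$TdS, -50)
  # L919A with H3K4me1 and D870A with H3K4me1
  expect_equal(derive_state_functions(12.2e-6, -77, 298.15)$dS, -164,
               tolerance = 0.01)
  expect_equal(derive_state_functions(1.4e-6, -79, 298.15)$dS, -153,
               tolerance = 0.01)
  expect_error(derive_state_functions(-1, -50), "positive")
  expect_error(derive_state_functions(1e-6, -50, T = 0), "positive")
})

test_that("pooled t-test matches stats::t.test and handles degeneracy", {
  set.seed(42)
  a <- rnorm(5); b <- rnorm(5, 1)
  ours <- compare_groups_ttest(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # hand value from the exact summary-statistic replicates
  t13 <- compare_groups_ttest(exact_replicates(1.3, 0.32),
                              exact_replicates(4.6, 0.28))
  expect_equal(abs(t13$t), 13.44, tolerance = 1e-3)
  expect_equal(t13$df, 4)
  expect_lt(t13$p, 0.01)
  # degenerate cases
  expect_equal(compare_groups_ttest(c(1, 1), c(1, 1))$p, 1)
  expect_equal(compare_groups_ttest(c(1, 1), c(2, 2))$p, 0)
})
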