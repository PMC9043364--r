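# Single-site ("independent") ITC binding model: forward model, fitting,
# and thermodynamic state-function decomposition.

#' Gas constant, J/(mol K)
#' @keywords internal
.R_GAS <- 8.314

#' Thermodynamic parameters of a single binding reaction
#'
#' Bundles the primary fitted quantities of a 1:1 ("independent") binding
#' reaction — dissociation constant, molar enthalpy and stoichiometry —
#' with the state functions derived from them at temperature `T`:
#' \eqn{\Delta G = RT \ln K_d}, \eqn{T\Delta S = \Delta H - \Delta G},
#' \eqn{\Delta S = 1000\, T\Delta S / T}.
#'
#' @param Kd dissociation constant, molar (M); must be > 0.
#' @param dH binding enthalpy, kJ/mol.
#' @param n stoichiometric coefficient (sites per macromolecule); > 0.
#' @param T absolute temperature, K.
#' @return An object of class `"thermo_params"`: a list with fields
#'   `Kd`, `dH`, `n`, `T` and derived `dG` (kJ/mol), `TdS` (kJ/mol),
#'   `dS` (J/(mol K)).
#' @examples
#' thermo_params(Kd = 1.3e-6, dH = -89)
#' @export
thermo_params <- function(Kd, dH, n = 1, T = 298.15) {
  stopifnot(is.numeric(Kd), length(Kd) == 1L, Kd > 0,
            is.numeric(dH), length(dH) == 1L,
            is.numeric(n), length(n) == 1L, n > 0,
            is.numeric(T), length(T) == 1L, T > 0)
  sf <- derive_state_functions(Kd, dH, T)
  structure(list(Kd = Kd, dH = dH, n = n, T = T,
                 dG = sf$dG, TdS = sf$TdS, dS = sf$dS),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("Binding thermodynamics at %.2f K\n", x$T))
  cat(sprintf("  Kd  = %.4g M (%.3g uM)\n", x$Kd, x$Kd * 1e6))
  cat(sprintf("  n   = %.3f\n", x$n))
  cat(sprintf("  dH  = %.2f kJ/mol\n", x$dH))
  cat(sprintf("  dG  = %.2f kJ/mol\n", x$dG))
  cat(sprintf("  TdS = %.2f kJ/mol   (dS = %.1f J/(mol K))\n", x$TdS, x$dS))
  invisible(x)
}

#' Derive Gibbs energy and entropy from Kd and enthalpy
#'
#' \eqn{\Delta G = RT \ln(K_d)/1000} kJ/mol (with Kd in molar units,
#' R = 8.314 J/(mol K)), \eqn{T\Delta S = \Delta H - \Delta G} kJ/mol,
#' \eqn{\Delta S = 1000 \cdot T\Delta S / T} J/(mol K). The entropic term
#' multiplied by the temperature (TdS) is the customary scale on which
#' enthalpic and entropic contributions are compared.
#'
#' @param Kd dissociation constant, M (> 0).
#' @param dH binding enthalpy, kJ/mol.
#' @param T absolute temperature, K (default 298.15).
#' @return list with `dG` (kJ/mol), `TdS` (kJ/mol), `dS` (J/(mol K)).
#' @examples
#' derive_state_functions(12.2e-6, -77)  # dS approx -164 J/(mol K)
#' @export
derive_state_functions <- function(Kd, dH, T = 298.15) {
  if (any(Kd <= 0)) stop("Kd must be positive")
  if (any(T <= 0)) stop("T must be positive")
  dG <- .R_GAS * T * log(Kd) / 1000
  TdS <- dH - dG
  list(dG = dG, TdS = TdS, dS = 1000 * TdS / T)
}

#' Titration design of an ITC experiment
#'
#' @param V0 cell working volume, liters (default 185 uL, a typical
#'   low-volume calorimeter cell).
#' @param M0 initial cell (macromolecule) concentration, M.
#' @param X0 syringe (ligand/peptide) concentration, M.
#' @param inj_volumes per-injection volumes, liters; default 22 x 2 uL.
#' @param T temperature, K.
#' @return An object of class `"itc_design"`.
#' @examples
#' itc_design(M0 = 1e-4, X0 = 8e-4)
#' @export
itc_design <- function(V0 = 185e-6, M0, X0,
                       inj_volumes = rep(2e-6, 22), T = 298.15) {
  stopifnot(V0 > 0, M0 > 0, X0 > 0, T > 0,
            length(inj_volumes) >= 2L, all(inj_volumes > 0))
  structure(list(V0 = V0, M0 = M0, X0 = X0,
                 inj_volumes = as.numeric(inj_volumes), T = T),
            class = "itc_design")
}

# Effective total concentrations in the cell after cumulative injected
# volume d, under the perfusion/displacement approximation: injected
# material displaces cell content, and material in transit is counted at
# half weight.
.itc_totals <- function(design, cumulative = NULL) {
  d <- if (is.null(cumulative)) cumsum(design$inj_volumes) else cumulative
  V0 <- design$V0
  Mt <- design$M0 * (1 - d / (2 * V0)) / (1 + d / (2 * V0))
  Xt <- design$X0 * (d / V0) / (1 + d / (2 * V0))
  list(d = d, Mt = Mt, Xt = Xt)
}

#' An ITC isotherm: design plus per-injection heats
#'
#' @param design an [itc_design()].
#' @param heats per-injection integrated heats, microjoules; same length
#'   as `design$inj_volumes`.
#' @return Object of class `"itc_isotherm"` with derived `molar_ratio`
#'   (total ligand / total macromolecule in the cell after each
#'   injection).
#' @export
itc_isotherm <- function(design, heats) {
  stopifnot(inherits(design, "itc_design"),
            length(heats) == length(design$inj_volumes))
  tot <- .itc_totals(design)
  structure(list(design = design, heats = as.numeric(heats),
                 molar_ratio = tot$Xt / tot$Mt),
            class = "itc_isotherm")
}

#' @export
print.itc_isotherm <- function(x, ...) {
  cat(sprintf("ITC isotherm: %d injections, cell %.3g uM, syringe %.3g uM\n",
              length(x$heats), x$design$M0 * 1e6, x$design$X0 * 1e6))
  cat(sprintf("  molar ratio %.3f - %.3f; heat range [%.2f, %.2f] uJ\n",
              min(x$molar_ratio), max(x$molar_ratio),
              min(x$heats), max(x$heats)))
  invisible(x)
}

#' Equilibrium bound-site concentration for 1:1 mass action
#'
#' Solves the mass-action quadratic for a single class of `n` identical,
#' independent sites per macromolecule: with `b = n*Mt + Xt + Kd`, the
#' bound concentration is `0.5*(b - sqrt(b^2 - 4*n*Mt*Xt))`, evaluated in
#' the numerically stable form `2*n*Mt*Xt / (b + sqrt(b^2 - 4*n*Mt*Xt))`
#' that avoids catastrophic cancellation in the weak-binding limit.
#'
#' @param Mt total macromolecule concentration, M (vectorized).
#' @param Xt total ligand concentration, M (vectorized).
#' @param Kd dissociation constant, M (> 0).
#' @param n stoichiometric coefficient.
#' @return bound complex (occupied-site) concentration, M;
#'   `0 <= [MX] <= min(n*Mt, Xt)`.
#' @examples
#' solve_bound_concentration(8e-5, 8e-5, 1.3e-6)
#' @export
solve_bound_concentration <- function(Mt, Xt, Kd, n = 1) {
  if (any(Kd <= 0)) stop("Kd must be positive")
  if (any(Mt < 0) || any(Xt < 0)) stop("concentrations must be non-negative")
  sites <- n * Mt
  b <- sites + Xt + Kd
  disc <- b^2 - 4 * sites * Xt
  if (any(disc < -1e-12)) stop("internal error: negative discriminant")
  disc[disc < 0] <- 0
  2 * sites * Xt / (b + sqrt(disc))
}

#' Forward-model per-injection ITC heats
#'
#' Implements the cumulative-heat single-site model. After injection i
#' with cumulative injected volume d_i, the effective cell totals are
#' `Mt_i = M0 (1 - d_i/2V0)/(1 + d_i/2V0)` and
#' `Xt_i = X0 (d_i/V0)/(1 + d_i/2V0)` (perfusion displacement
#' approximation). The cumulative heat is
#' `Q_i = dH * V0 * [MX]_i * 1e9` uJ where `[MX]_i` is the bound-site
#' concentration, and the differential heat of injection i is
#' `q_i = Q_i - Q_{i-1} + (v_i/V0) * (Q_i + Q_{i-1})/2` (the last term
#' accounts for heat-producing material displaced out of the cell).
#'
#' @param truth a [thermo_params()] object (ground truth or candidate).
#' @param design an [itc_design()]; temperatures must agree.
#' @return numeric vector of per-injection heats, microjoules.
#' @examples
#' tp <- thermo_params(1.3e-6, -89)
#' d <- itc_design(M0 = 1e-4, X0 = 8e-4)
#' predict_injection_heats(tp, d)
#' @export
predict_injection_heats <- function(truth, design) {
  stopifnot(inherits(truth, "thermo_params"), inherits(design, "itc_design"))
  if (abs(truth$T - design$T) > 1e-9)
    stop("temperature mismatch between parameters and design")
  .predict_heats(truth$Kd, truth$dH, truth$n, design)
}

# internal workhorse, plain numeric parameters
.predict_heats <- function(Kd, dH, n, design) {
  tot <- .itc_totals(design)
  mx <- solve_bound_concentration(tot$Mt, tot$Xt, Kd, n)
  Q <- dH * design$V0 * mx * 1e9           # kJ/mol * L * mol/L -> kJ -> uJ
  Qprev <- c(0, Q[-length(Q)])
  v <- design$inj_volumes
  Q - Qprev + (v / design$V0) * (Q + Qprev) / 2
}

#' Subtract a dilution blank from an isotherm
#'
#' The heat of ligand dilution into buffer (measured by titrating the
#' ligand into buffer alone) is subtracted injection-by-injection, or as
#' a single mean blank heat.
#'
#' @param sample an [itc_isotherm()].
#' @param blank an [itc_isotherm()] with the same number of injections,
#'   or a single number (mean blank heat, uJ).
#' @return the corrected `"itc_isotherm"` (design unchanged).
#' @export
subtract_blank <- function(sample, blank) {
  stopifnot(inherits(sample, "itc_isotherm"))
  if (inherits(blank, "itc_isotherm")) {
    if (length(blank$heats) != length(sample$heats))
      stop("blank and sample have different injection counts; ",
           "pass a scalar mean blank heat instead")
    bh <- blank$heats
  } else if (is.numeric(blank) && length(blank) == 1L) {
    bh <- rep(blank, length(sample$heats))
  } else {
    stop("blank must be an itc_isotherm or a single mean heat")
  }
  itc_isotherm(sample$design, sample$heats - bh)
}

# Heuristic starting values: dH from the first injections (where binding
# is near-stoichiometric for moderate-to-tight isotherms), Kd from the
# molar ratio at the half-height of the cumulative heat curve.
.itc_init <- function(iso) {
  design <- iso$design
  moles_inj <- design$inj_volumes * design$X0         # mol per injection
  qnorm <- iso$heats / (moles_inj * 1e9)              # kJ/mol of injectant
  dH0 <- mean(qnorm[seq_len(min(3L, length(qnorm)))])
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -50
  cumQ <- cumsum(iso$heats)
  half <- cumQ[length(cumQ)] / 2
  idx <- which(abs(cumQ) >= abs(half))[1]
  if (is.na(idx)) idx <- ceiling(length(cumQ) / 2)
  r_half <- iso$molar_ratio[idx]
  # at the half-equivalence point the free-energy curvature is set by the
  # c-value; map r_half deviation from 1 to a crude Kd scale
  Kd0 <- design$M0 / 50
  list(Kd = Kd0, dH = dH0, n = 1, r_half = r_half)
}

#' Fit the single-site binding model to an ITC isotherm
#'
#' Least-squares fit of the independent (single-class-of-sites) model to
#' per-injection heats in microjoules, by Levenberg-Marquardt on
#' (log10 Kd, dH, n). Parameter uncertainties come from the covariance of
#' the fit (residual variance times the inverse Gauss-Newton Hessian);
#' the standard error of Kd is propagated from log10 Kd by the delta
#' method. The c-value `n*M0/Kd` is reported and fits with c < 1 are
#' flagged as being in the weak-binding regime where parameters are
#' unreliable.
#'
#' @param iso an [itc_isotherm()] (blank-corrected).
#' @param free_n fit the stoichiometry `n` (default `TRUE`) or fix n = 1.
#' @param init optional named list with starting `Kd`, `dH`, `n`.
#' @param discard_first drop the first injection before fitting (common
#'   ITC practice for an under-filled first injection); default `FALSE`.
#' @return Object of class `"itc_fit"`: `params` ([thermo_params()]),
#'   `se` (named standard errors), `residual_rms` (uJ), `converged`,
#'   `c_value`, `weak_binding`, `cov`, `fitted`, `data`, `message`.
#' @examples
#' d <- itc_design(M0 = 1e-4, X0 = 8e-4)
#' iso <- itc_isotherm(d, predict_injection_heats(thermo_params(1.3e-6, -89), d))
#' itc_fit(iso, free_n = FALSE)
#' @export
itc_fit <- function(iso, free_n = TRUE, init = NULL, discard_first = FALSE) {
  stopifnot(inherits(iso, "itc_isotherm"))
  design <- iso$design
  keep <- seq_along(iso$heats)
  if (discard_first) keep <- keep[-1]
  if (length(keep) < 6L) stop("need at least 6 informative injections")
  obs <- iso$heats[keep]

  no_signal <- all(abs(obs) < .Machine$double.eps^0.5 * max(1, abs(obs)))
  if (all(obs == 0)) {
    return(.itc_fit_failed(iso, "no signal: all heats are zero"))
  }

  st <- .itc_init(iso)
  if (!is.null(init)) st[names(init)] <- init

  resid_fn <- function(p) {
    Kd <- 10^p[["lKd"]]
    n <- if (free_n) p[["n"]] else 1
    .predict_heats(Kd, p[["dH"]], n, design)[keep] - obs
  }

  lower <- c(lKd = -12, dH = -500, if (free_n) c(n = 0.1))
  upper <- c(lKd = 0, dH = 500, if (free_n) c(n = 10))

  # multi-start over a log-Kd grid guards against the flat weak-binding
  # valley; the heuristic start is tried first
  starts <- unique(c(log10(st$Kd), -7, -6, -5, -4))
  best <- NULL
  for (l0 in starts) {
    p0 <- c(lKd = l0, dH = st$dH, if (free_n) c(n = st$n))
    ans <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(ans)) next
    if (is.null(best) || ans$deviance < best$deviance) best <- ans
  }
  if (is.null(best)) return(.itc_fit_failed(iso, "optimizer failed"))

  p <- best$par
  Kd <- 10^p[["lKd"]]
  n <- if (free_n) p[["n"]] else 1
  dH <- p[["dH"]]
  k <- length(p)
  dof <- max(1L, length(obs) - k)
  sigma2 <- best$deviance / dof
  covm <- tryCatch(sigma2 * solve(best$hessian / 2), error = function(e) NULL)
  if (is.null(covm)) covm <- matrix(NA_real_, k, k,
                                    dimnames = list(names(p), names(p)))
  se_l <- sqrt(pmax(0, diag(covm)))
  names(se_l) <- names(p)
  se <- c(Kd = unname(Kd * log(10) * se_l[["lKd"]]),
          dH = unname(se_l[["dH"]]),
          n = if (free_n) unname(se_l[["n"]]) else NA_real_)

  converged <- best$info %in% 1:4 && all(is.finite(c(Kd, dH, n)))
  c_value <- n * design$M0 / Kd
  params <- thermo_params(Kd = Kd, dH = dH, n = n, T = design$T)
  fitted <- .predict_heats(Kd, dH, n, design)
  msg <- if (!converged) best$message
         else if (c_value < 1) "weak-binding regime, parameters unreliable"
         else "ok"

  structure(list(params = params, se = se,
                 residual_rms = sqrt(mean((fitted[keep] - obs)^2)),
                 converged = converged, c_value = c_value,
                 weak_binding = c_value < 1, cov = covm,
                 fitted = fitted, data = iso, keep = keep,
                 free_n = free_n, message = msg),
            class = "itc_fit")
}

.itc_fit_failed <- function(iso, msg) {
  structure(list(params = NULL, se = c(Kd = NA, dH = NA, n = NA),
                 residual_rms = NA_real_, converged = FALSE,
                 c_value = NA_real_, weak_binding = TRUE,
                 cov = NULL, fitted = rep(NA_real_, length(iso$heats)),
                 data = iso, keep = seq_along(iso$heats),
                 free_n = NA, message = msg),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("Single-site ITC fit\n")
  if (!x$converged) {
    cat("  NOT converged:", x$message, "\n")
    return(invisible(x))
  }
  p <- x$params
  cat(sprintf("  Kd = %.4g M (%.3g +/- %.2g uM)\n",
              p$Kd, p$Kd * 1e6, x$se[["Kd"]] * 1e6))
  cat(sprintf("  dH = %.2f +/- %.2f kJ/mol\n", p$dH, x$se[["dH"]]))
  cat(sprintf("  n  = %.3f%s\n", p$n,
              if (isTRUE(x$free_n)) sprintf(" +/- %.3f", x$se[["n"]])
              else " (fixed)"))
  cat(sprintf("  dG = %.2f kJ/mol, TdS = %.2f kJ/mol, dS = %.1f J/(mol K)\n",
              p$dG, p$TdS, p$dS))
  cat(sprintf("  c = %.3g; residual RMS %.3g uJ\n", x$c_value, x$residual_rms))
  if (x$weak_binding) cat("  warning:", x$message, "\n")
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  out <- list(fit = object,
              table = if (object$converged) data.frame(
                parameter = c("Kd_uM", "dH_kJ_mol", "n", "dG_kJ_mol",
                              "TdS_kJ_mol", "dS_J_mol_K"),
                estimate = c(object$params$Kd * 1e6, object$params$dH,
                             object$params$n, object$params$dG,
                             object$params$TdS, object$params$dS),
                se = c(object$se[["Kd"]] * 1e6, object$se[["dH"]],
                       object$se[["n"]], NA, NA, NA)) else NULL)
  class(out) <- "summary.itc_fit"
  out
}

#' @export
print.summary.itc_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.itc_fit <- function(object, ...) {
  if (!object$converged) return(c(Kd = NA_real_, dH = NA_real_, n = NA_real_))
  c(Kd = object$params$Kd, dH = object$params$dH, n = object$params$n)
}

#' @export
predict.itc_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  design <- if (is.null(newdata)) object$data$design else newdata
  stopifnot(inherits(design, "itc_design"))
  .predict_heats(object$params$Kd, object$params$dH, object$params$n, design)
}

#' @export
residuals.itc_fit <- function(object, ...) {
  object$data$heats - object$fitted
}

#' @export
fitted.itc_fit <- function(object, ...) object$fitted

#' @export
simulate.itc_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sigma = 2, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, itc_isotherm(
    object$data$design,
    object$fitted + stats::rnorm(length(object$fitted), 0, noise_sigma)),
    simplify = FALSE)
}

#' Plot an ITC fit as a Wiseman isotherm
#'
#' Normalized heat (kJ per mole of injectant) against molar ratio, with
#' the fitted model curve. Normalization is used for display only; the
#' fit itself is performed on raw heats in microjoules.
#'
#' @param x an `"itc_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.itc_fit <- function(x, ...) {
  iso <- x$data
  moles <- iso$design$inj_volumes * iso$design$X0 * 1e9  # scale to uJ/kJ
  qn <- iso$heats / moles
  graphics::plot(iso$molar_ratio, qn, xlab = "molar ratio [X]/[M]",
                 ylab = "kJ/mol of injectant", ...)
  if (x$converged) graphics::lines(iso$molar_ratio, x$fitted / moles)
  invisible(x)
}

#' Pooled two-sample Student's t-test with degenerate-case handling
#'
#' Two-sided, equal-variance (pooled) Student's t-test for comparing
#' replicate binding parameters (e.g. Kd values, n = 3 replicates per
#' group). Degenerate inputs are resolved deterministically: zero pooled
#' variance with equal means gives p = 1, with unequal means p = 0.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @examples
#' compare_groups_ttest(c(0.98, 1.3, 1.62), c(4.32, 4.6, 4.88))
#' @export
compare_groups_ttest <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  na <- length(groupA); nb <- length(groupB)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(groupA) + (nb - 1) * stats::var(groupB)) / df
  dmean <- mean(groupA) - mean(groupB)
  if (sp2 <= 0) {
    if (dmean == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(dmean) * Inf, df = df, p = 0))
  }
  t <- dmean / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
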