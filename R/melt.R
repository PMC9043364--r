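# Thermal denaturation monitored by intrinsic tryptophan fluorescence:
# I328/I352 ratio curves, four-parameter logistic fits, Tm extraction,
# sigmoidality gating and group comparison by one-way ANOVA.

#' Temperature-resolved fluorescence emission spectra
#'
#' @param temperatures degrees C, strictly increasing, within \[0, 100\].
#' @param wavelengths nm grid, strictly increasing (310-410 nm expected
#'   for tryptophan emission).
#' @param intensities matrix, `length(temperatures)` rows by
#'   `length(wavelengths)` columns, arbitrary units.
#' @param replicate_id optional label.
#' @return object of class `"spectrum_series"`.
#' @export
spectrum_series <- function(temperatures, wavelengths, intensities,
                            replicate_id = NULL) {
  temperatures <- as.numeric(temperatures)
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.matrix(intensities)
  stopifnot(all(diff(temperatures) > 0),
            all(temperatures >= 0), all(temperatures <= 100),
            all(diff(wavelengths) > 0),
            nrow(intensities) == length(temperatures),
            ncol(intensities) == length(wavelengths))
  structure(list(temperatures = temperatures, wavelengths = wavelengths,
                 intensities = intensities, replicate_id = replicate_id),
            class = "spectrum_series")
}

#' A melting curve: intensity ratio against temperature
#'
#' @param temperatures degrees C.
#' @param ratio I328/I352 (or analogous) fluorescence intensity ratio,
#'   finite and positive.
#' @param replicate_id optional label.
#' @return object of class `"melt_curve"`.
#' @export
melt_curve <- function(temperatures, ratio, replicate_id = NULL) {
  temperatures <- as.numeric(temperatures)
  ratio <- as.numeric(ratio)
  stopifnot(length(ratio) == length(temperatures),
            all(is.finite(ratio)), all(ratio > 0))
  structure(list(temperatures = temperatures, ratio = ratio,
                 replicate_id = replicate_id),
            class = "melt_curve")
}

#' Reduce emission spectra to an intensity-ratio melting curve
#'
#' For each temperature, the ratio of intensities at the grid wavelength
#' nearest 328 nm to that nearest 352 nm. When blank spectra (buffer or
#' peptide solution) are supplied they are subtracted first.
#'
#' @param s a [spectrum_series()].
#' @param lam_num numerator wavelength, nm (default 328).
#' @param lam_den denominator wavelength, nm (default 352).
#' @param blank optional [spectrum_series()] of identical shape.
#' @return a [melt_curve()].
#' @export
ratio_from_spectra <- function(s, lam_num = 328, lam_den = 352,
                               blank = NULL) {
  stopifnot(inherits(s, "spectrum_series"))
  wl <- s$wavelengths
  if (lam_num < min(wl) || lam_num > max(wl) ||
      lam_den < min(wl) || lam_den > max(wl))
    stop("requested wavelength outside the spectral grid")
  ints <- s$intensities
  if (!is.null(blank)) {
    stopifnot(inherits(blank, "spectrum_series"),
              all(dim(blank$intensities) == dim(ints)))
    ints <- ints - blank$intensities
  }
  i_num <- which.min(abs(wl - lam_num))
  i_den <- which.min(abs(wl - lam_den))
  den <- ints[, i_den]
  if (any(den <= 0)) stop("non-positive denominator intensity")
  melt_curve(s$temperatures, ints[, i_num] / den, s$replicate_id)
}

#' Four-parameter logistic (two-state melting) model
#'
#' `f(x) = y0 + a / (1 + exp(-b (x - x0)))`: `y0` pre-transition level,
#' `a` transition amplitude, `b` steepness (1/degC), `x0` the inflection
#' point, taken as the melting temperature Tm. The model value at `x0`
#' is exactly `y0 + a/2`.
#'
#' @param x temperature, degrees C.
#' @param y0,a,b,x0 model parameters.
#' @return model values.
#' @export
melt_sigmoid <- function(x, y0, a, b, x0) {
  y0 + a / (1 + exp(-b * (x - x0)))
}

#' Fit the two-state melting sigmoid to a melting curve
#'
#' Least squares over (y0, a, b, x0) by Levenberg-Marquardt.
#' Initialization: y0 from the mean of the first three ratios, a from
#' last-minus-first, x0 at the temperature of steepest finite-difference
#' slope, b from the width of the central half of the amplitude. The
#' fitted inflection `x0` is the melting temperature; the `sigmoidal`
#' flag is set by [assess_sigmoidality()] and Tm is reported as `NA`
#' when the data do not support a sigmoidal model.
#'
#' @param curve a [melt_curve()] with >= 6 points.
#' @param init optional named list overriding starting values.
#' @return object of class `"melt_fit"`: `coefficients` (y0, a, b, x0),
#'   `Tm`, `se` (per-parameter standard errors), `cov`, `r_squared`,
#'   `residual_rms`, `sigmoidal`, `reasons`, `converged`, `data`.
#' @examples
#' cu <- melt_curve(seq(5, 90, 2.5), melt_sigmoid(seq(5, 90, 2.5), 1.2, -0.45, 0.35, 67.3))
#' melt_fit(cu)
#' @export
melt_fit <- function(curve, init = NULL) {
  stopifnot(inherits(curve, "melt_curve"))
  x <- curve$temperatures
  y <- curve$ratio
  if (length(x) < 6L) stop("need at least 6 points")

  # initialization per the finite-difference heuristic
  y0_0 <- mean(y[1:3])
  a_0 <- y[length(y)] - y[1]
  if (a_0 == 0) a_0 <- 1e-3
  slope <- diff(y) / diff(x)
  x0_0 <- x[which.max(abs(slope))]
  lev <- y0_0 + a_0 * c(0.25, 0.75)
  xq <- vapply(lev, function(l) {
    i <- which.min(abs(y - l)); x[i]
  }, numeric(1))
  span <- abs(diff(xq))
  b_0 <- if (span > 0) 4 / span else 0.5
  st <- list(y0 = y0_0, a = a_0, b = b_0, x0 = x0_0)
  if (!is.null(init)) st[names(init)] <- init

  resid_fn <- function(p)
    melt_sigmoid(x, p[["y0"]], p[["a"]], p[["b"]], p[["x0"]]) - y

  ans <- tryCatch(
    minpack.lm::nls.lm(par = unlist(st), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 1000, maxfev = 5000,
                         ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)

  # info 5 (evaluation cap) is kept: the sigmoidality gate judges the
  # quality of such fits via amplitude, range and standard-error checks
  if (is.null(ans) || !ans$info %in% c(1:5) || !all(is.finite(ans$par))) {
    fit <- structure(list(coefficients = c(y0 = NA, a = NA, b = NA, x0 = NA),
                          Tm = NA_real_, se = c(y0 = NA, a = NA, b = NA, x0 = NA),
                          cov = NULL, r_squared = NA_real_,
                          residual_rms = NA_real_, converged = FALSE,
                          sigmoidal = FALSE,
                          reasons = "optimizer failed", data = curve),
                     class = "melt_fit")
    return(fit)
  }

  p <- ans$par
  dof <- max(1L, length(y) - 4L)
  sigma2 <- ans$deviance / dof
  covm <- tryCatch(sigma2 * solve(ans$hessian / 2), error = function(e) NULL)
  se <- if (is.null(covm)) c(y0 = NA, a = NA, b = NA, x0 = NA)
        else stats::setNames(sqrt(pmax(0, diag(covm))),
                             c("y0", "a", "b", "x0"))
  fitted <- melt_sigmoid(x, p[["y0"]], p[["a"]], p[["b"]], p[["x0"]])
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  fit <- structure(list(coefficients = p, Tm = unname(p[["x0"]]),
                        se = se, cov = covm,
                        r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA,
                        residual_rms = sqrt(ss_res / length(y)),
                        converged = TRUE, sigmoidal = NA, reasons = NULL,
                        data = curve),
                   class = "melt_fit")
  gate <- assess_sigmoidality(fit, curve)
  fit$sigmoidal <- gate$sigmoidal
  fit$reasons <- gate$reasons
  if (!fit$sigmoidal) fit$Tm <- NA_real_
  fit
}

#' Gate a melting fit on whether the data support a sigmoid
#'
#' A fit is declared non-sigmoidal when any of: the optimizer failed;
#' the fitted amplitude is smaller than 3x the residual RMS (transition
#' indistinguishable from noise); the inflection point lies outside the
#' sampled temperature range; or the standard error of the inflection
#' exceeds 5 degrees C. This reproduces the practice of reporting "no
#' sigmoidal model" rather than a Tm for non-cooperative traces.
#'
#' @param fit a `"melt_fit"`.
#' @param curve the fitted [melt_curve()] (defaults to `fit$data`).
#' @return list with `sigmoidal` flag and character vector `reasons`
#'   naming every failed check (empty when sigmoidal).
#' @export
assess_sigmoidality <- function(fit, curve = fit$data) {
  reasons <- character()
  if (!isTRUE(fit$converged)) {
    return(list(sigmoidal = FALSE, reasons = "optimizer failed"))
  }
  p <- fit$coefficients
  if (abs(p[["a"]]) < 3 * fit$residual_rms)
    reasons <- c(reasons, "amplitude below noise")
  rng <- range(curve$temperatures)
  if (p[["x0"]] < rng[1] || p[["x0"]] > rng[2])
    reasons <- c(reasons, "inflection outside range")
  if (!is.finite(fit$se[["x0"]]) || fit$se[["x0"]] > 5)
    reasons <- c(reasons, "inflection standard error > 5 degC")
  list(sigmoidal = length(reasons) == 0L, reasons = reasons)
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("Two-state melting fit (4-parameter logistic)\n")
  if (!x$converged) {
    cat("  NOT converged:", x$reasons, "\n")
    return(invisible(x))
  }
  p <- x$coefficients
  if (x$sigmoidal) {
    cat(sprintf("  Tm = %.2f +/- %.2f degC\n", p[["x0"]], x$se[["x0"]]))
  } else {
    cat("  non-sigmoidal data; Tm undefined\n")
    cat("  reasons:", paste(x$reasons, collapse = "; "), "\n")
  }
  cat(sprintf("  y0 = %.4f, a = %.4f, b = %.4f /degC; R^2 = %.4f\n",
              p[["y0"]], p[["a"]], p[["b"]], x$r_squared))
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) object$coefficients

#' @export
summary.melt_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.melt_fit")
}

#' @export
print.summary.melt_fit <- function(x, ...) {
  print(x$fit)
  if (x$fit$converged) {
    tab <- data.frame(estimate = x$fit$coefficients, se = x$fit$se)
    print(tab)
  }
  invisible(x)
}

#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  x <- if (is.null(newdata)) object$data$temperatures else as.numeric(newdata)
  p <- object$coefficients
  melt_sigmoid(x, p[["y0"]], p[["a"]], p[["b"]], p[["x0"]])
}

#' @export
residuals.melt_fit <- function(object, ...) {
  object$data$ratio - predict(object)
}

#' @export
fitted.melt_fit <- function(object, ...) predict(object)

#' @export
plot.melt_fit <- function(x, ...) {
  cu <- x$data
  graphics::plot(cu$temperatures, cu$ratio,
                 xlab = "temperature (degC)", ylab = "I328/I352", ...)
  if (x$converged) {
    xx <- seq(min(cu$temperatures), max(cu$temperatures), length.out = 200)
    graphics::lines(xx, predict(x, xx))
    if (x$sigmoidal) graphics::abline(v = x$coefficients[["x0"]], lty = 2)
  }
  invisible(x)
}

#' One-way fixed-effects ANOVA across groups of melting temperatures
#'
#' Compares replicate Tm values across constructs/conditions. Degenerate
#' input (zero within-group variance with equal group means) gives
#' F = 0, p = 1 rather than NaN.
#'
#' @param groups list of numeric vectors, >= 2 groups of >= 2 replicates.
#' @return list with `F`, `df` (c(between, within)), `p`.
#' @examples
#' melt_anova(list(c(67.1, 67.3, 67.5), c(56.7, 56.9, 57.1)))
#' @export
melt_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, 1L) >= 2L))
  y <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  k <- length(groups)
  N <- length(y)
  gm <- mean(y)
  means <- vapply(groups, mean, numeric(1))
  ss_b <- sum(vapply(groups, length, 1L) * (means - gm)^2)
  ss_w <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  df_b <- k - 1
  df_w <- N - k
  if (ss_w == 0) {
    if (ss_b == 0) return(list(F = 0, df = c(df_b, df_w), p = 1))
    return(list(F = Inf, df = c(df_b, df_w), p = 0))
  }
  F <- (ss_b / df_b) / (ss_w / df_w)
  list(F = F, df = c(df_b, df_w), p = stats::pf(F, df_b, df_w,
                                                lower.tail = FALSE))
}
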