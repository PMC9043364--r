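# Deterministic synthetic-data generators for every input class the
# analysis stages consume: ITC isotherms, melting curves/spectra, amide
# fingerprints, relaxation series and idealized tryptophan ring pairs.
# Identical arguments (seed included) give bit-identical output.

#' Simulate an ITC isotherm with a matching dilution blank
#'
#' Heats are the forward-model prediction of
#' [predict_injection_heats()] plus additive Gaussian noise; the blank
#' is a small constant dilution heat with the same noise, mimicking the
#' titration of peptide into buffer.
#'
#' @param truth a [thermo_params()] ground truth.
#' @param design an [itc_design()]; defaults to the study conditions
#'   used throughout this package (185 uL cell, 100 uM macromolecule,
#'   800 uM peptide, 22 x 2 uL injections at 298.15 K).
#' @param noise_sigma Gaussian heat noise, uJ (default 2; 0 gives the
#'   exact forward model).
#' @param blank_heat constant dilution heat per injection, uJ.
#' @param seed RNG seed (default 0).
#' @return list with `sample` and `blank`, both [itc_isotherm()]s.
#' @examples
#' sim <- gen_isotherm(thermo_params(1.3e-6, -89), noise_sigma = 0)
#' @export
gen_isotherm <- function(truth, design = itc_design(M0 = 1e-4, X0 = 8e-4),
                         noise_sigma = 2, blank_heat = -2, seed = 0) {
  stopifnot(inherits(truth, "thermo_params"), inherits(design, "itc_design"))
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  set.seed(seed)
  q <- predict_injection_heats(truth, design)
  n <- length(q)
  noise1 <- if (noise_sigma > 0) stats::rnorm(n, 0, noise_sigma) else rep(0, n)
  noise2 <- if (noise_sigma > 0) stats::rnorm(n, 0, noise_sigma) else rep(0, n)
  list(sample = itc_isotherm(design, q + blank_heat + noise1),
       blank = itc_isotherm(design, blank_heat + noise2))
}

# basis emission spectra for the spectral mode: two log-normal-shaped
# bands; only the 328/352 ratio is contractual
.melt_basis <- function(wavelengths, peak, width = 0.05) {
  exp(-(log(wavelengths / peak))^2 / (2 * width^2))
}

#' Simulate a thermal melting experiment
#'
#' In curve mode the I328/I352 ratio follows the four-parameter logistic
#' [melt_sigmoid()] exactly (plus additive Gaussian noise). In spectral
#' mode, native and denatured basis emission spectra (log-normal bands
#' peaking near 330 and 355 nm on the 310-410 nm grid) are mixed with a
#' per-temperature fraction chosen so that the 328/352 ratio of the
#' mixture reproduces the same target curve; multiplicative noise is
#' applied to the intensities.
#'
#' @param truth named list/vector with `y0`, `a`, `b`, `x0`.
#' @param temperatures sampling schedule, degC (default 5-90 step 2.5; a
#'   5-10 degC schedule mimics the coarser instrument practice).
#' @param spectral emit a [spectrum_series()] instead of a
#'   [melt_curve()].
#' @param noise_sigma ratio noise (curve mode) or relative intensity
#'   noise (spectral mode); default 0.
#' @param seed RNG seed.
#' @return a [melt_curve()] or [spectrum_series()].
#' @examples
#' gen_melt(list(y0 = 1.2, a = -0.45, b = 0.35, x0 = 67.3))
#' @export
gen_melt <- function(truth, temperatures = seq(5, 90, by = 2.5),
                     spectral = FALSE, noise_sigma = 0, seed = 0) {
  stopifnot(all(temperatures >= 0), all(temperatures <= 100))
  set.seed(seed)
  r <- melt_sigmoid(temperatures, truth$y0, truth$a, truth$b, truth$x0)
  if (!spectral) {
    if (noise_sigma > 0)
      r <- r + stats::rnorm(length(r), 0, noise_sigma)
    return(melt_curve(temperatures, r))
  }
  wl <- 310:410
  sn <- .melt_basis(wl, 330)
  sd_ <- .melt_basis(wl, 355)
  i328 <- which.min(abs(wl - 328)); i352 <- which.min(abs(wl - 352))
  rn <- sn[i328] / sn[i352]
  rd <- sd_[i328] / sd_[i352]
  if (any(r >= rn) || any(r <= rd))
    stop("target ratio outside the basis-spectrum ratio range [",
         signif(rd, 3), ", ", signif(rn, 3), "]")
  # solve the mixing fraction phi so that the 328/352 ratio of
  # (1-phi)*native + phi*denatured equals the target r at each T
  phi <- (sn[i328] - r * sn[i352]) /
    (r * (sd_[i352] - sn[i352]) - (sd_[i328] - sn[i328]))
  ints <- outer(1 - phi, sn) + outer(phi, sd_)
  ints <- ints * 1000
  if (noise_sigma > 0)
    ints <- ints * (1 + matrix(stats::rnorm(length(ints), 0, noise_sigma),
                               nrow(ints)))
  spectrum_series(temperatures, wl, ints)
}

# hexagonal lattice fallback guaranteeing pairwise separation s in a
# w x h rectangle; returns a 2-column matrix of at least as many points
# as the lattice admits
.hex_lattice <- function(w, h, s) {
  dy <- s * sqrt(3) / 2
  pts <- NULL
  k <- 0
  y <- 0
  while (y <= h + 1e-12) {
    off <- if (k %% 2 == 1) s / 2 else 0
    x <- seq(off, w, by = s)
    pts <- rbind(pts, cbind(x, y))
    k <- k + 1
    y <- k * dy
  }
  pts
}

#' Simulate a reference/query fingerprint pair with known shifts
#'
#' Peaks are placed over the amide window (1H 6.5-10.5 ppm, 15N 105-135
#' ppm) with a minimum pairwise separation of just over twice the
#' displacement in the alphaN-scaled metric, so that nearest-neighbour
#' matching of the displaced fingerprint is unambiguous. Placement is
#' uniform rejection sampling; at densities where that jams, a randomly
#' subsampled hexagonal lattice (which attains the packing bound) is
#' used instead. Exactly `round(n_peaks * shifted_fraction)` randomly
#' chosen peaks are displaced by `displacement_ppm` (scaled metric) in a
#' random direction; the rest are jittered by `jitter_ppm`.
#'
#' @param n_peaks number of peaks (default 60, typical for a small
#'   domain fingerprint).
#' @param shifted_fraction fraction of peaks displaced, in \[0, 1\].
#' @param displacement_ppm scaled-metric displacement of shifted peaks
#'   (default 0.3).
#' @param jitter_ppm scaled-metric jitter of unshifted peaks (default
#'   0.01).
#' @param alphaN nitrogen scaling factor (default 0.17).
#' @param seed RNG seed.
#' @return list with `reference` and `query` ([peak_list()]s) and
#'   `shifted_ids` (the ground-truth displaced ids).
#' @examples
#' fp <- gen_fingerprint(60, 0.45)
#' @export
gen_fingerprint <- function(n_peaks = 60, shifted_fraction,
                            displacement_ppm = 0.3, jitter_ppm = 0.01,
                            alphaN = 0.17, seed = 0) {
  stopifnot(shifted_fraction >= 0, shifted_fraction <= 1,
            displacement_ppm > 0, jitter_ppm >= 0)
  set.seed(seed)
  w <- 10.5 - 6.5                   # 1H extent, ppm
  h <- alphaN * (135 - 105)         # scaled 15N extent, ppm
  min_sep <- 2.05 * displacement_ppm

  # rejection sampling first
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  max_tries <- 200L * n_peaks
  while (nrow(pts) < n_peaks && tries < max_tries) {
    cand <- c(stats::runif(1, 0, w), stats::runif(1, 0, h))
    ok <- nrow(pts) == 0L ||
      min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) > min_sep
    if (ok) pts <- rbind(pts, cand)
    tries <- tries + 1L
  }
  if (nrow(pts) < n_peaks) {
    lat <- .hex_lattice(w, h, min_sep * 1.0001)
    if (nrow(lat) < n_peaks)
      stop("infeasible packing: ", n_peaks, " peaks cannot be separated by ",
           signif(min_sep, 3), " ppm in the amide window")
    pts <- lat[sample.int(nrow(lat), n_peaks), , drop = FALSE]
  }

  ref <- peak_list(seq_len(n_peaks), 6.5 + pts[, 1], 105 + pts[, 2] / alphaN)
  n_shift <- round(n_peaks * shifted_fraction)
  shifted_ids <- if (n_shift > 0) sort(sample.int(n_peaks, n_shift))
                 else integer(0)
  mag <- rep(jitter_ppm, n_peaks)
  mag[shifted_ids] <- displacement_ppm
  theta <- stats::runif(n_peaks, 0, 2 * pi)
  qdH <- ref$dH + mag * cos(theta)
  qdN <- ref$dN + mag * sin(theta) / alphaN
  query <- peak_list(seq_len(n_peaks), qdH, qdN, assigned = FALSE)
  list(reference = ref, query = query, shifted_ids = shifted_ids)
}

#' Simulate relaxation data with known ground truth
#'
#' For `kind = "noe"`, per-residue saturated/reference intensity pairs
#' with `I_ref = 1` and `I_sat = noe`, under multiplicative Gaussian
#' noise. For `kind = "decay"`, mono-exponential intensity series on the
#' standard T1 (or any supplied) delay grid.
#'
#' @param profile named numeric vector: per-residue NOE truth
#'   (`kind = "noe"`) or relaxation times in seconds
#'   (`kind = "decay"`).
#' @param kind `"noe"` or `"decay"`.
#' @param delays delay grid for decay series, seconds (default
#'   [t1_delays]).
#' @param I0 initial intensity for decay series.
#' @param noise relative (multiplicative) Gaussian noise sd; default 0.
#' @param seed RNG seed.
#' @return for `"noe"`: a `"hetnoe_table"`; for `"decay"`: named list of
#'   [decay_series()].
#' @examples
#' gen_relaxation(c(W865 = 0.8, G866 = 0.6), kind = "noe")
#' @export
gen_relaxation <- function(profile, kind = c("noe", "decay"),
                           delays = t1_delays, I0 = 100,
                           noise = 0, seed = 0) {
  kind <- match.arg(kind)
  set.seed(seed)
  ids <- names(profile)
  if (is.null(ids)) ids <- seq_along(profile)
  if (kind == "noe") {
    mult <- function(n) if (noise > 0) 1 + stats::rnorm(n, 0, noise) else 1
    I_ref <- rep(1, length(profile)) * mult(length(profile))
    I_sat <- as.numeric(profile) * mult(length(profile))
    return(het_noe(I_sat, I_ref, id = ids))
  }
  out <- lapply(seq_along(profile), function(i) {
    I <- I0 * exp(-delays / profile[[i]])
    if (noise > 0) I <- I * (1 + stats::rnorm(length(I), 0, noise))
    decay_series(delays, I, id = ids[i])
  })
  names(out) <- ids
  out
}

# idealized planar indole: fused regular pentagon/hexagon, bond 1.40 A,
# in the z = 0 plane with the shared CD2-CE2 edge on the y axis
.ideal_indole <- function() {
  s <- 1.40
  r5 <- s / (2 * sin(pi / 5))       # pentagon circumradius
  a5 <- s / (2 * tan(pi / 5))       # pentagon apothem
  a6 <- s * sqrt(3) / 2             # hexagon apothem
  pent <- function(th) c(-a5 + r5 * cos(th), r5 * sin(th), 0)
  hexv <- function(th) c(a6 + s * cos(th), s * sin(th), 0)
  deg <- pi / 180
  coords <- rbind(
    CG  = pent(-108 * deg),
    CD1 = pent(180 * deg),
    NE1 = pent(108 * deg),
    CE2 = pent(36 * deg),
    CD2 = pent(-36 * deg),
    CZ2 = hexv(90 * deg),
    CH2 = hexv(30 * deg),
    CZ3 = hexv(-30 * deg),
    CE3 = hexv(-90 * deg))
  coords[TRP_RING_ATOMS, ]
}

#' Generate an idealized tryptophan ring pair at a specified angle
#'
#' Two planar nine-atom indole rings as TRP residues 1 and 2 of chain A:
#' the first in the z = 0 plane, the second rotated by `angle_deg` about
#' a shared in-plane (x) axis and translated by `separation_A` along x.
#' The unsigned inter-plane angle is `min(angle_deg, 180 - angle_deg)`
#' and the oriented (canonical ring winding) angle is `angle_deg`
#' itself. The output serializes to valid PDB text via [write_pdb()].
#'
#' @param angle_deg designed inter-plane angle, degrees in \[0, 180\].
#' @param separation_A centroid offset along the shared axis, Angstroms.
#' @param seed accepted for generator-interface uniformity; the
#'   construction is deterministic.
#' @return a single-model atom data.frame in [read_pdb()] layout.
#' @examples
#' pocket_angle(list(gen_ringpair(65)), res_pair = c(1, 2))
#' @export
gen_ringpair <- function(angle_deg, separation_A = 8, seed = 0) {
  stopifnot(angle_deg >= 0, angle_deg <= 180)
  ring1 <- .ideal_indole()
  th <- angle_deg * pi / 180
  rot_x <- matrix(c(1, 0, 0,
                    0, cos(th), -sin(th),
                    0, sin(th), cos(th)), 3, 3, byrow = TRUE)
  ring2 <- ring1 %*% t(rot_x)
  ring2[, 1] <- ring2[, 1] + separation_A
  rownames(ring2) <- rownames(ring1)
  mk <- function(ring, resno, serial0) {
    data.frame(serial = serial0 + seq_len(nrow(ring)),
               atom_name = rownames(ring), alt_loc = "",
               res_name = "TRP", chain_id = "A", res_seq = resno,
               insert = "",
               x = ring[, 1], y = ring[, 2], z = ring[, 3],
               element = substr(rownames(ring), 1, 1),
               stringsAsFactors = FALSE)
  }
  rbind(mk(ring1, 1L, 0L), mk(ring2, 2L, 9L))
}
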