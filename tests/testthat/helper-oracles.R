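# Independent oracles used across the suite. These re-derive results by
# brute force (bisection, direct numerical minimization) and never call
# the code paths they check.

# Bound-site concentration by scalar bisection on the mass-action
# equation Kd = (S - x)(Xt - x)/x with S = n*Mt total sites.
bisect_bound <- function(Mt, Xt, Kd, n = 1) {
  S <- n * Mt
  if (S == 0 || Xt == 0) return(0)
  f <- function(x) (S - x) * (Xt - x) - Kd * x
  lo <- 0
  hi <- min(S, Xt)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Out-of-plane RMS minimized directly over spherical normal angles.
plane_rms_oracle <- function(coords) {
  cc <- sweep(coords, 2, colMeans(coords))
  obj <- function(ang) {
    n <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
    mean((cc %*% n)^2)
  }
  best <- Inf
  for (th in seq(0.1, pi, length.out = 8)) {
    for (ph in seq(0, 2 * pi, length.out = 8)) {
      o <- stats::optim(c(th, ph), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-16, maxit = 5000))
      if (o$value < best) best <- o$value
    }
  }
  sqrt(best)
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# replicate triple with exact mean m and exact sd s
exact_replicates <- function(m, s) c(m - s, m, m + s)

# printed study systems: Kd (M), dH (kJ/mol), dS (J/(mol K))
study_systems <- data.frame(
  system = c("WT_me1", "WT_me2", "WT_me3", "L919A_me1",
             "D870A_me1", "D870A_me2", "D870A_me3"),
  Kd = c(1.3e-6, 4.6e-6, 14.2e-6, 12.2e-6, 1.4e-6, 7.5e-6, 18.5e-6),
  dH = c(-89, -84, -60, -77, -79, -93, -57),
  dS = c(-192, -178, -109, -164, -153, -215, -102))

# printed melting temperatures (degC)
study_tms <- c(67.3, 71.4, 71.6, 64.9, 56.9, 46.7)
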