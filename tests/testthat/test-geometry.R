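# Pocket geometry: PDB parsing, ring extraction, total-least-squares
# plane fits and inter-plane angles.

make_pdb_text <- function(models) {
  # models: list of atom data.frames in read_pdb layout
  if (length(models) == 1L) return(paste(write_pdb(models[[1]]),
                                         collapse = "\n"))
  body <- unlist(lapply(seq_along(models), function(i) {
    lines <- write_pdb(models[[i]])
    c(sprintf("MODEL     %4d", i), lines[lines != "END"], "ENDMDL")
  }))
  paste(c(body, "END"), collapse = "\n")
}

test_that("read_pdb parses records, models and altlocs", {
  one <- paste("ATOM      1  CA  ALA A   1      11.000  22.000  33.000",
               " 1.00  0.00           C", sep = "")
  m <- read_pdb(paste(one, "END", sep = "\n"))
  expect_length(m, 1)
  expect_equal(m[[1]]$atom_name, "CA")
  expect_equal(c(m[[1]]$x, m[[1]]$y, m[[1]]$z), c(11, 22, 33))
  # two MODEL blocks give two models
  ring <- gen_ringpair(40)
  txt <- make_pdb_text(list(ring, ring))
  m2 <- read_pdb(txt)
  expect_length(m2, 2)
  expect_equal(m2[[1]]$x, m2[[2]]$x, tolerance = 1e-6)
  # altloc B records are dropped, A retained
  alt <- ring[1:2, ]
  alt$alt_loc <- c("A", "B")
  alt$serial <- 1:2
  malt <- read_pdb(paste(paste(write_pdb(alt), collapse = "\n")))
  expect_equal(nrow(malt[[1]]), 1)
  expect_equal(malt[[1]]$alt_loc, "A")
})

test_that("ring extraction validates residue identity and completeness", {
  model <- gen_ringpair(65)
  ring <- extract_trp_ring(model, "A", 1)
  expect_equal(rownames(ring),
               c("CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                 "CZ2", "CZ3", "CH2"))
  expect_error(extract_trp_ring(model, "A", 9), "not found")
  notrp <- model
  notrp$res_name[notrp$res_seq == 1] <- "ALA"
  expect_error(extract_trp_ring(notrp, "A", 1), "not a tryptophan")
  incomplete <- model[model$atom_name != "CH2", ]
  expect_error(extract_trp_ring(incomplete, "A", 1), "CH2")
})

test_that("plane fit is exact on planar rings and optimal off-plane", {
  ring <- extract_trp_ring(gen_ringpair(0), "A", 1)
  pf <- fit_plane(ring)
  expect_equal(pf$rms_out_of_plane, 0, tolerance = 1e-12)
  expect_equal(sum(pf$normal^2), 1, tolerance = 1e-12)
  # normal orthogonal to every in-plane edge vector
  edges <- sweep(ring[-1, ], 2, ring[1, ])
  expect_equal(max(abs(edges %*% pf$normal)), 0, tolerance = 1e-10)
  # one atom displaced along the normal: rms matches the independent
  # direct minimization oracle
  bumped <- ring
  bumped[5, 3] <- bumped[5, 3] + 0.1
  pf2 <- fit_plane(bumped)
  expect_equal(pf2$rms_out_of_plane, plane_rms_oracle(bumped),
               tolerance = 1e-9)
  # and beats 1000 random candidate planes through the centroid
  set.seed(8)
  cc <- sweep(bumped, 2, colMeans(bumped))
  rand_rms <- replicate(1000, {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    sqrt(mean((cc %*% n)^2))
  })
  expect_lte(pf2$rms_out_of_plane, min(rand_rms))
  expect_error(fit_plane(matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), 3,
                                byrow = TRUE)), "collinear")
})

test_that("plane fits and angles are rigid-motion invariant", {
  set.seed(13)
  model <- gen_ringpair(37.3)
  r1 <- extract_trp_ring(model, "A", 1)
  r2 <- extract_trp_ring(model, "A", 2)
  base <- interplane_angle(fit_plane(r1), fit_plane(r2))
  for (i in 1:5) {
    R <- random_rotation()
    t <- rnorm(3, 0, 50)
    m1 <- sweep(r1 %*% t(R), 2, t, "+")
    m2 <- sweep(r2 %*% t(R), 2, t, "+")
    rownames(m1) <- rownames(r1); rownames(m2) <- rownames(r2)
    moved <- interplane_angle(fit_plane(m1), fit_plane(m2),
                              list(newell_normal(m1), newell_normal(m2)))
    expect_equal(moved$angle_unsigned, base$angle_unsigned,
                 tolerance = 1e-9)
    expect_equal(moved$angle_oriented, 37.3, tolerance = 1e-9)
    # the fitted normal rotates with the ring
    expect_equal(abs(sum((fit_plane(m1)$normal) %*% R %*%
                           fit_plane(r1)$normal)), 1, tolerance = 1e-10)
  }
})

test_that("interplane angle identities hold", {
  m <- gen_ringpair(30)
  p1 <- fit_plane(extract_trp_ring(m, "A", 1))
  p2 <- fit_plane(extract_trp_ring(m, "A", 2))
  expect_equal(interplane_angle(p1, p1)$angle_unsigned, 0)
  ang <- interplane_angle(p1, p2)
  expect_equal(ang$angle_unsigned, 30, tolerance = 1e-6)
  # symmetry in the arguments
  rev <- interplane_angle(p2, p1)
  expect_equal(rev$angle_unsigned, ang$angle_unsigned, tolerance = 1e-12)
  # unsigned is the acute representative of oriented
  for (a in c(20, 65, 113, 160)) {
    pa <- pocket_angle(list(gen_ringpair(a)), res_pair = c(1, 2))
    expect_equal(pa$angle_oriented, a, tolerance = 1e-6)
    expect_equal(pa$angle_unsigned, min(a, 180 - a), tolerance = 1e-6)
  }
})

test_that("pocket_angle composes over models and chains", {
  m45 <- gen_ringpair(45)
  pa <- pocket_angle(list(m45), res_pair = c(1, 2))
  expect_equal(pa$angle_unsigned, 45, tolerance = 1e-6)
  # multi-model ensemble: headline is model 1, spread is reported
  ens <- list(gen_ringpair(60), gen_ringpair(70), gen_ringpair(80))
  pe <- pocket_angle(ens, res_pair = c(1, 2))
  expect_equal(nrow(pe$per_model), 3)
  expect_equal(pe$angle_unsigned, 60, tolerance = 1e-6)
  expect_equal(pe$mean, 70, tolerance = 1e-6)
  expect_equal(pe$range, c(60, 80), tolerance = 1e-6)
  # file path input works end to end
  tf <- tempfile(fileext = ".pdb")
  write_pdb(m45, tf)
  # PDB serialization rounds coordinates to 1e-3 Angstroms
  pa2 <- pocket_angle(tf, res_pair = c(1, 2))
  expect_equal(pa2$angle_unsigned, 45, tolerance = 0.005)
})
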