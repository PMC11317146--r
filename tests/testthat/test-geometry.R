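# Glycosidic torsion, base frames, pair parameters, superposition

make_chi_residue <- function(chi_deg, resname = "DC") {
  # four defining atoms with an exact constructed torsion: C2 and N1 on
  # the rotation axis, C1' off-axis, O4' rotated about the axis by chi
  c2 <- c(0, 0, 0); n1 <- c(1.4, 0, 0)
  c1 <- n1 + c(0.47, 1.4, 0)
  axis <- (c1 - n1) / sqrt(sum((c1 - n1)^2))
  perp <- c(1, 0, 0) - sum(c(1, 0, 0) * axis) * axis
  perp <- perp / sqrt(sum(perp^2))
  th <- chi_deg * pi / 180
  kx <- pracma::cross(axis, perp)
  dirn <- -perp * cos(th) + kx * sin(th)  # chi measured from the C2 side
  o4 <- c1 + 1.41 * dirn
  as_structure(data.frame(
    name = c("C2", "N1", "C1'", "O4'"), resname = resname, chain = "A",
    resnum = 1, x = c(c2[1], n1[1], c1[1], o4[1]),
    y = c(c2[2], n1[2], c1[2], o4[2]),
    z = c(c2[3], n1[3], c1[3], o4[3])))$atoms
}

test_that("glycosidic torsion matches an independent dihedral oracle", {
  for (chi in c(-179, -120, -90.0001, -45, 0, 55, 90, 135, 180)) {
    ra <- make_chi_residue(chi)
    got <- glycosidic_chi(ra)
    ora <- oracle_dihedral(
      as.numeric(ra[ra$name == "O4'", c("x", "y", "z")]),
      as.numeric(ra[ra$name == "C1'", c("x", "y", "z")]),
      as.numeric(ra[ra$name == "N1", c("x", "y", "z")]),
      as.numeric(ra[ra$name == "C2", c("x", "y", "z")]))
    expect_equal(got$chi, ora, tolerance = 1e-6)
    expect_equal(got$call,
                 if (got$chi > -90 && got$chi <= 90) "syn" else "anti")
  }
  # exactly planar-trans is anti; +60 is syn
  expect_equal(glycosidic_chi(make_chi_residue(180))$call, "anti")
  expect_equal(glycosidic_chi(make_chi_residue(60))$chi, 60,
               tolerance = 1e-6)
  expect_equal(glycosidic_chi(make_chi_residue(60))$call, "syn")
})

test_that("chi is undefined, not wrong, when a defining atom is missing", {
  ra <- make_chi_residue(60)
  got <- glycosidic_chi(ra[ra$name != "O4'", ])
  expect_true(is.na(got$chi))
  expect_equal(got$call, "undefined")
})

test_that("chi is invariant under rigid motion", {
  m <- build_pair(pair_spec(geometry = "WC", chi_pyr = -117))
  ref <- glycosidic_chi(res_atoms_of(m, "A", 1))$chi
  for (seed in 1:10) {
    R <- random_rotation(seed)
    m2 <- rigid_transform(m, R, t = c(seed, -seed, 2 * seed))
    expect_equal(glycosidic_chi(res_atoms_of(m2, "A", 1))$chi, ref,
                 tolerance = 1e-6)
  }
})

test_that("base frame recovers identity and known rigid motions", {
  m <- build_pair(pair_spec(geometry = "WC"))
  ra <- res_atoms_of(m, "A", 1)
  f <- base_frame(ra)
  expect_lt(f$residual, 1e-6)
  expect_equal(f$origin, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(f$axes, diag(3), tolerance = 1e-6)
  expect_equal(crossprod(f$axes), diag(3), tolerance = 1e-8)

  for (seed in 1:5) {
    R <- random_rotation(seed); tr <- c(1, 2, 3) * seed
    m2 <- rigid_transform(m, R, tr)
    f2 <- base_frame(res_atoms_of(m2, "A", 1))
    expect_equal(f2$axes, R, tolerance = 1e-6)
    expect_equal(f2$origin, as.numeric(tr), tolerance = 1e-6)
  }
})

test_that("base frame degrades gracefully under coordinate noise", {
  m <- build_pair(pair_spec(geometry = "WC"))
  angs <- residuals <- numeric(20)
  for (seed in 1:20) {
    m2 <- perturb(m, sd = 0.05, seed = seed)
    f2 <- base_frame(res_atoms_of(m2, "A", 1))
    residuals[seed] <- f2$residual
    cosang <- (sum(diag(crossprod(f2$axes, diag(3)))) - 1) / 2
    angs[seed] <- acos(pmin(1, cosang)) * 180 / pi
  }
  expect_lt(mean(residuals), 0.15)   # sigma-scale fit residual
  expect_gt(mean(residuals), 0.02)
  expect_lt(mean(angs), 2)           # frame near truth on average
  expect_true(all(angs < 5))
})

test_that("insufficient ring atoms is an explicit error", {
  m <- build_pair(pair_spec(geometry = "WC"))
  ra <- res_atoms_of(m, "A", 1)
  expect_error(base_frame(ra[1:6, ]), "insufficient ring atoms")
})

test_that("ideal WC pair has all six rigid-body parameters at zero", {
  m <- build_pair(pair_spec(geometry = "WC"))
  p <- pair_parameters(res_atoms_of(m, "A", 1), res_atoms_of(m, "B", 2))
  for (f in c("shear", "stretch", "stagger", "buckle", "propeller",
              "opening"))
    expect_equal(p[[f]], 0, tolerance = 1e-6)
  expect_lt(abs(p$lambda_Y - p$lambda_R), 1)
})

test_that("lambda angles and C1'-C1' agree with direct vector arithmetic", {
  m <- build_pair(pair_spec(geometry = "aWC", shear = 0.9))
  ra <- res_atoms_of(m, "A", 1); rb <- res_atoms_of(m, "B", 2)
  p <- pair_parameters(ra, rb)
  c1a <- as.numeric(ra[ra$name == "C1'", c("x", "y", "z")])
  c1b <- as.numeric(rb[rb$name == "C1'", c("x", "y", "z")])
  expect_equal(p$c1c1, sqrt(sum((c1a - c1b)^2)), tolerance = 1e-9)
  n1 <- as.numeric(ra[ra$name == "N1", c("x", "y", "z")])
  v1 <- n1 - c1a; v2 <- c1b - c1a
  lamY <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(p$lambda_Y, lamY, tolerance = 1e-9)
})

test_that("pair parameters are recovered across a grid of built values", {
  grid <- expand.grid(shear = c(-1.2, 0, 0.8), buckle = c(-10, 0, 15),
                      opening = c(-4, 0, 6))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    m <- build_pair(pair_spec(geometry = "WC", shear = g$shear,
                              stretch = 0.25, stagger = -0.3,
                              buckle = g$buckle, propeller = -8,
                              opening = g$opening))
    p <- pair_parameters(res_atoms_of(m, "A", 1), res_atoms_of(m, "B", 2))
    expect_equal(p$shear, g$shear, tolerance = 1e-3)
    expect_equal(p$stretch, 0.25, tolerance = 1e-3)
    expect_equal(p$stagger, -0.3, tolerance = 1e-3)
    expect_equal(p$buckle, g$buckle, tolerance = 1e-3)
    expect_equal(p$propeller, -8, tolerance = 1e-3)
    expect_equal(p$opening, g$opening, tolerance = 1e-3)
  }
})

test_that("superposition RMSD matches the SVD oracle and its invariances", {
  s <- build_duplex(duplex_spec())
  m <- first_model(s)
  expect_equal(superpose_rmsd(m, m), 0, tolerance = 1e-9)

  m2 <- rigid_transform(m, random_rotation(7), c(3, -2, 9))
  expect_lt(superpose_rmsd(m, m2), 1e-6)

  # displace one atom by d and check against direct enumeration
  m3 <- m
  m3$atoms$x[10] <- m3$atoms$x[10] + 1.7
  nuc <- m$atoms$category == "nucleotide"
  A <- as.matrix(m$atoms[nuc, c("x", "y", "z")])
  B <- as.matrix(m3$atoms[nuc, c("x", "y", "z")])
  expect_equal(superpose_rmsd(m, m3), oracle_kabsch_rmsd(A, B),
               tolerance = 1e-9)
  # symmetry
  expect_equal(superpose_rmsd(m, m3), superpose_rmsd(m3, m),
               tolerance = 1e-9)
  # cross-check against bio3d's fitted RMSD (printed at 3 decimals)
  expect_lt(abs(superpose_rmsd(m, m3) -
                  bio3d::rmsd(as.vector(t(A)), as.vector(t(B)),
                              fit = TRUE)), 6e-4)
})

test_that("superposition with no correspondence lists unmatched residues", {
  s <- build_duplex(duplex_spec())
  m <- first_model(s)
  m2 <- m
  m2$atoms$chain <- "Z"
  expect_error(superpose_rmsd(m, m2), "unmatched")
})
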