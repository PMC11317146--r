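# The fixture generator: determinism, noise model, feasibility guards,
# full generator -> analyzer round trips

test_that("building is deterministic in the seed", {
  s1 <- build_duplex(duplex_spec(noise_sd = 0.05, seed = 7))
  s2 <- build_duplex(duplex_spec(noise_sd = 0.05, seed = 7))
  s3 <- build_duplex(duplex_spec(noise_sd = 0.05, seed = 8))
  expect_identical(s1$atoms, s2$atoms)
  expect_gt(max(abs(s1$atoms$x - s3$atoms$x)), 0)
})

test_that("perturb is the identity at zero noise and seed-reproducible", {
  m <- build_pair(pair_spec(geometry = "WC"))
  expect_identical(perturb(m, 0, seed = 1)$atoms, m$atoms)
  p1 <- perturb(m, 0.05, seed = 5)
  p2 <- perturb(m, 0.05, seed = 5)
  expect_identical(p1$atoms, p2$atoms)
  expect_false(identical(p1$atoms, perturb(m, 0.05, seed = 6)$atoms))
})

test_that("perturb leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(perturb(build_pair(pair_spec(geometry = "WC")), 0.1, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("the noise model has the chi-distributed displacement magnitude", {
  # E|displacement| for isotropic 3D Gaussian noise = sd * 2 * sqrt(2/pi)
  s <- build_duplex(duplex_spec())
  sd <- 0.05
  disp <- c()
  for (seed in 1:4) {
    p <- perturb(s, sd, seed = seed)
    d <- as.matrix(p$atoms[, c("x", "y", "z")]) -
      as.matrix(s$atoms[, c("x", "y", "z")])
    disp <- c(disp, sqrt(rowSums(d^2)))
  }
  expect_equal(mean(disp), sd * 2 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("infeasible water placement errors with the violated inequality", {
  expect_error(
    build_pair(pair_spec(pyr = "5CM", geometry = "(w)cWH",
                         water = list(atoms = c("O2", "N7"),
                                      distances = c(1.0, 1.0)))),
    "triangle")
})

test_that("altloc plans validate occupancies and labels", {
  expect_error(duplex_spec(altlocs = list(
    list(label = "A", occupancy = 0.8, spec = pair_spec(geometry = "WC")),
    list(label = "B", occupancy = 0.1, spec = pair_spec(geometry = "WC")))),
    "sum to 1")
  expect_error(duplex_spec(altlocs = list(
    list(label = "A", occupancy = 0.5, spec = pair_spec(geometry = "WC")),
    list(label = "A", occupancy = 0.5, spec = pair_spec(geometry = "WC")))),
    "clashing")
})

test_that("Hoogsteen geometries demand a syn purine", {
  expect_error(pair_spec(pyr = "5CM", geometry = "(w)cWH", chi_pur = -117),
               "syn")
})

test_that("chi targets are recovered across the generator grid", {
  for (chi in c(-150, -117, -60.0001, 55, 90)) {
    m <- build_pair(pair_spec(geometry = "WC", chi_pyr = chi,
                              chi_pur = chi))
    expect_equal(glycosidic_chi(res_atoms_of(m, "A", 1))$chi, chi,
                 tolerance = 1e-3)
    expect_equal(glycosidic_chi(res_atoms_of(m, "B", 2))$chi, chi,
                 tolerance = 1e-3)
  }
})

test_that("every geometry class is recovered at zero noise over base types", {
  cases <- list(
    list(spec = pair_spec(pyr = "DC", pur = "DG", geometry = "WC"),
         want = "WC"),
    list(spec = pair_spec(pyr = "5CM", pur = "DG", geometry = "WC"),
         want = "WC"),
    list(spec = pair_spec(pyr = "DT", pur = "DA", geometry = "WC"),
         want = "WC"),
    list(spec = pair_spec(pyr = "DC", pur = "DG", geometry = "aWC"),
         want = "aWC"),
    list(spec = pair_spec(pyr = "5CM", pur = "DG", geometry = "aWC"),
         want = "aWC"),
    list(spec = pair_spec(pyr = "DC", pur = "DG", geometry = "cWH"),
         want = "cWH"),
    list(spec = pair_spec(pyr = "5CM", pur = "DG", geometry = "cWH"),
         want = "cWH"),
    list(spec = pair_spec(pyr = "5CM", pur = "DG", geometry = "(w)cWH"),
         want = "(w)cWH"),
    list(spec = pair_spec(pyr = "DC", pur = "DI", geometry = "nonWC"),
         want = "nonWC"))
  for (cs in cases) {
    pairs <- detect_base_pairs(build_pair(cs$spec))
    expect_length(pairs, 1L)
    expect_equal(pairs[[1]]$label, cs$want)
  }
})

test_that("occupancy bookkeeping survives write -> read -> expand -> enumerate", {
  for (split in list(c(0.9, 0.1), c(0.6, 0.4), c(0.7, 0.3))) {
    s <- build_duplex(polymorphic_duplex(split[1], split[2]))
    f <- withr::local_tempfile(fileext = ".pdb")
    write_structure(s, f)
    s2 <- read_structure(f)
    models <- expand_conformers(s2)
    expect_equal(vapply(models, `[[`, numeric(1), "occupancy"), split,
                 tolerance = 1e-2)
    tab <- enumerate_pair_conformers(s2)
    central <- tab[tab$conformer != "", ]
    expect_equal(sort(central$occupancy), sort(split), tolerance = 1e-2)
    expect_setequal(central$label, c("aWC", "(w)cWH"))
  }
})

test_that("placeholder ligand rings are emitted and categorized as ligand", {
  s <- build_duplex(duplex_spec(ligands = 3L))
  lig <- s$atoms[s$atoms$resname == "LIG", ]
  expect_equal(nrow(lig), 6L)
  expect_equal(unique(lig$category), "ligand")
  # the ring is planar and stacked between steps 3 and 4
  expect_equal(sd(lig$z), 0, tolerance = 1e-9)
})
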