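# Hydrogen bonds, bifurcation, water bridges, ion shells

test_that("atoms beyond the cutoff are not bonded", {
  s <- as_structure(data.frame(
    name = c("N4", "O6"), resname = c("DC", "DG"), chain = c("A", "B"),
    resnum = c(1, 2), x = c(0, 5), y = 0, z = 0))
  m <- first_model(s)
  expect_equal(nrow(find_hbonds(m)), 0L)
  expect_equal(nrow(find_hbonds(m, cutoff = 5.5)), 1L)
})

test_that("an ideal WC C:G pair has exactly the three canonical bonds", {
  m <- build_pair(pair_spec(geometry = "WC"))
  hb <- find_hbonds(m)
  expect_equal(nrow(hb), 3L)
  got <- sort(paste(hb$donor_atom, hb$acceptor_atom))
  expect_equal(got, sort(c("N4 O6", "N1 N3", "N2 O2")))
  # brute-force scan: every reported bond is a real distance under cutoff
  for (k in seq_len(nrow(hb)))
    expect_lte(hb$distance[k], 3.5)
  bf <- brute_contacts(m, "A", 1, "B", 2, 3.5)
  bfpairs <- paste(bf$a, bf$b)
  expect_true(all(paste(hb$donor_atom, hb$acceptor_atom) %in% bfpairs |
                    paste(hb$acceptor_atom, hb$donor_atom) %in% bfpairs))
})

test_that("the water-mediated Hoogsteen exemplar has the printed bond set", {
  m <- build_pair(pair_spec(pyr = "5CM", geometry = "(w)cWH"))
  hb <- find_hbonds(m)
  base_hb <- hb[hb$donor_res != "S|101|" & hb$acceptor_res != "S|101|", ]
  pairs <- paste(base_hb$donor_atom, base_hb$acceptor_atom)
  expect_true("N4 O6" %in% pairs)   # direct amino-to-carbonyl bond
  expect_true("N3 O6" %in% pairs)   # bifurcated, protonation-assumed
  expect_false(any(grepl("^O2 N7$|^N7 O2$", pairs)))  # bridged, not direct
  expect_true(base_hb$protonation_assumed[
    base_hb$donor_atom == "N3" & base_hb$acceptor_atom == "O6"])
})

test_that("bifurcation grouping follows shared-terminus logic", {
  m <- build_pair(pair_spec(pyr = "5CM", geometry = "(w)cWH"))
  hb <- detect_bifurcated(find_hbonds(m))
  shared <- hb[hb$acceptor_atom == "O6" &
                 hb$donor_atom %in% c("N4", "N3"), ]
  expect_equal(nrow(shared), 2L)
  expect_length(unique(shared$bifurcated_group), 1L)
  expect_false(any(is.na(shared$bifurcated_group)))

  # bonds without a shared terminus on the same partner form no group
  wc <- detect_bifurcated(find_hbonds(build_pair(pair_spec(geometry = "WC"))))
  expect_true(all(is.na(wc$bifurcated_group)))
  # empty in, empty out
  empty <- find_hbonds(first_model(as_structure(data.frame(
    name = "O", resname = "HOH", chain = "W", resnum = 1,
    x = 0, y = 0, z = 0))))
  expect_equal(nrow(detect_bifurcated(empty)), 0L)
})

test_that("water bridges require both legs under the cutoff", {
  dry <- build_pair(pair_spec(geometry = "WC"))
  expect_equal(nrow(find_water_bridges(dry)), 0L)

  m <- build_pair(pair_spec(pyr = "5CM", geometry = "(w)cWH"))
  br <- find_water_bridges(m)
  edge <- br[(br$atom1 == "O2" & br$atom2 == "N7") |
               (br$atom1 == "N7" & br$atom2 == "O2"), ]
  expect_equal(nrow(edge), 1L)
  # the two stored distances re-verify by direct computation
  rid <- function(a) paste(a$chain, a$resnum, a$icode, sep = "|")
  at_xyz <- function(r, nm) {
    a <- m$atoms
    as.numeric(a[rid(a) == r & a$name == nm, c("x", "y", "z")])
  }
  w <- at_xyz(edge$water_res, "O")
  expect_equal(edge$dist1, sqrt(sum((w - at_xyz(edge$res1, edge$atom1))^2)),
               tolerance = 1e-9)
  expect_equal(edge$dist2, sqrt(sum((w - at_xyz(edge$res2, edge$atom2))^2)),
               tolerance = 1e-9)
  expect_equal(sort(c(edge$dist1, edge$dist2)), c(2.8, 2.9),
               tolerance = 1e-6)

  # pull the water out of range of one partner: bridge disappears
  m2 <- m
  wi <- which(m2$atoms$resname == "HOH")
  n7 <- as.numeric(m2$atoms[m2$atoms$name == "N7", c("x", "y", "z")])
  w <- as.numeric(m2$atoms[wi, c("x", "y", "z")])
  m2$atoms[wi, c("x", "y", "z")] <- as.list(n7 + (w - n7) * (4.2 / 2.9))
  br2 <- find_water_bridges(m2)
  expect_equal(nrow(br2[(br2$atom1 == "O2" & br2$atom2 == "N7") |
                          (br2$atom1 == "N7" & br2$atom2 == "O2"), ]), 0L)
})

test_that("bond sets are monotone in the cutoff and rigid-motion invariant", {
  s <- build_duplex(duplex_spec(noise_sd = 0.05, seed = 3))
  m <- first_model(s)
  keyset <- function(hb) paste(hb$donor_res, hb$donor_atom,
                               hb$acceptor_res, hb$acceptor_atom)
  prev <- character(0)
  for (cutoff in c(2.8, 3.1, 3.4, 3.7)) {
    cur <- keyset(find_hbonds(m, cutoff = cutoff))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  ref <- sort(keyset(find_hbonds(m)))
  for (seed in 1:5) {
    m2 <- rigid_transform(m, random_rotation(seed), c(-2, 4, 1) * seed)
    expect_equal(sort(keyset(find_hbonds(m2))), ref)
  }
})

test_that("ion shells label octahedral and non-octahedral coordination", {
  expect_length(ion_shell(build_pair(pair_spec(geometry = "WC"))), 0L)

  axes6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)) * 2.2
  mk <- function(naxes) {
    pts <- axes6[seq_len(naxes), , drop = FALSE]
    as_structure(rbind(
      data.frame(name = "MN", resname = "MN", chain = "M", resnum = 1,
                 x = 0, y = 0, z = 0),
      data.frame(name = "O", resname = "HOH", chain = "W",
                 resnum = seq_len(naxes) + 10,
                 x = pts[, 1], y = pts[, 2], z = pts[, 3])))
  }
  sh6 <- ion_shell(first_model(mk(6)))
  expect_length(sh6, 1L)
  expect_equal(sh6[[1]]$geometry, "octahedral")
  expect_equal(nrow(sh6[[1]]$ligands), 6L)
  expect_equal(sh6[[1]]$ligands$distance, rep(2.2, 6), tolerance = 1e-9)

  sh4 <- ion_shell(first_model(mk(4)))
  expect_equal(sh4[[1]]$geometry, "other")
})
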