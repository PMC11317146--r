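# Pair detection, geometry taxonomy, duplex assembly, conformer
# enumeration

test_that("detection requires edge bonding, distance and coplanarity", {
  # a single nucleotide pairs with nothing
  m1 <- first_model(build_duplex(duplex_spec()))
  solo <- m1
  solo$atoms <- solo$atoms[solo$atoms$chain == "A" & solo$atoms$resnum == 1, ]
  expect_length(detect_base_pairs(solo), 0L)

  # a full ideal duplex yields exactly one pair per step
  expect_length(detect_base_pairs(m1), 7L)

  # two bases stacked 3.4 A apart (plane normals parallel) are in
  # contact but have no pairing-range C1'-C1' separation: not a pair
  p <- build_pair(pair_spec(geometry = "WC"))
  stacked <- p
  stacked$atoms <- stacked$atoms[stacked$atoms$chain == "A", ]
  top <- stacked$atoms
  top$z <- top$z + 3.4
  top$chain <- "B"; top$resnum <- 2
  stacked$atoms <- rbind(stacked$atoms, top)
  expect_length(detect_base_pairs(stacked), 0L)
})

test_that("every taxonomy exemplar is classified as built", {
  for (nm in names(taxonomy_specs())) {
    m <- build_pair(taxonomy_specs()[[nm]])
    pairs <- detect_base_pairs(m)
    expect_length(pairs, 1L)
    expect_equal(pairs[[1]]$label, nm)
  }
})

test_that("classification rule details behave at the thresholds", {
  # shear 0.9 with canonical bonds and anti-anti crosses into aWC
  m <- build_pair(pair_spec(geometry = "WC", shear = 0.9))
  expect_equal(detect_base_pairs(m)[[1]]$label, "aWC")
  # shear within threshold stays WC
  m <- build_pair(pair_spec(geometry = "WC", shear = 0.5))
  expect_equal(detect_base_pairs(m)[[1]]$label, "WC")
  # the C:I pair is anti-anti on the WC edge but non-canonical
  m <- build_pair(pair_spec(geometry = "nonWC"))
  bp <- detect_base_pairs(m)[[1]]
  expect_equal(bp$label, "nonWC")
  expect_equal(bp$chi_i$call, "anti")
  expect_equal(bp$chi_j$call, "anti")
  bonds <- paste(bp$hbonds$atom_i, bp$hbonds$atom_j)
  expect_true("N3 N1" %in% bonds)
  expect_false(any(grepl("N2", bonds)))  # inosine has no N2
  # the water-mediated exemplar is cis with a syn purine
  m <- build_pair(pair_spec(pyr = "5CM", geometry = "(w)cWH"))
  bp <- detect_base_pairs(m)[[1]]
  expect_equal(bp$orientation, "cis")
  expect_equal(bp$chi_j$call, "syn")
  expect_equal(bp$label, "(w)cWH")
})

test_that("labels are a deterministic function of stored evidence", {
  s <- build_duplex(polymorphic_duplex(0.9, 0.1))
  tab <- enumerate_pair_conformers(s)
  for (bp in attr(tab, "pairs"))
    expect_equal(classify_geometry(bp), bp$label)
})

test_that("duplex assembly chains pairs through backbone connectivity", {
  m <- first_model(build_duplex(duplex_spec()))
  pairs <- detect_base_pairs(m)
  dups <- build_duplexes(pairs, m)
  expect_length(dups, 1L)
  expect_length(dups[[1]]$pairs, 7L)

  # two disjoint duplexes in one model give two chains
  s1 <- build_duplex(duplex_spec())
  s2 <- build_duplex(duplex_spec())
  a2 <- s2$atoms
  a2$x <- a2$x + 60
  a2$chain <- chartr("AB", "CD", a2$chain)
  both <- as_structure(rbind(s1$atoms, a2), entry = "TWO")
  m2 <- first_model(both)
  d2 <- build_duplexes(detect_base_pairs(m2), m2)
  expect_length(d2, 2L)
  expect_equal(vapply(d2, function(d) length(d$pairs), integer(1)),
               c(7L, 7L))
})

test_that("duplex count is invariant under atom-record reordering", {
  s <- build_duplex(duplex_spec())
  set.seed(42)
  s2 <- as_structure(s$atoms[sample(nrow(s$atoms)), ], entry = "PERM")
  m2 <- first_model(s2)
  d <- build_duplexes(detect_base_pairs(m2), m2)
  expect_length(d, 1L)
  expect_length(d[[1]]$pairs, 7L)
})

test_that("conformer enumeration attaches the deposited occupancy splits", {
  # single-conformer duplex: everything at occupancy 1
  tab <- enumerate_pair_conformers(build_duplex(duplex_spec()))
  expect_equal(tab$occupancy, rep(1, 7))
  expect_equal(tab$label, rep("WC", 7))

  for (split in list(c(0.9, 0.1), c(0.6, 0.4), c(0.7, 0.3))) {
    s <- build_duplex(polymorphic_duplex(split[1], split[2]))
    tab <- enumerate_pair_conformers(s)
    central <- tab[tab$conformer != "", ]
    expect_equal(nrow(central), 2L)
    expect_equal(sort(central$occupancy), sort(split))
    expect_equal(central$label[central$conformer == "A"], "aWC")
    expect_equal(central$label[central$conformer == "B"], "(w)cWH")
    # occupancy conservation for the polymorphic pair
    expect_lte(sum(central$occupancy), 1 + 1e-6)
    # non-polymorphic pairs are merged, not duplicated
    expect_equal(sum(tab$conformer == ""), 6L)
  }
})
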