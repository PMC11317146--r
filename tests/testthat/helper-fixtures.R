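# Shared fixtures and independent oracles.  The oracles deliberately use
# different formulations than the package internals (acos/triple-product
# dihedral instead of atan2; direct SVD Kabsch instead of bio3d).

# signed dihedral via plane normals + scalar triple product (IUPAC sign:
# looking along b->c, d clockwise from a is positive)
oracle_dihedral <- function(a, b, c, d) {
  n1 <- pracma::cross(b - a, c - b)
  n2 <- pracma::cross(c - b, d - c)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (sum(pracma::cross(n1, n2) * (c - b)) > 0) ang <- -ang
  ang
}

# least-squares superposition RMSD by direct SVD
oracle_kabsch_rmsd <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(t(A0) %*% B0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((B0 - A0 %*% t(R))^2)))
}

# random rotation matrix from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# atoms of one residue from a model/structure
res_atoms_of <- function(model, chain, resnum) {
  a <- if (inherits(model, "nastructure")) model$atoms else model$atoms
  a[a$chain == chain & a$resnum == resnum, , drop = FALSE]
}

# distance between two named atoms, straight from coordinates
atom_dist <- function(model, chain1, resnum1, name1, chain2, resnum2, name2) {
  r1 <- res_atoms_of(model, chain1, resnum1)
  r2 <- res_atoms_of(model, chain2, resnum2)
  p1 <- as.numeric(r1[r1$name == name1, c("x", "y", "z")])
  p2 <- as.numeric(r2[r2$name == name2, c("x", "y", "z")])
  sqrt(sum((p1 - p2)^2))
}

# brute-force all-pairs inter-residue atom distance scan
brute_contacts <- function(model, chainA, resA, chainB, resB, cutoff) {
  ra <- res_atoms_of(model, chainA, resA)
  rb <- res_atoms_of(model, chainB, resB)
  out <- list()
  for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb))) {
    d <- sqrt(sum((as.numeric(ra[i, c("x", "y", "z")]) -
                     as.numeric(rb[j, c("x", "y", "z")]))^2))
    if (d <= cutoff)
      out[[length(out) + 1L]] <- data.frame(a = ra$name[i], b = rb$name[j],
                                            d = d)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(a = character(), b = character(), d = numeric())
}

# the five-exemplar taxonomy suite
taxonomy_specs <- function() {
  list(WC = pair_spec(geometry = "WC"),
       aWC = pair_spec(geometry = "aWC"),
       cWH = pair_spec(pyr = "5CM", geometry = "cWH"),
       `(w)cWH` = pair_spec(pyr = "5CM", geometry = "(w)cWH"),
       nonWC = pair_spec(geometry = "nonWC"))
}

# the altloc plan emulating a polymorphic methylated duplex
polymorphic_duplex <- function(occ_major = 0.9, occ_minor = 0.1,
                               major = "aWC", seed = 1L, noise_sd = 0) {
  duplex_spec(seq1 = c("A", "C", "G", "mC", "C", "G", "T"),
              altlocs = list(
                list(label = "A", occupancy = occ_major,
                     spec = pair_spec(pyr = "5CM", geometry = major)),
                list(label = "B", occupancy = occ_minor,
                     spec = pair_spec(pyr = "5CM", geometry = "(w)cWH"))),
              seed = seed, noise_sd = noise_sd)
}

first_model <- function(s) expand_conformers(s)[[1]]
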