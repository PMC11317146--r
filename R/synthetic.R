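# Idealized nucleic-acid fixture generator: single base pairs with
# controllable rigid-body parameters and glycosidic states, B-form-like
# duplexes with altloc/occupancy plans, bridging waters, placeholder
# planar-ring ligands, and seeded Gaussian noise.

.code_to_resname <- c(A = "DA", C = "DC", G = "DG", T = "DT", U = "DU",
                      I = "DI", mC = "5CM", MC = "5CM")

.resname_of <- function(code) {
  out <- .code_to_resname[code]
  if (any(is.na(out))) {
    # accept residue names directly
    out[is.na(out)] <- code[is.na(out)]
  }
  unname(out)
}

#' Specify a single base pair for the synthetic builder
#'
#' @param pyr,pur residue names (or one-letter codes) of the pyrimidine
#'   and purine; `5CM` is 5-methylcytosine, `DI` inosine.
#' @param geometry target geometry class: `"WC"`, `"aWC"`, `"cWH"`,
#'   `"(w)cWH"` or `"nonWC"`.
#' @param shear,stretch,stagger,buckle,propeller,opening rigid-body pair
#'   parameters (Angstrom / degrees) for the WC-family geometries.  The
#'   `aWC` default applies a shear of -1.2 Angstrom (pyrimidine toward
#'   the helix interior) when no displacement is requested.
#' @param chi_pyr,chi_pur target glycosidic torsions (degrees); the purine
#'   defaults to -117 (anti) or +55 (syn) as the geometry requires.
#' @param water for `(w)cWH`: list with `atoms` (pyrimidine atom, purine
#'   atom, default `c("O2","N7")`) and `distances` (water-to-atom, default
#'   `c(2.8, 2.9)` Angstrom).
#' @param hg_distances target heavy-atom distances for the Hoogsteen-edge
#'   construction: N4...O6 direct bond, N3...O6 bifurcated bond, O2...N7
#'   separation.
#' @return object of class `pair_spec`.
#' @export
pair_spec <- function(pyr = "DC", pur = NULL,
                      geometry = c("WC", "aWC", "cWH", "(w)cWH", "nonWC"),
                      shear = 0, stretch = 0, stagger = 0,
                      buckle = 0, propeller = 0, opening = 0,
                      chi_pyr = -117, chi_pur = NULL, water = NULL,
                      hg_distances = c(2.9, 3.2, 4.6)) {
  geometry <- match.arg(geometry)
  pyr <- .resname_of(pyr)
  if (is.null(pur)) pur <- if (geometry == "nonWC") "DI" else "DG"
  pur <- .resname_of(pur)
  if (!.is_purine_res(pur) || .is_purine_res(pyr))
    stop("pair_spec requires a pyrimidine `pyr` and a purine `pur`")
  hoogsteen <- geometry %in% c("cWH", "(w)cWH")
  if (is.null(chi_pur)) chi_pur <- if (hoogsteen) 55 else -117
  if (hoogsteen && !(chi_pur > -90 && chi_pur <= 90))
    stop("geometry ", geometry, " requires a syn purine (chi in (-90, 90])")
  # default aWC exemplar: the pyrimidine sheared toward the helix
  # interior (negative along the mid-frame x axis), the displacement
  # direction seen for methylated cytosines
  if (geometry == "aWC" && shear == 0 && buckle == 0 && propeller == 0)
    shear <- -1.2
  if (geometry == "(w)cWH" && is.null(water))
    water <- list(atoms = c("O2", "N7"), distances = c(2.8, 2.9))
  if (geometry == "cWH") hg_distances[3] <- 2.9  # direct O2...N7 bond
  structure(list(pyr = pyr, pur = pur, geometry = geometry,
                 params = list(shear = shear, stretch = stretch,
                               stagger = stagger, buckle = buckle,
                               propeller = propeller, opening = opening),
                 chi_pyr = chi_pyr, chi_pur = chi_pur, water = water,
                 hg_distances = hg_distances),
            class = "pair_spec")
}

# --- residue construction -------------------------------------------------

# build base + sugar + backbone atoms of one nucleotide whose base frame is
# (T, o) and glycosidic torsion is chi; returns a data frame of atom rows.
.build_residue <- function(resname, T, o, chi, chain, resnum, bfactor = 20) {
  std <- .std_base_for(resname)
  place <- function(v) as.numeric(T %*% v + o)
  xyz <- t(apply(std, 1, place))
  nm <- rownames(std)
  gly <- .glyco_n(resname)
  cref <- .chi_atoms(resname)[4]
  A <- xyz[cref, ]; N <- xyz[gly, ]; C1 <- xyz["C1'", ]
  pa <- function(a, b, c, d, ang, tor) .place_atom(a, b, c, d, ang, tor)
  O4 <- pa(A, N, C1, 1.413, 108.2, chi)
  C2p <- pa(A, N, C1, 1.528, 113.7, chi - 122)
  C3p <- pa(N, C1, C2p, 1.525, 102.7, 157)
  C4p <- pa(C1, C2p, C3p, 1.526, 102.6, -35)
  O3p <- pa(C1, C2p, C3p, 1.423, 110.6, -155)
  C5p <- pa(C2p, C3p, C4p, 1.510, 114.7, 160)
  O5p <- pa(C3p, C4p, C5p, 1.440, 110.2, 54)
  P <- pa(C4p, C5p, O5p, 1.593, 120.9, 180)
  OP1 <- pa(C5p, O5p, P, 1.485, 107.7, 60)
  OP2 <- pa(C5p, O5p, P, 1.485, 107.7, -60)
  extra <- rbind(`O4'` = O4, `C2'` = C2p, `C3'` = C3p, `C4'` = C4p,
                 `O3'` = O3p, `C5'` = C5p, `O5'` = O5p,
                 P = P, OP1 = OP1, OP2 = OP2)
  allxyz <- rbind(xyz, extra)
  data.frame(serial = NA_integer_, name = rownames(allxyz), altloc = "",
             resname = resname, chain = chain, resnum = resnum, icode = "",
             x = allxyz[, 1], y = allxyz[, 2], z = allxyz[, 3],
             occupancy = 1, bfactor = bfactor,
             element = .guess_element(rownames(allxyz)),
             stringsAsFactors = FALSE)
}

.water_row <- function(xyz, chain, resnum, occupancy = 1, bfactor = 30) {
  data.frame(serial = NA_integer_, name = "O", altloc = "",
             resname = "HOH", chain = chain, resnum = resnum, icode = "",
             x = xyz[1], y = xyz[2], z = xyz[3],
             occupancy = occupancy, bfactor = bfactor, element = "O",
             stringsAsFactors = FALSE)
}

# place the purine of a Hoogsteen-family pair: proper in-plane rotation
# (base normal parallel to the pyrimidine's) positioned so that the
# target heavy-atom distances N4...O6, N3...O6 and O2...N7 are met.
.solve_hoogsteen_purine <- function(pyr_std, pur_std, d_targets) {
  tgt_from <- pyr_std[c("N4", "N3", "O2"), 1:2, drop = FALSE]
  obj <- function(par) {
    th <- par[1]; tx <- par[2]; ty <- par[3]
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    pur2 <- sweep(pur_std[, 1:2, drop = FALSE] %*% t(R), 2, -c(tx, ty))
    rownames(pur2) <- rownames(pur_std)
    d1 <- .norm3(c(tgt_from["N4", ] - pur2["O6", ], 0))
    d2 <- .norm3(c(tgt_from["N3", ] - pur2["O6", ], 0))
    d3 <- .norm3(c(tgt_from["O2", ] - pur2["N7", ], 0))
    (d1 - d_targets[1])^2 + (d2 - d_targets[2])^2 + (d3 - d_targets[3])^2
  }
  # several optimizer starts converge to distance-feasible but physically
  # overlapping placements; keep the clash-free one (all inter-base
  # heavy-atom separations >= 2.5 A)
  best <- NULL
  for (th0 in seq(0, 2 * pi, length.out = 9)[-9]) {
    fit <- stats::optim(c(th0, 0, -6), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (fit$value > 1e-8) next
    th <- fit$par[1]
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    p2 <- sweep(pur_std[, 1:2, drop = FALSE] %*% t(R), 2, -fit$par[2:3])
    sep <- sqrt(outer(rowSums(pyr_std[, 1:2]^2), rowSums(p2^2), "+") -
                  2 * pyr_std[, 1:2] %*% t(p2))
    if (min(sep) < 2.5) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("Hoogsteen placement infeasible for target distances ",
         paste(sprintf("%.2f", d_targets), collapse = "/"))
  th <- best$par[1]
  T2 <- .rot_axis(c(0, 0, 1), .deg(th))
  list(T = T2, o = c(best$par[2], best$par[3], 0))
}

# intersection of two circles in the z = 0 plane; picks the solution
# farther from `away` (a 3-vector).
.solve_water_position <- function(p1, r1, p2, r2, away) {
  d <- .norm3(p1 - p2)
  if (d > r1 + r2)
    stop(sprintf(paste0("water placement infeasible: |%.2f - %.2f| ",
                        "triangle violated (separation %.2f > %.2f + %.2f)"),
                 r1, r2, d, r1, r2))
  if (d < abs(r1 - r2))
    stop(sprintf(paste0("water placement infeasible: separation %.2f < ",
                        "|%.2f - %.2f|"), d, r1, r2))
  a <- (r1^2 - r2^2 + d^2) / (2 * d)
  h2 <- r1^2 - a^2
  h <- sqrt(max(0, h2))
  u <- .unit(p2 - p1)
  mid <- p1 + a * u
  perp <- .unit(.cross(c(0, 0, 1), u))
  cands <- list(mid + h * perp, mid - h * perp)
  dists <- vapply(cands, function(p) .norm3(p - away), numeric(1))
  cands[[which.max(dists)]]
}

#' Build a single base pair from a specification
#'
#' Places standard bases so that [pair_parameters()] on the result
#' reproduces the requested rigid-body parameters (WC-family geometries),
#' or solves the Hoogsteen-edge placement (syn purine) for the `cWH` /
#' `(w)cWH` geometries, including the bridging water for `(w)cWH`.
#' Sugar and backbone atoms are included so the glycosidic torsion is
#' defined and connectivity-based analyses work.
#'
#' @param spec a [pair_spec()].
#' @return a `conformer_model` with two nucleotides (chain A residue 1 =
#'   pyrimidine, chain B residue 2 = purine) and any requested water.
#' @export
build_pair <- function(spec) {
  stopifnot(inherits(spec, "pair_spec"))
  parts <- .build_pair_atoms(spec, chain1 = "A", resnum1 = 1,
                             chain2 = "B", resnum2 = 2, water_resnum = 101)
  atoms <- parts$atoms
  atoms$serial <- seq_len(nrow(atoms))
  .new_conformer(.new_structure(atoms, entry = "SYNTH")$atoms,
                 entry = "SYNTH", label = "", occupancy = 1)
}

# core pair construction in the local (mid-frame) coordinate system
.build_pair_atoms <- function(spec, chain1, resnum1, chain2, resnum2,
                              water_resnum = 101) {
  pyr_std <- .std_base_for(spec$pyr)
  pur_std <- .std_base_for(spec$pur)
  if (spec$geometry %in% c("WC", "aWC", "nonWC")) {
    fr <- do.call(.frames_from_params, spec$params)
    r1 <- .build_residue(spec$pyr, fr$T1, fr$o1, spec$chi_pyr,
                         chain1, resnum1)
    r2 <- .build_residue(spec$pur, fr$T2, fr$o2, spec$chi_pur,
                         chain2, resnum2)
    wat <- NULL
  } else {
    sol <- .solve_hoogsteen_purine(pyr_std, pur_std, spec$hg_distances)
    r1 <- .build_residue(spec$pyr, diag(3), c(0, 0, 0), spec$chi_pyr,
                         chain1, resnum1)
    r2 <- .build_residue(spec$pur, sol$T, sol$o, spec$chi_pur,
                         chain2, resnum2)
    wat <- NULL
    if (!is.null(spec$water)) {
      p1 <- as.numeric(r1[match(spec$water$atoms[1], r1$name),
                          c("x", "y", "z")])
      p2 <- as.numeric(r2[match(spec$water$atoms[2], r2$name),
                          c("x", "y", "z")])
      ring1 <- .ring_centroid(r1, .six_ring_atoms(spec$pyr))
      wpos <- .solve_water_position(p1, spec$water$distances[1],
                                    p2, spec$water$distances[2],
                                    away = ring1)
      wat <- .water_row(wpos, chain = "S", resnum = water_resnum)
    }
  }
  list(atoms = rbind(r1, r2, wat), residues = list(r1 = r1, r2 = r2))
}

#' Specify a synthetic duplex
#'
#' @param seq1 strand-1 sequence 5'->3' as one-letter codes (`"mC"` for
#'   5-methylcytosine, `"I"` for inosine); default the 7-mer
#'   `A C G C C G T`.
#' @param seq2 strand-2 sequence 5'->3'; default the WC complement of
#'   `seq1` (pairing residue i of strand 1 with residue n-i+1 of strand
#'   2).
#' @param rise,twist per-step helical rise (Angstrom) and twist (degrees).
#' @param central a [pair_spec()] overriding the central pair, or `NULL`.
#' @param altlocs alternate-conformer plan for the central pair: list of
#'   `list(label=, occupancy=, spec=)`; occupancies must sum to 1.
#' @param noise_sd isotropic Gaussian coordinate noise, Angstrom.
#' @param seed integer seed for the noise generator.
#' @param ligands optional integer vector of steps after which to insert a
#'   placeholder planar ring ligand (generic intercalator stand-in).
#' @return object of class `duplex_spec`.
#' @export
duplex_spec <- function(seq1 = c("A", "C", "G", "C", "C", "G", "T"),
                        seq2 = NULL, rise = 3.4, twist = 36,
                        central = NULL, altlocs = NULL,
                        noise_sd = 0, seed = 1L, ligands = NULL) {
  comp <- c(A = "T", T = "A", G = "C", C = "G", mC = "G", I = "C",
            U = "A")
  if (is.null(seq2)) seq2 <- rev(unname(comp[seq1]))
  if (length(seq1) != length(seq2))
    stop("strands must have equal length")
  if (!is.null(altlocs)) {
    occ <- vapply(altlocs, `[[`, numeric(1), "occupancy")
    if (abs(sum(occ) - 1) > 1e-6)
      stop("altloc occupancies must sum to 1 (got ", sum(occ), ")")
    labs <- vapply(altlocs, `[[`, character(1), "label")
    if (anyDuplicated(labs)) stop("clashing altloc labels: ",
                                  paste(labs[duplicated(labs)], collapse = ","))
  }
  structure(list(seq1 = seq1, seq2 = seq2, rise = rise, twist = twist,
                 central = central, altlocs = altlocs,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 ligands = ligands),
            class = "duplex_spec")
}

#' Build an idealized B-form duplex structure
#'
#' Stacks Watson-Crick pairs of standard bases with the stated rise and
#' twist; the central pair can be overridden by a [pair_spec()] or an
#' alternate-location plan with stated occupancies (each conformer's base
#' pair, bridging water and the 3'-linking phosphates carry the altloc
#' label).  A minimal backbone (P, OP1, OP2, O5', C5', C4', C3', O3',
#' C2', C1', O4') is included and phosphates are positioned so O3'->P
#' connectivity holds along each strand.  Optional placeholder planar-ring
#' ligands can be stacked between steps.  Gaussian coordinate noise is
#' applied with the stated seed.
#'
#' @param spec a [duplex_spec()].
#' @return a `nastructure`.
#' @export
build_duplex <- function(spec) {
  stopifnot(inherits(spec, "duplex_spec"))
  n <- length(spec$seq1)
  centre <- ceiling(n / 2)
  rows <- list()
  water_seq <- 101L
  step_of <- function(k) {
    G <- .rot_axis(c(0, 0, 1), (k - 1) * spec$twist)
    t <- c(0, 0, (k - 1) * spec$rise)
    list(G = G, t = t)
  }
  apply_step <- function(df, st) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(st$G)
    df$x <- xyz[, 1] + st$t[1]; df$y <- xyz[, 2] + st$t[2]
    df$z <- xyz[, 3] + st$t[3]
    df
  }
  pair_at <- function(k, pspec, altloc = "", occupancy = 1) {
    code1 <- spec$seq1[k]; code2 <- spec$seq2[n - k + 1]
    rn1 <- .resname_of(code1); rn2 <- .resname_of(code2)
    if (is.null(pspec)) {
      pyr_first <- !.is_purine_res(rn1)
      pspec <- pair_spec(pyr = if (pyr_first) rn1 else rn2,
                         pur = if (pyr_first) rn2 else rn1,
                         geometry = "WC")
    } else {
      pyr_first <- identical(pspec$pyr, rn1)
      if (!pyr_first && !identical(pspec$pur, rn1))
        stop("central pair_spec does not match the sequence at step ", k)
    }
    # the pair is constructed pyrimidine-first; when strand 1 holds the
    # purine, rotate the whole pair by pi about x (the same physical
    # pair with strand roles exchanged) so strand 1's backbone stays on
    # one face of the helix
    if (pyr_first) {
      parts <- .build_pair_atoms(pspec, chain1 = "A", resnum1 = k,
                                 chain2 = "B", resnum2 = 2 * n - k + 1,
                                 water_resnum = water_seq)
      df <- parts$atoms
    } else {
      parts <- .build_pair_atoms(pspec, chain1 = "B",
                                 resnum1 = 2 * n - k + 1,
                                 chain2 = "A", resnum2 = k,
                                 water_resnum = water_seq)
      df <- parts$atoms
      df$y <- -df$y
      df$z <- -df$z
    }
    df <- apply_step(df, step_of(k))
    if (any(df$resname == "HOH")) water_seq <<- water_seq + 1L
    df$altloc <- altloc
    df$occupancy <- occupancy
    df
  }
  for (k in seq_len(n)) {
    if (k == centre && !is.null(spec$altlocs)) {
      for (al in spec$altlocs)
        rows[[length(rows) + 1L]] <- pair_at(k, al$spec, al$label,
                                             al$occupancy)
    } else if (k == centre && !is.null(spec$central)) {
      rows[[length(rows) + 1L]] <- pair_at(k, spec$central)
    } else {
      rows[[length(rows) + 1L]] <- pair_at(k, NULL)
    }
  }
  atoms <- do.call(rbind, rows)
  if (!is.null(spec$ligands)) {
    for (s in spec$ligands)
      atoms <- rbind(atoms, .ligand_ring(step_of(s), spec$rise,
                                         resnum = 900 + s))
  }
  atoms <- .fix_phosphates(atoms, n)
  if (spec$noise_sd > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(spec$seed)
    m <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(m, 0, spec$noise_sd)
    atoms$y <- atoms$y + stats::rnorm(m, 0, spec$noise_sd)
    atoms$z <- atoms$z + stats::rnorm(m, 0, spec$noise_sd)
  }
  atoms$serial <- seq_len(nrow(atoms))
  .new_structure(atoms, entry = "SYNTH")
}

# placeholder planar six-ring ligand (two ring nitrogens) stacked halfway
# between step s and s+1
.ligand_ring <- function(st, rise, resnum) {
  ang <- seq(0, 300, by = 60) * pi / 180
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  nm <- c("N1", "C2", "C3", "N4", "C5", "C6")
  xyz <- ring %*% t(st$G)
  xyz <- sweep(xyz, 2, st$t + c(0, 0, rise / 2), "+")
  data.frame(serial = NA_integer_, name = nm, altloc = "",
             resname = "LIG", chain = "L", resnum = resnum, icode = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, bfactor = 25,
             element = substr(nm, 1, 1), stringsAsFactors = FALSE)
}

# reposition phosphates so that O3'(i) -> P(i+1) is a 1.59 A link along
# each strand; remove the 5'-terminal phosphate group.  When the preceding
# residue exists only in alternate conformations, the linking phosphate
# group is split into one altloc copy per conformer (as deposited
# structures do), so connectivity holds in every single-conformer model.
.fix_phosphates <- function(atoms, n) {
  strands <- list(list(chain = "A", ord = seq_len(n)),
                  list(chain = "B", ord = seq(n + 1, 2 * n)))
  drop <- rep(FALSE, nrow(atoms))
  extra <- list()
  place_group <- function(rows, o3x, o5x) {
    newp <- o3x + 1.59 * .unit(o5x - o3x)
    rows[rows$name == "P", c("x", "y", "z")] <- as.list(newp)
    for (opn in c("OP1", "OP2")) {
      i <- which(rows$name == opn)
      if (length(i) == 1) {
        tor <- if (opn == "OP1") 100 else -100
        rows[i, c("x", "y", "z")] <- as.list(
          .place_atom(o5x, o3x, newp, 1.485, 110, tor))
      }
    }
    rows
  }
  for (s in strands) {
    first <- TRUE
    prev_by_alt <- list()
    for (rn in s$ord) {
      sel <- which(atoms$chain == s$chain & atoms$resnum == rn)
      if (!length(sel)) next
      alts <- unique(atoms$altloc[sel])
      if (first) {
        drop[sel[atoms$name[sel] %in% c("P", "OP1", "OP2")]] <- TRUE
      } else {
        for (al in alts) {
          rsel <- sel[atoms$altloc[sel] == al]
          pg <- rsel[atoms$name[rsel] %in% c("P", "OP1", "OP2")]
          o5i <- rsel[atoms$name[rsel] == "O5'"]
          if (!length(pg) || length(o5i) != 1) next
          o5x <- as.numeric(atoms[o5i, c("x", "y", "z")])
          prev <- prev_by_alt[[paste0("alt:", al)]]
          if (is.null(prev)) prev <- prev_by_alt[["alt:"]]
          if (!is.null(prev)) {
            atoms[pg, ] <- place_group(atoms[pg, , drop = FALSE],
                                       as.numeric(prev$xyz), o5x)
          } else if (al == "" && length(prev_by_alt)) {
            # predecessor exists only as alternate conformers: split this
            # residue's phosphate group per conformer
            drop[pg] <- TRUE
            for (k in names(prev_by_alt)) {
              pv <- prev_by_alt[[k]]
              rows <- place_group(atoms[pg, , drop = FALSE],
                                  as.numeric(pv$xyz), o5x)
              rows$altloc <- sub("^alt:", "", k)
              rows$occupancy <- pv$occ
              extra[[length(extra) + 1L]] <- rows
            }
          }
        }
      }
      new_prev <- list()
      for (al in alts) {
        rsel <- sel[atoms$altloc[sel] == al]
        o3i <- rsel[atoms$name[rsel] == "O3'"]
        if (length(o3i) == 1)
          new_prev[[paste0("alt:", al)]] <-
            list(xyz = atoms[o3i, c("x", "y", "z")],
                 occ = atoms$occupancy[o3i])
      }
      if (length(new_prev)) prev_by_alt <- new_prev
      first <- FALSE
    }
  }
  out <- atoms[!drop, , drop = FALSE]
  if (length(extra)) out <- do.call(rbind, c(list(out), extra))
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv()))
    rm(".Random.seed", envir = globalenv())
}

#' Apply seeded Gaussian coordinate noise to a model
#'
#' i.i.d. Gaussian displacement per atom and axis; `sd = 0` is the
#' identity; results are reproducible by seed and the caller's RNG state
#' is left untouched.
#'
#' @param model a `conformer_model` or `nastructure`.
#' @param sd noise standard deviation per coordinate, Angstrom.
#' @param seed integer seed.
#' @return the model with perturbed coordinates.
#' @export
perturb <- function(model, sd, seed = 1L) {
  stopifnot(sd >= 0)
  if (sd == 0) return(model)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  atoms <- .model_atoms(model)
  m <- nrow(atoms)
  atoms$x <- atoms$x + stats::rnorm(m, 0, sd)
  atoms$y <- atoms$y + stats::rnorm(m, 0, sd)
  atoms$z <- atoms$z + stats::rnorm(m, 0, sd)
  if (inherits(model, "nastructure")) model$atoms <- atoms
  else model$atoms <- atoms
  model
}

#' Apply a rigid motion to a model (rotation then translation)
#'
#' Utility for invariance testing and fixture construction.
#'
#' @param model `conformer_model` or `nastructure`.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation.
#' @return transformed model.
#' @export
rigid_transform <- function(model, R = diag(3), t = c(0, 0, 0)) {
  atoms <- .model_atoms(model)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + t[1]; atoms$y <- xyz[, 2] + t[2]
  atoms$z <- xyz[, 3] + t[3]
  model$atoms <- atoms
  model
}

#' Assemble a structure from an atom table
#'
#' Low-level constructor for fixtures: takes a data frame with columns
#' serial, name, altloc, resname, chain, resnum, icode, x, y, z,
#' occupancy, bfactor, element and returns a `nastructure` (categories
#' assigned from residue names).
#'
#' @param atoms atom data frame.
#' @param entry entry identifier.
#' @return `nastructure`.
#' @export
as_structure <- function(atoms, entry = "USER") {
  defaults <- list(serial = NA_integer_, altloc = "", icode = "",
                   occupancy = 1, bfactor = 0)
  for (nm in names(defaults))
    if (is.null(atoms[[nm]]))
      atoms[[nm]] <- rep(defaults[[nm]], nrow(atoms))
  if (is.null(atoms$element))
    atoms$element <- .guess_element(as.character(atoms$name))
  if (any(is.na(atoms$serial))) atoms$serial <- seq_len(nrow(atoms))
  .new_structure(atoms[, .atom_cols], entry = entry)
}
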