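# Base-pair detection, geometry-class assignment (WC / aWC / cWH / (w)cWH /
# non-canonical WC / other), duplex building from backbone connectivity,
# and occupancy-aware enumeration across alternate-location conformers.

.default_thresholds <- function() {
  list(hbond_cutoff = 3.5, bridge_cutoff = 3.5, ion_cutoff = 2.8,
       asym_lambda = 8, asym_shear = 0.8,
       c1c1_min = 8, c1c1_max = 12.5, plane_angle_max = 65)
}

# base (non-backbone) heavy atoms of a nucleotide residue
.base_atom_names <- function(resname) {
  std <- .std_base_for(resname)
  if (is.null(std)) return(character())
  setdiff(rownames(std), "C1'")
}

# hbonds between base atoms of residues i and j, as (atom_i, atom_j) pairs
.bonds_between <- function(hbonds, id_i, id_j, base_i, base_j) {
  if (!nrow(hbonds)) return(hbonds[0, ])
  fwd <- hbonds$donor_res == id_i & hbonds$acceptor_res == id_j &
    hbonds$donor_atom %in% base_i & hbonds$acceptor_atom %in% base_j
  rev <- hbonds$donor_res == id_j & hbonds$acceptor_res == id_i &
    hbonds$donor_atom %in% base_j & hbonds$acceptor_atom %in% base_i
  out <- hbonds[fwd | rev, , drop = FALSE]
  if (!nrow(out)) return(out)
  swap <- out$donor_res == id_j
  out$atom_i <- ifelse(swap, out$acceptor_atom, out$donor_atom)
  out$atom_j <- ifelse(swap, out$donor_atom, out$acceptor_atom)
  out
}

.bridges_between <- function(bridges, id_i, id_j, base_i, base_j) {
  if (!nrow(bridges)) return(bridges[0, ])
  fwd <- bridges$res1 == id_i & bridges$res2 == id_j &
    bridges$atom1 %in% base_i & bridges$atom2 %in% base_j
  rev <- bridges$res1 == id_j & bridges$res2 == id_i &
    bridges$atom1 %in% base_j & bridges$atom2 %in% base_i
  out <- bridges[fwd | rev, , drop = FALSE]
  if (!nrow(out)) return(out)
  swap <- out$res1 == id_j
  out$atom_i <- ifelse(swap, out$atom2, out$atom1)
  out$atom_j <- ifelse(swap, out$atom1, out$atom2)
  out
}

# cis/trans from glycosidic-bond vectors projected on the mean pair plane:
# cis when both C1' atoms lie on the same side of the line through the two
# glycosidic nitrogens.
.pair_orientation <- function(res_i, res_j, normal) {
  ni <- .atom_xyz(res_i, .glyco_n(res_i$resname[1]))
  nj <- .atom_xyz(res_j, .glyco_n(res_j$resname[1]))
  ci <- .atom_xyz(res_i, "C1'"); cj <- .atom_xyz(res_j, "C1'")
  if (is.null(ni) || is.null(nj) || is.null(ci) || is.null(cj))
    return(NA_character_)
  axis <- nj - ni
  si <- sum(.cross(axis, ci - ni) * normal)
  sj <- sum(.cross(axis, cj - nj) * normal)
  if (si * sj > 0) "cis" else "trans"
}

#' Detect base pairs in a conformer model
#'
#' Candidate residue pairs must share at least one inter-base hydrogen
#' bond or qualifying water bridge between base atoms, have a C1'-C1'
#' distance within `[c1c1_min, c1c1_max]` and base-plane normals within
#' `plane_angle_max` degrees.  A residue joins at most one pair: matching
#' is greedy by hydrogen-bond count, ties broken by shorter C1'-C1'.
#' Pairs are listed pyrimidine-first when the pair has one of each.
#'
#' @param model a `conformer_model`.
#' @param thresholds list of cutoffs (see `bpgeom:::.default_thresholds`).
#' @return list of `base_pair` objects carrying residue refs, evidence
#'   (H-bonds, bridges), pair parameters, glycosidic states, orientation
#'   and classification label.
#' @export
detect_base_pairs <- function(model, thresholds = .default_thresholds()) {
  th <- utils::modifyList(.default_thresholds(), thresholds)
  atoms <- .model_atoms(model)
  res <- .residues(model)
  nuc <- res[res$category == "nucleotide", , drop = FALSE]
  if (nrow(nuc) < 2) return(list())
  hb <- find_hbonds(model, cutoff = th$hbond_cutoff)
  br <- find_water_bridges(model, cutoff = th$bridge_cutoff)

  ratoms <- lapply(nuc$id, function(id) .res_atoms(model, id))
  names(ratoms) <- nuc$id
  frames <- lapply(ratoms, function(ra)
    tryCatch(base_frame(ra), error = function(e) NULL))
  c1 <- lapply(ratoms, function(ra) .atom_xyz(ra, "C1'"))
  basenames <- lapply(nuc$resname, .base_atom_names)
  names(basenames) <- nuc$id

  cand <- list()
  n <- nrow(nuc)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    ida <- nuc$id[a]; idb <- nuc$id[b]
    if (is.null(frames[[ida]]) || is.null(frames[[idb]])) next
    if (is.null(c1[[ida]]) || is.null(c1[[idb]])) next
    d <- .norm3(c1[[ida]] - c1[[idb]])
    if (d < th$c1c1_min || d > th$c1c1_max) next
    za <- frames[[ida]]$axes[, 3]; zb <- frames[[idb]]$axes[, 3]
    pang <- .deg(acos(.clamp1(abs(sum(za * zb)))))
    if (pang > th$plane_angle_max) next
    bonds <- .bonds_between(hb, ida, idb, basenames[[ida]], basenames[[idb]])
    brs <- .bridges_between(br, ida, idb, basenames[[ida]], basenames[[idb]])
    if (!nrow(bonds) && !nrow(brs)) next
    cand[[length(cand) + 1L]] <- list(a = a, b = b, nb = nrow(bonds), d = d)
  }
  if (!length(cand)) return(list())
  ord <- order(-vapply(cand, `[[`, numeric(1), "nb"),
               vapply(cand, `[[`, numeric(1), "d"))
  used <- logical(n)
  pairs <- list()
  for (k in ord) {
    a <- cand[[k]]$a; b <- cand[[k]]$b
    if (used[a] || used[b]) next
    used[a] <- used[b] <- TRUE
    # pyrimidine-first ordering
    pur_a <- .is_purine_res(nuc$resname[a])
    pur_b <- .is_purine_res(nuc$resname[b])
    if (pur_a && !pur_b) { tmp <- a; a <- b; b <- tmp }
    pairs[[length(pairs) + 1L]] <-
      .make_base_pair(model, nuc$id[a], nuc$id[b], ratoms, hb, br,
                      conformer = model$label, occupancy = model$occupancy)
  }
  pairs
}

.make_base_pair <- function(model, id_i, id_j, ratoms, hb, br,
                            conformer = "", occupancy = 1) {
  ri <- ratoms[[id_i]]; rj <- ratoms[[id_j]]
  base_i <- .base_atom_names(ri$resname[1])
  base_j <- .base_atom_names(rj$resname[1])
  bonds <- .bonds_between(hb, id_i, id_j, base_i, base_j)
  brs <- .bridges_between(br, id_i, id_j, base_i, base_j)
  params <- tryCatch(pair_parameters(ri, rj), error = function(e) NULL)
  chi_i <- glycosidic_chi(ri); chi_j <- glycosidic_chi(rj)
  # the first base's own normal: well-conditioned for every geometry,
  # including Hoogsteen pairs where the mid-frame hinge degenerates
  normal <- if (!is.null(params)) params$frameA$axes[, 3] else c(0, 0, 1)
  bp <- structure(list(
    res_i = id_i, res_j = id_j,
    resname_i = ri$resname[1], resname_j = rj$resname[1],
    conformer = conformer, occupancy = occupancy,
    hbonds = bonds, bridges = brs, params = params,
    chi_i = chi_i, chi_j = chi_j,
    orientation = .pair_orientation(ri, rj, normal)),
    class = "base_pair")
  bp$label <- classify_geometry(bp)
  bp
}

# canonical Watson-Crick bond sets (atom_i on the pyrimidine, atom_j on
# the purine), per base-type combination; NULL when no canonical WC set
# exists for the combination (e.g. C:I, where inosine lacks N2).
.canonical_set <- function(code_pyr, code_pur) {
  if (code_pyr %in% c("C", "MC") && code_pur == "G")
    return(list(set = c("N4-O6", "N3-N1", "O2-N2"),
                required = "N3-N1", min_n = 2))
  if (code_pyr %in% c("T", "U") && code_pur == "A")
    return(list(set = c("N3-N1", "O4-N6"), required = "N3-N1", min_n = 2))
  NULL
}

#' Classify a base pair into the geometry taxonomy
#'
#' Decision rules applied in order:
#' 1. `WC`: both glycosidic torsions anti, the canonical Watson-Crick bond
#'    set present (for C:G at least two of N4-O6 / N3-N1 / O2-N2 including
#'    N3-N1), lambda asymmetry and shear within thresholds.
#' 2. `aWC`: as WC on bonds and anti-anti but `|lambdaY - lambdaR|` above
#'    the asymmetry threshold or `|shear|` above the shear threshold.
#' 3. `cWH` / `(w)cWH`: purine syn, pyrimidine WC edge bonded to the
#'    purine Hoogsteen edge (bonds among N4-O6 / N3-O6 / O2-N7), cis
#'    orientation; `(w)cWH` when the O2...N7 contact is realized as a
#'    water bridge rather than a direct bond.
#' 4. `nonWC`: anti-anti with a WC-edge bond set that is not the
#'    canonical set (e.g. C:I).
#' 5. `other`: anything else.
#'
#' @param bp a `base_pair` with populated evidence fields.
#' @param thresholds list with `asym_lambda` (degrees) and `asym_shear`
#'   (Angstrom).
#' @return character geometry label.
#' @export
classify_geometry <- function(bp, thresholds = .default_thresholds()) {
  th <- utils::modifyList(.default_thresholds(), thresholds)
  if (is.null(bp$params))
    return("unclassified(parameters undefined)")
  if (is.na(bp$chi_i$chi) || is.na(bp$chi_j$chi))
    return("unclassified(chi undefined)")
  ci <- .base_code[[bp$resname_i]]; cj <- .base_code[[bp$resname_j]]
  if (is.null(ci) || is.null(cj))
    return("unclassified(unknown residue type)")
  # orient pyrimidine = i for rule evaluation
  if (ci %in% .purine_codes && cj %in% .pyrimidine_codes)
    return(classify_geometry(.swap_pair(bp), thresholds))
  pyr <- ci; pur <- cj
  bonds <- if (nrow(bp$hbonds)) paste(bp$hbonds$atom_i, bp$hbonds$atom_j,
                                      sep = "-") else character()
  anti_anti <- bp$chi_i$call == "anti" && bp$chi_j$call == "anti"
  lam_asym <- abs(bp$params$lambda_A - bp$params$lambda_B)
  shear_ok <- abs(bp$params$shear) <= th$asym_shear
  lam_ok <- lam_asym <= th$asym_lambda

  canon <- if (pur %in% .purine_codes) .canonical_set(pyr, pur) else NULL
  canonical_ok <- FALSE
  if (!is.null(canon)) {
    present <- intersect(canon$set, bonds)
    canonical_ok <- length(present) >= canon$min_n &&
      canon$required %in% present
  }
  if (anti_anti && canonical_ok && lam_ok && shear_ok) return("WC")
  if (anti_anti && canonical_ok) return("aWC")

  # Hoogsteen branch: purine syn, pyrimidine WC edge vs purine HG edge
  if (pur %in% .purine_codes && bp$chi_j$call == "syn") {
    hg_atoms <- .hoogsteen_edge[[pur]]
    wc_atoms <- .wc_edge[[pyr]]
    hg_bonds <- bonds[vapply(strsplit(bonds, "-"), function(p)
      p[1] %in% wc_atoms && p[2] %in% c(hg_atoms, "O6"), logical(1))]
    bridge_o2n7 <- nrow(bp$bridges) &&
      any(bp$bridges$atom_i %in% wc_atoms & bp$bridges$atom_j == "N7")
    if ((length(hg_bonds) || bridge_o2n7) &&
        identical(bp$orientation, "cis")) {
      direct_o2n7 <- any(grepl("-N7$", hg_bonds))
      if (!direct_o2n7 && bridge_o2n7) return("(w)cWH")
      return("cWH")
    }
  }

  if (anti_anti && pur %in% .purine_codes) {
    wc_bonds <- bonds[vapply(strsplit(bonds, "-"), function(p)
      p[1] %in% .wc_edge[[pyr]] && p[2] %in% .wc_edge[[pur]], logical(1))]
    if (length(wc_bonds)) return("nonWC")
  }
  "other"
}

.swap_pair <- function(bp) {
  sw <- bp
  sw$res_i <- bp$res_j; sw$res_j <- bp$res_i
  sw$resname_i <- bp$resname_j; sw$resname_j <- bp$resname_i
  sw$chi_i <- bp$chi_j; sw$chi_j <- bp$chi_i
  if (nrow(bp$hbonds)) {
    sw$hbonds$atom_i <- bp$hbonds$atom_j
    sw$hbonds$atom_j <- bp$hbonds$atom_i
  }
  if (nrow(bp$bridges)) {
    sw$bridges$atom_i <- bp$bridges$atom_j
    sw$bridges$atom_j <- bp$bridges$atom_i
  }
  sw
}

#' Chain base pairs into antiparallel duplexes
#'
#' Pairs are chained by backbone connectivity (O3' to P links within 2.0
#' Angstrom) into maximal antiparallel runs: consecutive pairs must be
#' backbone-consecutive on both strands with opposite strand directions.
#' Duplexes are ordered and labelled (`D1`, `D2`, ...) by the file order
#' of their first residue.
#'
#' @param pairs list of `base_pair` from [detect_base_pairs()].
#' @param model the `conformer_model` the pairs came from.
#' @return list of `duplex` objects (`label`, `pairs`, `strand1`,
#'   `strand2` residue id vectors).
#' @export
build_duplexes <- function(pairs, model) {
  if (!length(pairs)) return(list())
  atoms <- .model_atoms(model)
  rid <- .res_id(atoms)
  res <- .residues(model)
  # successor map: residue whose P lies within 2.0 A of this residue's O3'
  o3 <- atoms[atoms$name == "O3'", , drop = FALSE]
  pp <- atoms[atoms$name == "P", , drop = FALSE]
  succ <- character(0)
  if (nrow(o3) && nrow(pp)) {
    pmat <- as.matrix(pp[, c("x", "y", "z")])
    for (k in seq_len(nrow(o3))) {
      d <- sqrt(rowSums(sweep(pmat, 2,
                              as.numeric(o3[k, c("x", "y", "z")]))^2))
      hits <- which(d <= 2.0)
      from <- .res_id(o3[k, , drop = FALSE])
      hits <- hits[.res_id(pp[hits, , drop = FALSE]) != from]
      if (length(hits) > 1)
        stop("branching backbone connectivity at residue ", from, " -> ",
             paste(.res_id(pp[hits, , drop = FALSE]), collapse = ", "))
      if (length(hits) == 1)
        succ[from] <- .res_id(pp[hits, , drop = FALSE])
    }
  }
  nxt <- function(id) if (!is.na(succ[id]) && !is.null(succ[id]))
    unname(succ[id]) else NA_character_

  keyed <- setNames(pairs, vapply(pairs, function(p)
    paste(p$res_i, p$res_j, sep = "~"), character(1)))
  bykey <- function(i, j) {
    k1 <- paste(i, j, sep = "~"); k2 <- paste(j, i, sep = "~")
    if (k1 %in% names(keyed)) keyed[[k1]]
    else if (k2 %in% names(keyed)) keyed[[k2]] else NULL
  }
  # successor of pair (i,j) along the duplex is the pair on residues
  # (succ(i), pred(j)) — antiparallel strands advance in opposite
  # directions.  Adjacency is computed on unordered residue sets because
  # pyrimidine-first listing may swap strand roles between pairs.
  pred <- if (length(succ)) setNames(names(succ), unname(succ))
          else character(0)
  prv <- function(id) if (!is.na(pred[id]) && !is.null(pred[id]))
    unname(pred[id]) else NA_character_

  pkey <- function(p) paste(p$res_i, p$res_j, sep = "~")
  keys <- vapply(pairs, pkey, character(1))
  nbrs <- lapply(pairs, function(p) {
    out <- character(0)
    for (cand in list(c(nxt(p$res_i), prv(p$res_j)),
                      c(prv(p$res_i), nxt(p$res_j)))) {
      if (anyNA(cand)) next
      q <- bykey(cand[1], cand[2])
      if (!is.null(q)) out <- c(out, pkey(q))
    }
    setdiff(unique(out), pkey(p))
  })
  names(nbrs) <- keys
  order_of <- function(p) min(match(c(p$res_i, p$res_j), res$id))
  file_ord <- vapply(pairs, order_of, numeric(1))
  visited <- character(0)
  duplexes <- list()
  for (start_k in order(file_ord)) {
    key0 <- keys[start_k]
    if (key0 %in% visited) next
    # walk to one end of the component first
    prev <- NA_character_; cur <- key0
    repeat {
      step <- setdiff(nbrs[[cur]], c(prev, key0))
      if (!length(step)) break
      prev <- cur; cur <- step[1]
      if (cur == key0) break  # cycle guard
    }
    head_key <- cur
    run <- list(); prev <- NA_character_; cur <- head_key
    repeat {
      run[[length(run) + 1L]] <- keyed[[cur]]
      visited <- c(visited, cur)
      step <- setdiff(nbrs[[cur]], c(prev, visited))
      if (!length(step)) break
      prev <- cur; cur <- step[1]
    }
    duplexes[[length(duplexes) + 1L]] <- run
  }
  duplexes <- duplexes[order(vapply(duplexes, function(r)
    order_of(r[[1]]), numeric(1)))]
  lapply(seq_along(duplexes), function(k) {
    run <- duplexes[[k]]
    structure(list(label = paste0("D", k), pairs = run,
                   strand1 = vapply(run, `[[`, character(1), "res_i"),
                   strand2 = vapply(run, `[[`, character(1), "res_j")),
              class = "duplex")
  })
}

#' Enumerate classified base pairs across altloc conformers
#'
#' Expands the structure into single-conformer models, runs detection and
#' classification in each, and merges: pairs whose residues carry no
#' alternate-location atoms are identical across conformers and reported
#' once with occupancy 1; pairs differing between conformers are reported
#' per conformer with that conformer's occupancy.
#'
#' @param s a `nastructure`.
#' @param thresholds cutoff list, see [detect_base_pairs()].
#' @return data frame (one row per pair record) with columns entry,
#'   duplex, res_i, res_j, conformer, occupancy, label, c1c1, lambda_Y,
#'   lambda_R, shear, chi_i, call_i, chi_j, call_j, n_hbonds, n_bridges;
#'   full `base_pair` objects in `attr(, "pairs")`.
#' @export
enumerate_pair_conformers <- function(s, thresholds = .default_thresholds()) {
  models <- expand_conformers(s)
  atoms <- .model_atoms(s)
  # a pair is polymorphic when nucleoside atoms of its residues are
  # altloc'd; an alternate linking phosphate group alone does not change
  # the pair
  alt_nucleoside <- atoms$altloc != "" &
    !(atoms$name %in% c("P", "OP1", "OP2"))
  rid_alt <- unique(.res_id(atoms)[alt_nucleoside])
  rows <- list(); objs <- list()
  seen_fixed <- character(0)
  for (m in models) {
    pairs <- detect_base_pairs(m, thresholds)
    dups <- build_duplexes(pairs, m)
    dlab <- character(0)
    for (d in dups) for (p in d$pairs)
      dlab[paste(p$res_i, p$res_j, sep = "~")] <- d$label
    for (p in pairs) {
      key <- paste(p$res_i, p$res_j, sep = "~")
      polymorphic <- p$res_i %in% rid_alt || p$res_j %in% rid_alt
      if (!polymorphic) {
        if (key %in% seen_fixed) next
        seen_fixed <- c(seen_fixed, key)
        p$occupancy <- 1; p$conformer <- ""
      }
      lab <- if (!is.na(dlab[key]) && !is.null(dlab[key])) dlab[key] else ""
      rows[[length(rows) + 1L]] <- .pair_row(s$entry, lab, p)
      objs[[length(objs) + 1L]] <- p
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .pair_row(NULL)
  rownames(out) <- NULL
  attr(out, "pairs") <- objs
  out
}

.pair_row <- function(entry, duplex = NULL, p = NULL) {
  if (is.null(p))
    return(data.frame(entry = character(), duplex = character(),
                      res_i = character(), res_j = character(),
                      resname_i = character(), resname_j = character(),
                      conformer = character(), occupancy = numeric(),
                      label = character(), c1c1 = numeric(),
                      lambda_Y = numeric(), lambda_R = numeric(),
                      shear = numeric(), chi_i = numeric(),
                      call_i = character(), chi_j = numeric(),
                      call_j = character(), n_hbonds = integer(),
                      n_bridges = integer(), stringsAsFactors = FALSE))
  data.frame(entry = entry, duplex = duplex, res_i = p$res_i,
             res_j = p$res_j, resname_i = p$resname_i,
             resname_j = p$resname_j, conformer = p$conformer,
             occupancy = p$occupancy, label = p$label,
             c1c1 = if (!is.null(p$params)) p$params$c1c1 else NA_real_,
             lambda_Y = if (!is.null(p$params)) p$params$lambda_Y else NA_real_,
             lambda_R = if (!is.null(p$params)) p$params$lambda_R else NA_real_,
             shear = if (!is.null(p$params)) p$params$shear else NA_real_,
             chi_i = p$chi_i$chi, call_i = p$chi_i$call,
             chi_j = p$chi_j$chi, call_j = p$chi_j$call,
             n_hbonds = nrow(p$hbonds), n_bridges = nrow(p$bridges),
             stringsAsFactors = FALSE)
}

#' @export
print.base_pair <- function(x, ...) {
  cat(sprintf("<base_pair> %s(%s) : %s(%s)  %s\n", x$resname_i, x$res_i,
              x$resname_j, x$res_j, x$label))
  if (!is.null(x$params))
    cat(sprintf("  c1c1 %.2f  lamY %.1f  lamR %.1f  shear %.2f  %s/%s %s\n",
                x$params$c1c1, x$params$lambda_Y, x$params$lambda_R,
                x$params$shear, x$chi_i$call, x$chi_j$call,
                x$orientation))
  cat(sprintf("  %d H-bond(s), %d water bridge(s), occupancy %.2f\n",
              nrow(x$hbonds), nrow(x$bridges), x$occupancy))
  invisible(x)
}

#' @export
print.duplex <- function(x, ...) {
  cat("<duplex>", x$label, "with", length(x$pairs), "base pairs\n")
  invisible(x)
}
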