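# Direct hydrogen bonds, bifurcated bonds, water-mediated bridges and ion
# coordination shells.  Heavy-atom criterion throughout: deposited crystal
# structures at 1.6-2.5 A rarely contain hydrogens, so a bond is a polar
# donor/acceptor pair within the distance cutoff.

# polar-atom table for one model: data frame of atom row indices with
# donor/acceptor capability and flags
.polar_atoms <- function(atoms) {
  n <- nrow(atoms)
  donor <- logical(n); acceptor <- logical(n); assumed <- logical(n)
  code <- .base_code[atoms$resname]
  nuc <- atoms$category == "nucleotide"
  for (i in which(nuc & !is.na(code))) {
    cd <- code[i]; nm <- atoms$name[i]
    if (nm %in% .base_donors[[cd]]) donor[i] <- TRUE
    if (nm %in% .base_acceptors[[cd]]) acceptor[i] <- TRUE
    ap <- .assumed_protonation_donors[[cd]]
    if (!is.null(ap) && nm %in% ap) assumed[i] <- TRUE
    if (nm %in% .backbone_acceptors) acceptor[i] <- TRUE
  }
  wat <- atoms$category == "water" & atoms$element == "O"
  donor[wat] <- TRUE; acceptor[wat] <- TRUE
  # ligand polar atoms participate generically by element
  lig <- atoms$category == "ligand" & atoms$element %in% c("N", "O")
  donor[lig] <- TRUE; acceptor[lig] <- TRUE
  data.frame(idx = seq_len(n), donor = donor, acceptor = acceptor,
             assumed = assumed)[donor | acceptor, , drop = FALSE]
}

#' Enumerate direct hydrogen bonds in a conformer model
#'
#' All donor-acceptor heavy-atom pairs within `cutoff`, excluding pairs
#' within the same residue, covalently linked backbone pairs, and
#' sub-covalent separations (< 2.0 Angstrom).  Cytosine N3 participates as
#' a donor under an assumed protonation state; such bonds carry
#' `protonation_assumed = TRUE`.
#'
#' @param model a `conformer_model`.
#' @param cutoff heavy-atom donor-acceptor distance cutoff in Angstrom.
#' @param include_water include bonds where one terminus is a water oxygen
#'   (default `TRUE`).
#' @return data frame of class `hbond_table`: donor/acceptor residue ids,
#'   names, atoms, distance, `protonation_assumed`, `bifurcated_group`
#'   (NA until [detect_bifurcated()]).
#' @export
find_hbonds <- function(model, cutoff = 3.5, include_water = TRUE) {
  atoms <- .model_atoms(model)
  pol <- .polar_atoms(atoms)
  empty <- data.frame(donor_res = character(), acceptor_res = character(),
                      donor_resname = character(), acceptor_resname = character(),
                      donor_atom = character(), acceptor_atom = character(),
                      distance = numeric(), protonation_assumed = logical(),
                      bifurcated_group = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("hbond_table", "data.frame")
  if (nrow(pol) < 2) return(empty)
  don <- pol[pol$donor, , drop = FALSE]
  acc <- pol[pol$acceptor, , drop = FALSE]
  if (!nrow(don) || !nrow(acc)) return(empty)
  dxyz <- as.matrix(atoms[don$idx, c("x", "y", "z")])
  axyz <- as.matrix(atoms[acc$idx, c("x", "y", "z")])
  dd <- outer(rowSums(dxyz^2), rowSums(axyz^2), "+") -
    2 * dxyz %*% t(axyz)
  dd[dd < 0] <- 0
  dist <- sqrt(dd)
  rid <- .res_id(atoms)
  hit <- which(dist <= cutoff & dist >= 2.0, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  di <- don$idx[hit[, 1]]; ai <- acc$idx[hit[, 2]]
  keep <- rid[di] != rid[ai]
  # drop symmetric duplicates for water-water / ligand-ligand pairs where
  # both atoms are donor+acceptor: keep one record per unordered atom pair
  pair_key <- ifelse(di < ai, paste(di, ai), paste(ai, di))
  both <- (atoms$category[di] %in% c("water", "ligand")) &
          (atoms$category[ai] %in% c("water", "ligand"))
  keep <- keep & !(both & duplicated(pair_key))
  if (!include_water)
    keep <- keep & atoms$category[di] != "water" &
            atoms$category[ai] != "water"
  # exclude the O3'-P covalent linkage neighbourhood
  keep <- keep & !(atoms$name[di] == "O3'" & atoms$name[ai] == "O5'" &
                     dist[hit] < 2.8)
  if (!any(keep)) return(empty)
  di <- di[keep]; ai <- ai[keep]
  out <- data.frame(
    donor_res = rid[di], acceptor_res = rid[ai],
    donor_resname = atoms$resname[di], acceptor_resname = atoms$resname[ai],
    donor_atom = atoms$name[di], acceptor_atom = atoms$name[ai],
    distance = dist[hit][keep],
    protonation_assumed = pol$assumed[match(di, pol$idx)],
    bifurcated_group = NA_integer_, stringsAsFactors = FALSE)
  out <- out[order(out$donor_res, out$acceptor_res, out$distance), ]
  rownames(out) <- NULL
  class(out) <- c("hbond_table", "data.frame")
  out
}

#' Annotate bifurcated hydrogen bonds
#'
#' Bonds sharing one acceptor atom with two or more donors from the same
#' partner residue (or one donor atom with two or more acceptors on the
#' same partner residue) receive a common `bifurcated_group` id.
#'
#' @param hbonds an `hbond_table` from [find_hbonds()].
#' @return the table with `bifurcated_group` filled in.
#' @export
detect_bifurcated <- function(hbonds) {
  if (!nrow(hbonds)) return(hbonds)
  hbonds$bifurcated_group <- NA_integer_
  gid <- 0L
  # shared acceptor, >=2 donors from one partner residue
  keyA <- paste(hbonds$acceptor_res, hbonds$acceptor_atom, hbonds$donor_res)
  keyD <- paste(hbonds$donor_res, hbonds$donor_atom, hbonds$acceptor_res)
  for (key in unique(keyA)) {
    rows <- which(keyA == key)
    if (length(unique(hbonds$donor_atom[rows])) >= 2) {
      gid <- gid + 1L
      hbonds$bifurcated_group[rows] <- gid
    }
  }
  for (key in unique(keyD)) {
    rows <- which(keyD == key & is.na(hbonds$bifurcated_group))
    if (length(unique(hbonds$acceptor_atom[rows])) >= 2) {
      gid <- gid + 1L
      hbonds$bifurcated_group[rows] <- gid
    }
  }
  hbonds
}

#' Enumerate water-mediated bridges
#'
#' Every water oxygen lying within `cutoff` of polar atoms of two
#' different non-water residues yields one bridge record per qualifying
#' partner pair, carrying both distances and the water B-factor.
#'
#' @param model a `conformer_model`.
#' @param cutoff per-leg heavy-atom distance cutoff in Angstrom.
#' @param partners optional character vector of two residue ids; only
#'   bridges joining those two residues are returned.
#' @return data frame of class `bridge_table`.
#' @export
find_water_bridges <- function(model, cutoff = 3.5, partners = NULL) {
  atoms <- .model_atoms(model)
  empty <- data.frame(water_res = character(), water_bfactor = numeric(),
                      res1 = character(), atom1 = character(),
                      dist1 = numeric(),
                      res2 = character(), atom2 = character(),
                      dist2 = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("bridge_table", "data.frame")
  wat <- which(atoms$category == "water" & atoms$element == "O")
  if (!length(wat)) return(empty)
  pol <- .polar_atoms(atoms)
  pi_ <- pol$idx[atoms$category[pol$idx] %in% c("nucleotide", "ligand")]
  if (!length(pi_)) return(empty)
  rid <- .res_id(atoms)
  pxyz <- as.matrix(atoms[pi_, c("x", "y", "z")])
  rows <- list()
  for (w in wat) {
    wx <- as.numeric(atoms[w, c("x", "y", "z")])
    d <- sqrt(rowSums(sweep(pxyz, 2, wx)^2))
    near <- which(d <= cutoff & d >= 2.0)
    if (length(near) < 2) next
    cmb <- utils::combn(near, 2)
    for (k in seq_len(ncol(cmb))) {
      i <- pi_[cmb[1, k]]; j <- pi_[cmb[2, k]]
      if (rid[i] == rid[j]) next
      rows[[length(rows) + 1L]] <- data.frame(
        water_res = rid[w], water_bfactor = atoms$bfactor[w],
        res1 = rid[i], atom1 = atoms$name[i], dist1 = d[cmb[1, k]],
        res2 = rid[j], atom2 = atoms$name[j], dist2 = d[cmb[2, k]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  if (!is.null(partners)) {
    ok <- (out$res1 %in% partners) & (out$res2 %in% partners) &
      out$res1 != out$res2
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("bridge_table", "data.frame")
  out
}

#' Ion coordination shells
#'
#' For each ion residue, reports coordinating O/N atoms within the ion
#' cutoff and labels the shell `octahedral` when it has exactly six
#' ligands whose cis ligand-ion-ligand angles are all within 90 +/- 15
#' degrees; otherwise `other`.
#'
#' @param model a `conformer_model`.
#' @param cutoff ion-ligand distance cutoff in Angstrom.
#' @return list of shells, each with `ion_res`, `ion_name`, a data frame
#'   `ligands` (residue id, atom, distance) and `geometry`.
#' @export
ion_shell <- function(model, cutoff = 2.8) {
  atoms <- .model_atoms(model)
  ions <- which(atoms$category == "ion")
  if (!length(ions)) return(list())
  rid <- .res_id(atoms)
  cand <- which(atoms$element %in% c("O", "N") & atoms$category != "ion")
  cxyz <- as.matrix(atoms[cand, c("x", "y", "z")])
  out <- list()
  for (i in ions) {
    ix <- as.numeric(atoms[i, c("x", "y", "z")])
    d <- sqrt(rowSums(sweep(cxyz, 2, ix)^2))
    near <- which(d <= cutoff)
    if (!length(near)) next
    lig <- data.frame(res = rid[cand[near]],
                      atom = atoms$name[cand[near]],
                      distance = d[near], stringsAsFactors = FALSE)
    geom <- "other"
    if (nrow(lig) == 6) {
      vecs <- sweep(cxyz[near, , drop = FALSE], 2, ix)
      angs <- c()
      for (a in 1:5) for (b in (a + 1):6)
        angs <- c(angs, .angle3(cxyz[near[a], ] ,ix, cxyz[near[b], ]))
      cis <- angs[angs <= 135]
      if (length(cis) && all(abs(cis - 90) <= 15)) geom <- "octahedral"
    }
    out[[length(out) + 1L]] <- list(ion_res = rid[i],
                                    ion_name = atoms$resname[i],
                                    ligands = lig, geometry = geom)
  }
  out
}
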