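# pi-pi stacking between adjacent bases and methyl-pi / methyl-sugar
# contacts of 5-methylcytosine.

.ring_centroid <- function(res_atoms, names) {
  have <- intersect(names, res_atoms$name)
  if (length(have) < length(names)) return(NULL)
  xyz <- t(vapply(have, function(nm) .atom_xyz(res_atoms, nm), numeric(3)))
  colMeans(xyz)
}

.ring_normal <- function(res_atoms, names) {
  have <- intersect(names, res_atoms$name)
  xyz <- t(vapply(have, function(nm) .atom_xyz(res_atoms, nm), numeric(3)))
  c0 <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, c0))
  sv$v[, 3]
}

#' pi-pi stacking geometry between two bases
#'
#' Uses the six-membered-ring heavy atoms of each base.  Reports the
#' centroid-centroid distance, the plane separation (projection of the
#' centroid displacement on the mean ring normal) and the angle between
#' the two ring planes.  Both conventional readings of a printed
#' "pi-pi distance" are therefore available.
#'
#' @param resA,resB atom data frames of the two bases.
#' @return list of class `stacking_contact` with `kind = "pi_pi"`,
#'   `centroid_distance`, `plane_separation`, `normal_angle`.
#' @export
pi_pi_distance <- function(resA, resB) {
  ra <- .six_ring_atoms(resA$resname[1]); rb <- .six_ring_atoms(resB$resname[1])
  ca <- .ring_centroid(resA, ra); cb <- .ring_centroid(resB, rb)
  if (is.null(ca) || is.null(cb))
    stop("missing six-membered-ring atoms for pi-pi measurement")
  na <- .ring_normal(resA, ra); nb <- .ring_normal(resB, rb)
  if (sum(na * nb) < 0) nb <- -nb
  nm <- .unit(na + nb)
  disp <- ca - cb
  ang <- .deg(acos(.clamp1(abs(sum(na * nb)))))
  structure(list(kind = "pi_pi",
                 res_i = .res_id(resA)[1], res_j = .res_id(resB)[1],
                 centroid_distance = .norm3(disp),
                 plane_separation = abs(sum(disp * nm)),
                 normal_angle = ang),
            class = "stacking_contact")
}

#' Methyl-pi and methyl-sugar contacts of 5-methylcytosine
#'
#' For each 5-methylcytosine (or, with `c5_proxy = TRUE`, each
#' unmethylated cytosine using C5 as the probe position) reports the
#' distance from the methyl carbon C7 (or C5) to (a) the base-ring
#' centroids of sequence-adjacent nucleotides on the same strand
#' (`methyl_pi`) and (b) the sugar-ring centroid of the 5' neighbour
#' (`methyl_sugar`).  Adjacency is by backbone connectivity.
#'
#' @param model a `conformer_model`.
#' @param c5_proxy measure from C5 of unmodified cytosines as well, for
#'   methylated-vs-unmethylated comparisons.
#' @return data frame of contacts (kind, residues, probe atom, distance).
#' @export
methyl_contacts <- function(model, c5_proxy = FALSE) {
  atoms <- .model_atoms(model)
  res <- .residues(model)
  nuc <- res[res$category == "nucleotide", , drop = FALSE]
  empty <- data.frame(kind = character(), res = character(),
                      probe = character(), partner = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(nuc)) return(empty)
  targets <- nuc[nuc$resname %in% c("5CM", "5MC") |
                   (c5_proxy & nuc$resname %in% c("DC", "C")), ,
                 drop = FALSE]
  if (!nrow(targets)) return(empty)
  nb <- .strand_neighbours(model)
  rows <- list()
  for (k in seq_len(nrow(targets))) {
    id <- targets$id[k]
    ra <- .res_atoms(model, id)
    probe_name <- if ("C7" %in% ra$name) "C7" else "C5"
    probe <- .atom_xyz(ra, probe_name)
    if (is.null(probe)) next
    for (dir in c("prev", "next")) {
      nid <- nb[[dir]][id]
      if (is.na(nid) || is.null(nid)) next
      rn <- .res_atoms(model, nid)
      cen <- .ring_centroid(rn, .six_ring_atoms(rn$resname[1]))
      if (!is.null(cen))
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "methyl_pi", res = id, probe = probe_name, partner = nid,
          distance = .norm3(probe - cen), stringsAsFactors = FALSE)
      if (dir == "prev") {
        sug <- .ring_centroid(rn, .sugar_ring_atoms)
        if (!is.null(sug))
          rows[[length(rows) + 1L]] <- data.frame(
            kind = "methyl_sugar", res = id, probe = probe_name,
            partner = nid, distance = .norm3(probe - sug),
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# 5' (prev) and 3' (next) strand neighbours by O3'->P connectivity
.strand_neighbours <- function(model) {
  atoms <- .model_atoms(model)
  o3 <- atoms[atoms$name == "O3'", , drop = FALSE]
  pp <- atoms[atoms$name == "P", , drop = FALSE]
  nxt <- character(0); prv <- character(0)
  if (nrow(o3) && nrow(pp)) {
    pmat <- as.matrix(pp[, c("x", "y", "z")])
    for (k in seq_len(nrow(o3))) {
      d <- sqrt(rowSums(sweep(pmat, 2,
                              as.numeric(o3[k, c("x", "y", "z")]))^2))
      hit <- which(d <= 2.0)
      from <- .res_id(o3[k, , drop = FALSE])
      hit <- hit[.res_id(pp[hit, , drop = FALSE]) != from]
      if (length(hit) == 1) {
        to <- .res_id(pp[hit, , drop = FALSE])
        nxt[from] <- to
        prv[to] <- from
      }
    }
  }
  list(`next` = nxt, prev = prv)
}
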