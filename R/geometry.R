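# Per-nucleotide and per-pair geometry: glycosidic torsion, base reference
# frames, lambda pivot angles, C1'-C1' distance, shear/stretch/stagger and
# buckle/propeller/opening via the mid-frame convention, and Kabsch RMSD.

.norm3 <- function(v) sqrt(sum(v * v))
.unit <- function(v) v / .norm3(v)
.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
.clamp1 <- function(x) pmin(1, pmax(-1, x))
.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

# angle a-b-c in degrees
.angle3 <- function(a, b, c) {
  u <- .unit(a - b); v <- .unit(c - b)
  .deg(acos(.clamp1(sum(u * v))))
}

# signed dihedral a-b-c-d in degrees, in (-180, 180]
.torsion <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  ang <- .deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

# rotation matrix about unit axis by angle in degrees (Rodrigues)
.rot_axis <- function(axis, angle_deg) {
  u <- .unit(axis); th <- .rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# place atom X bonded to c with |X-c| = dist, angle X-c-b = ang (deg) and
# torsion X-c-b-a = tor (deg): the internal-coordinate (Z-matrix) builder.
.place_atom <- function(a, b, c, dist, ang, tor) {
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  th <- .rad(180 - ang); ph <- -.rad(tor)
  d <- dist * (cos(th) * bc +
               sin(th) * (cos(ph) * m + sin(ph) * n))
  c + d
}

#' Glycosidic torsion and syn/anti state
#'
#' Computes the glycosidic torsion chi as the signed dihedral
#' O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for pyrimidines, and calls
#' the conformer `syn` when chi lies in (-90, +90] degrees, `anti`
#' otherwise.
#'
#' @param res_atoms atom data frame of one nucleotide residue (one
#'   conformer), e.g. a subset of a `conformer_model`'s `atoms`.
#' @return list with `chi` (degrees) and `call` (`"syn"`/`"anti"`), or
#'   `chi = NA` and `call = "undefined"` when a defining atom is missing.
#' @export
glycosidic_chi <- function(res_atoms) {
  resname <- res_atoms$resname[1]
  quad <- .chi_atoms(resname)
  pos <- lapply(quad, function(nm) .atom_xyz(res_atoms, nm))
  if (any(vapply(pos, is.null, logical(1))))
    return(list(chi = NA_real_, call = "undefined"))
  chi <- .torsion(pos[[1]], pos[[2]], pos[[3]], pos[[4]])
  list(chi = chi, call = if (chi > -90 && chi <= 90) "syn" else "anti")
}

#' Base reference frame by least-squares fit to the standard base
#'
#' Superposes the embedded standard base geometry onto the observed base
#' heavy atoms (Kabsch) and returns the implied frame: `origin` is the
#' image of the standard-frame origin, `axes` the right-handed orthonormal
#' triad (x toward the major-groove edge, y along the pairing axis, z the
#' base normal), `residual` the fit RMSD in Angstrom.
#'
#' @param res_atoms atom data frame of one nucleotide residue.
#' @return list with `origin`, `axes` (3x3, columns x/y/z) and `residual`.
#' @export
base_frame <- function(res_atoms) {
  resname <- res_atoms$resname[1]
  std <- .std_base_for(resname)
  if (is.null(std)) stop("no standard base geometry for residue ", resname)
  want <- .frame_atoms_for(resname)
  have <- intersect(want, res_atoms$name)
  if (length(have) < 6)
    stop("insufficient ring atoms for base frame of ", resname,
         " (", length(have), " < 6)")
  X <- std[have, , drop = FALSE]
  Y <- t(vapply(have, function(nm) .atom_xyz(res_atoms, nm), numeric(3)))
  k <- .kabsch(X, Y)
  list(origin = as.numeric(k$t), axes = k$R, residual = k$rmsd)
}

# Kabsch: find R (proper rotation), t minimizing ||Y - (X R^T + t)||.
# Returns R such that y ~ R x + t for row vectors x of X.
.kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  s <- svd(t(X0) %*% Y0)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fit <- X0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((Y0 - fit)^2)))
  list(R = R, t = cy - as.numeric(R %*% cx), rmsd = rmsd)
}

#' Base-pair geometric parameters
#'
#' Computes the C1'-C1' distance, the lambda pivot angles (the angle at
#' each C1' between the glycosidic bond and the C1'-C1' line; lambda_R for
#' the purine, lambda_Y for the pyrimidine), and the six rigid-body pair
#' parameters shear/stretch/stagger (Angstrom) and
#' buckle/propeller/opening (degrees) from the mid-frame decomposition of
#' the two base reference frames.  The second base's frame is flipped
#' (y, z negated) before comparison, per the standard convention for
#' paired bases on antiparallel strands.
#'
#' @param resA,resB atom data frames of the two paired nucleotides; by
#'   convention `resA` is the first-listed (reporting) strand.
#' @return list of class `pair_parameters` with fields `c1c1`, `lambda_Y`,
#'   `lambda_R` (or `lambda_A`/`lambda_B` positions when both bases have
#'   the same type class), `shear`, `stretch`, `stagger`, `buckle`,
#'   `propeller`, `opening` plus the two frames.
#' @export
pair_parameters <- function(resA, resB) {
  if (is.null(.atom_xyz(resA, "C1'")) || is.null(.atom_xyz(resB, "C1'")))
    stop("pair parameters undefined: missing C1' or glycosidic nitrogen")
  fA <- base_frame(resA); fB <- base_frame(resB)

  # C1' and glycosidic-N positions implied by the fitted frames: the fit
  # averages coordinate noise over all base atoms, so lambda does not
  # inherit the short glycosidic-bond lever arm of the raw atoms
  imp <- function(f, resname, nm) {
    std <- .std_base_for(resname)
    as.numeric(f$axes %*% std[nm, ] + f$origin)
  }
  rnA <- resA$resname[1]; rnB <- resB$resname[1]
  c1a <- imp(fA, rnA, "C1'"); c1b <- imp(fB, rnB, "C1'")
  na <- imp(fA, rnA, .glyco_n(rnA)); nb <- imp(fB, rnB, .glyco_n(rnB))

  c1c1 <- .norm3(c1a - c1b)
  lamA <- .angle3(na, c1a, c1b)
  lamB <- .angle3(nb, c1b, c1a)
  purA <- .is_purine_res(resA$resname[1])
  purB <- .is_purine_res(resB$resname[1])
  lambda_R <- if (purA) lamA else if (purB) lamB else NA_real_
  lambda_Y <- if (!purA) lamA else if (!purB) lamB else NA_real_

  p <- .midframe_params(fA, fB)
  structure(c(list(c1c1 = c1c1, lambda_Y = lambda_Y, lambda_R = lambda_R,
                   lambda_A = lamA, lambda_B = lamB),
              p, list(frameA = fA, frameB = fB)),
            class = "pair_parameters")
}

# mid-frame decomposition of frames (base B flipped)
.midframe_params <- function(fA, fB) {
  T1 <- fA$axes
  T2 <- fB$axes %*% diag(c(1, -1, -1))
  z1 <- T1[, 3]; z2 <- T2[, 3]
  cz <- .clamp1(sum(z1 * z2))
  gamma <- .deg(acos(cz))
  cr <- .cross(z2, z1)
  if (.norm3(cr) > 1e-9) {
    hinge <- .unit(cr)
    A1 <- .rot_axis(hinge, -gamma / 2) %*% T1
    A2 <- .rot_axis(hinge, +gamma / 2) %*% T2
  } else {
    # normals parallel (gamma ~ 0) or antiparallel (gamma ~ 180, e.g. a
    # Hoogsteen flip): hinge direction is arbitrary; use base A's x axis
    # for a deterministic decomposition
    hinge <- T1[, 1]
    A1 <- .rot_axis(hinge, -gamma / 2) %*% T1
    A2 <- .rot_axis(hinge, +gamma / 2) %*% T2
  }
  zm <- .unit((A1[, 3] + A2[, 3]) / 2)
  y1 <- A1[, 2]; y2 <- A2[, 2]
  opening <- .deg(atan2(sum(.cross(y2, y1) * zm), .clamp1(sum(y1 * y2))))
  Tm <- .rot_axis(zm, -opening / 2) %*% A1
  phi <- .deg(atan2(sum(hinge * Tm[, 2]), sum(hinge * Tm[, 1])))
  buckle <- gamma * cos(.rad(phi))
  propeller <- gamma * sin(.rad(phi))
  d <- as.numeric(t(Tm) %*% (fA$origin - fB$origin))
  list(shear = d[1], stretch = d[2], stagger = d[3],
       buckle = buckle, propeller = propeller, opening = opening,
       midframe = list(origin = (fA$origin + fB$origin) / 2, axes = Tm))
}

# inverse of .midframe_params: triads and origins for given parameters,
# mid-frame at the identity.  Used by the synthetic builder.
.frames_from_params <- function(shear = 0, stretch = 0, stagger = 0,
                                buckle = 0, propeller = 0, opening = 0) {
  gamma <- sqrt(buckle^2 + propeller^2)
  phi <- .deg(atan2(propeller, buckle))
  hinge <- c(cos(.rad(phi)), sin(.rad(phi)), 0)
  Rz <- function(a) .rot_axis(c(0, 0, 1), a)
  T1 <- if (gamma > 0) .rot_axis(hinge, +gamma / 2) %*% Rz(+opening / 2)
        else Rz(+opening / 2)
  T2f <- if (gamma > 0) .rot_axis(hinge, -gamma / 2) %*% Rz(-opening / 2)
         else Rz(-opening / 2)
  d <- c(shear, stretch, stagger)
  list(T1 = T1, o1 = +d / 2,
       T2 = T2f %*% diag(c(1, -1, -1)), o2 = -d / 2)
}

#' Least-squares superposition RMSD between two models
#'
#' Establishes atom correspondence by (chain, residue number, insertion
#' code, atom name) — optionally through a chain mapping — and reports the
#' optimal rigid-body (Kabsch) RMSD over the selection.  The default
#' selection is all heavy atoms of nucleotide residues; waters, ions and
#' ligands are excluded.
#'
#' @param modelA,modelB `conformer_model` (or `nastructure`) objects.
#' @param selection function taking an atom data frame and returning a
#'   logical vector; default selects nucleotide heavy atoms.
#' @param chain_map named character vector mapping chains of `modelA` to
#'   chains of `modelB` (default: identity).
#' @param offset_map named numeric vector of residue-number offsets per
#'   `modelA` chain applied before matching (default 0).
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(modelA, modelB, selection = NULL,
                           chain_map = NULL, offset_map = NULL) {
  if (is.null(selection))
    selection <- function(a) a$category == "nucleotide" & a$element != "H"
  a <- .model_atoms(modelA); b <- .model_atoms(modelB)
  a <- a[selection(a), , drop = FALSE]
  b <- b[selection(b), , drop = FALSE]
  ch <- a$chain
  if (!is.null(chain_map)) {
    mapped <- chain_map[ch]
    ch <- ifelse(is.na(mapped), ch, mapped)
  }
  rn <- a$resnum
  if (!is.null(offset_map)) {
    off <- offset_map[a$chain]
    rn <- rn + ifelse(is.na(off), 0, off)
  }
  keyA <- paste(ch, rn, a$icode, a$name)
  keyB <- paste(b$chain, b$resnum, b$icode, b$name)
  j <- match(keyA, keyB)
  ok <- !is.na(j)
  if (sum(ok) < 3) {
    unmatched <- unique(paste(a$chain[!ok], a$resnum[!ok]))
    stop("fewer than 3 corresponding atoms; unmatched residues: ",
         paste(utils::head(unmatched, 10), collapse = ", "))
  }
  A <- as.matrix(a[ok, c("x", "y", "z")])
  B <- as.matrix(b[j[ok], c("x", "y", "z")])
  # full-precision Kabsch (bio3d::rmsd rounds to 3 decimals)
  .kabsch(A, B)$rmsd
}

#' @export
print.pair_parameters <- function(x, ...) {
  cat(sprintf("C1'-C1' %.2f A  lambdaY %.1f  lambdaR %.1f\n",
              x$c1c1, x$lambda_Y, x$lambda_R))
  cat(sprintf("shear %.2f  stretch %.2f  stagger %.2f (A)\n",
              x$shear, x$stretch, x$stagger))
  cat(sprintf("buckle %.1f  propeller %.1f  opening %.1f (deg)\n",
              x$buckle, x$propeller, x$opening))
  invisible(x)
}
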