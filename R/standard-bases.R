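# Embedded standard-base geometries in the standard base reference frame:
# origin near the ring centre, x toward the major-groove edge, y along the
# pairing (long) axis toward the glycosidic bond, z the base normal.  All
# atoms lie in the z = 0 plane.  Pairing a complementary base is a rotation
# of pi about the x axis.  Heavy atoms only (plus C1' to anchor the
# glycosidic bond).

.std_base_raw <- list(
  A = c(
    "C1'", -2.479, 5.346,
    "N9",  -1.291, 4.498,
    "C8",   0.024, 4.897,
    "N7",   0.877, 3.902,
    "C5",   0.071, 2.771,
    "C6",   0.369, 1.398,
    "N6",   1.611, 0.909,
    "N1",  -0.668, 0.532,
    "C2",  -1.912, 1.023,
    "N3",  -2.320, 2.290,
    "C4",  -1.267, 3.124),
  G = c(
    "C1'", -2.477, 5.399,
    "N9",  -1.289, 4.551,
    "C8",   0.023, 4.962,
    "N7",   0.870, 3.969,
    "C5",   0.071, 2.833,
    "C6",   0.424, 1.460,
    "O6",   1.554, 0.955,
    "N1",  -0.700, 0.641,
    "C2",  -1.999, 1.087,
    "N2",  -2.949, 0.139,
    "N3",  -2.342, 2.364,
    "C4",  -1.265, 3.177),
  C = c(
    "C1'", -2.477, 5.402,
    "N1",  -1.285, 4.542,
    "C2",  -1.472, 3.158,
    "O2",  -2.628, 2.709,
    "N3",  -0.391, 2.344,
    "C4",   0.837, 2.868,
    "N4",   1.875, 2.027,
    "C5",   1.056, 4.275,
    "C6",  -0.023, 5.068),
  T = c(
    "C1'", -2.481, 5.354,
    "N1",  -1.284, 4.500,
    "C2",  -1.462, 3.135,
    "O2",  -2.562, 2.608,
    "N3",  -0.298, 2.407,
    "C4",   0.994, 2.897,
    "O4",   1.944, 2.119,
    "C5",   1.106, 4.338,
    "C7",   2.466, 4.961,
    "C6",  -0.024, 5.057),
  U = c(
    "C1'", -2.481, 5.354,
    "N1",  -1.284, 4.500,
    "C2",  -1.462, 3.131,
    "O2",  -2.563, 2.608,
    "N3",  -0.302, 2.397,
    "C4",   0.989, 2.884,
    "O4",   1.935, 2.094,
    "C5",   1.089, 4.311,
    "C6",  -0.024, 5.053)
)

.std_base_matrix <- function(raw) {
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  xyz <- cbind(as.numeric(m[, 2]), as.numeric(m[, 3]), 0)
  rownames(xyz) <- m[, 1]
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

# Derived bases: inosine lacks the N2 amino group of guanine; 5-methyl-C is
# cytosine with an in-plane methyl carbon C7 bonded to C5, placed 1.50 A
# from C5 along the exocyclic direction (away from the ring).
.make_std_bases <- function() {
  std <- lapply(.std_base_raw, .std_base_matrix)
  std$I <- std$G[rownames(std$G) != "N2", , drop = FALSE]
  mc <- std$C
  mid <- (mc["C4", ] + mc["C6", ]) / 2
  dir <- mc["C5", ] - mid
  dir <- dir / sqrt(sum(dir^2))
  mc <- rbind(mc, C7 = mc["C5", ] + 1.50 * dir)
  std$MC <- mc
  std
}

.std_bases <- .make_std_bases()

# One-letter base code per residue name (nucleotide rows only).
.base_code <- c(
  DA = "A", A = "A", ADE = "A",
  DG = "G", G = "G", GUA = "G",
  DC = "C", C = "C", CYT = "C",
  DT = "T", T = "T", THY = "T",
  DU = "U", U = "U", URA = "U",
  DI = "I", I = "I",
  `5CM` = "MC", `5MC` = "MC", DOC = "C"
)

.water_names <- c("HOH", "WAT", "DOD", "H2O")
.ion_names   <- c("MN", "MG", "NA", "K", "ZN", "CA", "CL")

.purine_codes     <- c("A", "G", "I")
.pyrimidine_codes <- c("C", "T", "U", "MC")

#' Residue category from residue name
#'
#' Maps a residue name to one of `nucleotide`, `water`, `ion`, `ligand`.
#' Standard and modified deoxy/ribo nucleotides (including 5-methylcytosine
#' `5CM` and inosine `DI`) are nucleotides; `HOH`/`WAT` are water;
#' common monatomic ions are ions; everything else is a ligand.
#'
#' @param resname character vector of residue names.
#' @return character vector of categories, same length as `resname`.
#' @export
residue_category <- function(resname) {
  resname <- toupper(trimws(resname))
  out <- rep("ligand", length(resname))
  out[resname %in% names(.base_code)] <- "nucleotide"
  out[resname %in% .water_names] <- "water"
  out[resname %in% .ion_names] <- "ion"
  out
}

.is_purine_res <- function(resname) {
  code <- .base_code[toupper(trimws(resname))]
  !is.na(code) & code %in% .purine_codes
}

.std_base_for <- function(resname) {
  code <- .base_code[[toupper(trimws(resname))]]
  if (is.null(code)) return(NULL)
  .std_bases[[code]]
}

# Ring atom names used for frame fitting (all base heavy atoms except C1')
.frame_atoms_for <- function(resname) {
  std <- .std_base_for(resname)
  if (is.null(std)) return(NULL)
  setdiff(rownames(std), "C1'")
}

# Six-membered-ring atoms for stacking centroids
.six_ring_atoms <- function(resname) {
  if (.is_purine_res(resname)) c("N1", "C2", "N3", "C4", "C5", "C6")
  else c("N1", "C2", "N3", "C4", "C5", "C6")
}

.sugar_ring_atoms <- c("C1'", "C2'", "C3'", "C4'", "O4'")

.glyco_n <- function(resname) if (.is_purine_res(resname)) "N9" else "N1"

# chi torsion atom quads: O4'-C1'-N9-C4 (purine) / O4'-C1'-N1-C2 (pyrimidine)
.chi_atoms <- function(resname) {
  if (.is_purine_res(resname)) c("O4'", "C1'", "N9", "C4")
  else c("O4'", "C1'", "N1", "C2")
}

# Hydrogen-bond donor / acceptor table per base code.  Heavy atoms only.
# Cytosine N3 is listed as a donor as well as an acceptor to support a
# protonated-N3 bond; such bonds are flagged "protonation-assumed".
.base_donors <- list(
  A  = c("N6"),
  G  = c("N1", "N2"),
  I  = c("N1"),
  C  = c("N4", "N3"),
  MC = c("N4", "N3"),
  T  = c("N3"),
  U  = c("N3")
)
.base_acceptors <- list(
  A  = c("N1", "N3", "N7"),
  G  = c("O6", "N7", "N3"),
  I  = c("O6", "N7", "N3"),
  C  = c("O2", "N3"),
  MC = c("O2", "N3"),
  T  = c("O2", "O4"),
  U  = c("O2", "O4")
)
# Donors that are only donors under an assumed protonation state
.assumed_protonation_donors <- list(C = "N3", MC = "N3")

.backbone_acceptors <- c("OP1", "OP2", "O4'", "O3'", "O5'")

# Edge membership for classification.  The pyrimidine Watson-Crick edge and
# the purine Watson-Crick / Hoogsteen edges, by base atoms.
.wc_edge <- list(
  A  = c("N1", "N6"),
  G  = c("N1", "N2", "O6"),
  I  = c("N1", "O6"),
  C  = c("N3", "N4", "O2"),
  MC = c("N3", "N4", "O2"),
  T  = c("N3", "O2", "O4"),
  U  = c("N3", "O2", "O4")
)
.hoogsteen_edge <- list(
  A = c("N7", "N6"),
  G = c("N7", "O6"),
  I = c("N7", "O6")
)
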