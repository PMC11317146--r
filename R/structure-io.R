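#' @importFrom stats setNames aggregate
#' @importFrom utils write.table
NULL

.atom_cols <- c("serial", "name", "altloc", "resname", "chain", "resnum",
                "icode", "x", "y", "z", "occupancy", "bfactor", "element")

.new_structure <- function(atoms, entry = "UNKN", resolution = NA_real_) {
  stopifnot(all(.atom_cols %in% names(atoms)))
  atoms$category <- residue_category(atoms$resname)
  rownames(atoms) <- NULL
  structure(list(entry = entry,
                 atoms = atoms,
                 altlocs = sort(unique(atoms$altloc[atoms$altloc != ""])),
                 resolution = resolution),
            class = "nastructure")
}

.guess_element <- function(name) {
  nm <- trimws(name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("MN", "MG", "NA", "CL", "ZN", "BR", "FE"),
         two, toupper(substr(gsub("[0-9']", "", nm), 1, 1)))
}

#' Read a nucleic-acid crystal structure
#'
#' Parses a PDB (fixed-column) or mmCIF (`atom_site` loop) coordinate file
#' into an atom-level container.  All ATOM/HETATM records are retained,
#' including waters, ions and ligand atoms; alternate-location labels,
#' occupancies and B-factors are preserved exactly.  Residues are
#' categorized as nucleotide, water, ion or ligand; unknown residue names
#' are categorized as ligand with a warning.
#'
#' @param path path to the coordinate file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension).
#' @return an object of class `nastructure` with elements `entry`,
#'   `atoms` (data frame of atom records), `altlocs` and `resolution`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  # cheap record sanity check so that arbitrary text fails as a parse
  # error while a valid header-only file still reads as empty
  head_lines <- readLines(path, n = 200, warn = FALSE)
  ok <- if (format == "mmcif") any(grepl("^data_|_atom_site", head_lines))
        else any(grepl("^(ATOM|HETATM|HEADER|REMARK|CRYST1|MODEL|TER|END)",
                       head_lines))
  if (!ok)
    stop("failed to parse ", format, " file '", path,
         "': no recognizable records")
  p <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e)))
  a <- p$atom
  atoms <- data.frame(
    serial = a$eleno,
    name = gsub('"', "", trimws(a$elety)),  # CIF-quoted primed names
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resname = toupper(trimws(a$resid)),
    chain = ifelse(is.na(a$chain), "", a$chain),
    resnum = a$resno,
    icode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    bfactor = ifelse(is.na(a$b), 0, a$b),
    element = if (!is.null(a$elesy) && !all(is.na(a$elesy)))
      toupper(ifelse(is.na(a$elesy), .guess_element(a$elety), trimws(a$elesy)))
    else .guess_element(a$elety),
    stringsAsFactors = FALSE)
  if (any(bad <- !is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates at serial(s): ",
         paste(atoms$serial[bad], collapse = ", "))
  cat_known <- atoms$resname %in% c(names(.base_code), .water_names, .ion_names)
  s <- .new_structure(atoms, entry = toupper(sub("\\.[^.]*$", "", basename(path))))
  unknown <- unique(atoms$resname[!cat_known])
  if (length(unknown))
    warning("unknown residue name(s) categorized as ligand: ",
            paste(unknown, collapse = ", "))
  s
}

.model_atoms <- function(x) {
  if (inherits(x, "nastructure")) x$atoms
  else if (inherits(x, "conformer_model")) x$atoms
  else if (is.data.frame(x)) x
  else stop("expected a nastructure or conformer_model")
}

#' Write a structure or conformer model to PDB or mmCIF
#'
#' Output is re-readable by [read_structure()] with coordinates equal
#' within the format precision (10^-3 Angstrom) and occupancies within
#' 10^-2.
#'
#' @param x a `nastructure` or `conformer_model`.
#' @param path output file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  atoms <- .model_atoms(x)
  if (format == "pdb") {
    if (nrow(atoms) && any(nchar(trimws(atoms$name)) > 4))
      stop("atom name longer than 4 characters cannot be written as PDB")
    if (nrow(atoms) && any(abs(c(atoms$x, atoms$y, atoms$z)) >= 10000))
      stop("coordinate exceeds the PDB fixed-width field (|v| >= 10000 A)")
    .write_pdb_atoms(atoms, path)
  } else {
    .write_mmcif_atoms(atoms, path,
                       entry = if (!is.null(x$entry)) x$entry else "XXXX")
  }
  invisible(path)
}

.write_pdb_atoms <- function(atoms, path) {
  if (!nrow(atoms)) {
    writeLines("END", path)
    return(invisible(path))
  }
  het <- atoms$category %in% c("water", "ion", "ligand")
  pdbatom <- data.frame(
    type = ifelse(het, "HETATM", "ATOM"),
    eleno = atoms$serial, elety = atoms$name,
    alt = ifelse(atoms$altloc == "", NA, atoms$altloc),
    resid = atoms$resname, chain = ifelse(atoms$chain == "", NA, atoms$chain),
    resno = atoms$resnum, insert = ifelse(atoms$icode == "", NA, atoms$icode),
    x = atoms$x, y = atoms$y, z = atoms$z,
    o = atoms$occupancy, b = atoms$bfactor,
    segid = NA, elesy = atoms$element, charge = NA,
    stringsAsFactors = FALSE)
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  p <- structure(list(atom = pdbatom, xyz = bio3d::as.xyz(xyz)),
                 class = "pdb")
  bio3d::write.pdb(p, file = path)
  invisible(path)
}

# Minimal mmCIF atom_site writer in the canonical wwPDB column layout
# (no installed R package writes mmCIF).
.write_mmcif_atoms <- function(atoms, path, entry = "XXXX") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("data_", entry), "#", "loop_",
               paste0("_atom_site.",
                      c("group_PDB", "id", "type_symbol", "label_atom_id",
                        "label_alt_id", "label_comp_id", "label_asym_id",
                        "label_entity_id", "label_seq_id",
                        "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                        "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                        "auth_seq_id", "auth_comp_id", "auth_asym_id",
                        "auth_atom_id", "pdbx_PDB_model_num"))), con)
  if (nrow(atoms)) {
    het <- atoms$category %in% c("water", "ion", "ligand")
    q <- function(v) ifelse(v == "" | is.na(v), ".", v)
    qa <- function(v) {
      # quote atom names containing primes
      ifelse(grepl("'", v), paste0('"', v, '"'), v)
    }
    lines <- paste(ifelse(het, "HETATM", "ATOM"), atoms$serial,
                   q(atoms$element), qa(q(atoms$name)), q(atoms$altloc),
                   q(atoms$resname), q(atoms$chain), 1, atoms$resnum,
                   ifelse(atoms$icode == "", "?", atoms$icode),
                   sprintf("%.3f", atoms$x), sprintf("%.3f", atoms$y),
                   sprintf("%.3f", atoms$z),
                   sprintf("%.2f", atoms$occupancy),
                   sprintf("%.2f", atoms$bfactor), "?",
                   atoms$resnum, q(atoms$resname), q(atoms$chain),
                   qa(q(atoms$name)), 1)
    writeLines(lines, con)
  }
  writeLines("#", con)
  invisible(path)
}

#' Expand alternate-location groups into single-conformer models
#'
#' Produces one self-consistent single-conformer view of the structure per
#' alternate-location label, each carrying the occupancy of its altloc
#' group.  Blank-altloc atoms are replicated into every model.  A
#' structure without altlocs yields a single model with occupancy 1.
#'
#' @param s a `nastructure`.
#' @return list of `conformer_model` objects.
#' @export
expand_conformers <- function(s) {
  atoms <- .model_atoms(s)
  labels <- sort(unique(atoms$altloc[atoms$altloc != ""]))
  entry <- if (!is.null(s$entry)) s$entry else "UNKN"
  if (!length(labels)) {
    return(list(.new_conformer(atoms, entry, label = "", occupancy = 1)))
  }
  lapply(labels, function(lab) {
    grp <- atoms[atoms$altloc == lab, , drop = FALSE]
    if (!nrow(grp)) return(NULL)
    occ <- grp$occupancy
    if (diff(range(occ)) > 0.05)
      warning("occupancies within altloc group '", lab,
              "' differ by more than 0.05 (range ",
              sprintf("%.2f-%.2f", min(occ), max(occ)), ")")
    sel <- atoms$altloc %in% c("", lab)
    .new_conformer(atoms[sel, , drop = FALSE], entry,
                   label = lab, occupancy = mean(occ))
  })
}

.new_conformer <- function(atoms, entry, label, occupancy) {
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate atom in conformer model: ",
         key[duplicated(key)][1])
  rownames(atoms) <- NULL
  structure(list(entry = entry, label = label, occupancy = occupancy,
                 atoms = atoms),
            class = "conformer_model")
}

#' @export
print.nastructure <- function(x, ...) {
  cat("<nastructure>", x$entry, "\n")
  cat("  atoms:", nrow(x$atoms), "\n")
  tab <- table(unique(x$atoms[, c("chain", "resnum", "icode", "resname",
                                  "category")])$category)
  cat("  residues:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  altlocs:", if (length(x$altlocs))
    paste(x$altlocs, collapse = ",") else "(none)", "\n")
  invisible(x)
}

#' @export
print.conformer_model <- function(x, ...) {
  cat("<conformer_model>", x$entry,
      if (x$label != "") paste0("altloc=", x$label) else "single-conformer",
      sprintf("occupancy=%.2f", x$occupancy), "\n")
  cat("  atoms:", nrow(x$atoms), "\n")
  invisible(x)
}

# --- residue helpers used across modules ---------------------------------

.res_id <- function(atoms) paste(atoms$chain, atoms$resnum, atoms$icode,
                                 sep = "|")

# table of residues in file order
.residues <- function(model) {
  atoms <- .model_atoms(model)
  id <- .res_id(atoms)
  first <- !duplicated(id)
  data.frame(id = id[first], chain = atoms$chain[first],
             resnum = atoms$resnum[first], icode = atoms$icode[first],
             resname = atoms$resname[first],
             category = atoms$category[first],
             stringsAsFactors = FALSE)
}

.res_atoms <- function(model, id) {
  atoms <- .model_atoms(model)
  atoms[.res_id(atoms) == id, , drop = FALSE]
}

.atom_xyz <- function(res_atoms, name) {
  i <- match(name, res_atoms$name)
  if (is.na(i)) return(NULL)
  as.numeric(res_atoms[i, c("x", "y", "z")])
}
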