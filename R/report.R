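# End-to-end orchestration: analyze structures (pairs, parameters,
# H-bond/bridge networks, stacking, classification, per-duplex RMSD
# matrix) and compare structures by superposition.

#' Analyze one or more structures end to end
#'
#' Pipeline: read, expand alternate-location conformers, detect base
#' pairs and duplexes, compute pair parameters, hydrogen bonds, water
#' bridges, ion shells and stacking contacts, classify every pair, and
#' collect an RMSD matrix across the duplexes of each entry.
#'
#' @param paths character vector of PDB/mmCIF files, or a list of
#'   `nastructure` objects.
#' @param thresholds cutoff list (see [detect_base_pairs()]); entries
#'   override the defaults.
#' @param c5_proxy also measure methyl-surrogate contacts from C5 of
#'   unmodified cytosines (for methylated-vs-unmethylated comparisons).
#' @return object of class `analysis_report`: per-entry tables `pairs`,
#'   `hbonds`, `bridges`, `ions`, `stacking`, `methyl`, `duplex_rmsd`,
#'   plus the run parameters.
#' @export
analyze <- function(paths, thresholds = list(), c5_proxy = FALSE) {
  th <- utils::modifyList(.default_thresholds(), thresholds)
  entries <- list()
  for (p in paths) {
    s <- if (inherits(p, "nastructure")) p else read_structure(p)
    models <- expand_conformers(s)
    m1 <- models[[1]]
    pairs_tab <- enumerate_pair_conformers(s, th)
    hb <- detect_bifurcated(find_hbonds(m1, cutoff = th$hbond_cutoff))
    br <- find_water_bridges(m1, cutoff = th$bridge_cutoff)
    ions <- ion_shell(m1, cutoff = th$ion_cutoff)
    stack <- .stacking_table(m1)
    methyl <- methyl_contacts(m1, c5_proxy = c5_proxy)
    dups <- build_duplexes(detect_base_pairs(m1, th), m1)
    rmat <- .duplex_rmsd_matrix(m1, dups)
    entries[[s$entry]] <- list(entry = s$entry, pairs = pairs_tab,
                               hbonds = hb, bridges = br, ions = ions,
                               stacking = stack, methyl = methyl,
                               duplexes = dups, duplex_rmsd = rmat)
  }
  structure(list(entries = entries, thresholds = th,
                 version = as.character(utils::packageVersion("bpgeom")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "analysis_report")
}

# pi-pi contacts between strand-adjacent bases
.stacking_table <- function(model) {
  nb <- .strand_neighbours(model)
  rows <- list()
  for (from in names(nb$`next`)) {
    to <- nb$`next`[[from]]
    ra <- .res_atoms(model, from); rb <- .res_atoms(model, to)
    if (ra$category[1] != "nucleotide" || rb$category[1] != "nucleotide")
      next
    ct <- tryCatch(pi_pi_distance(ra, rb), error = function(e) NULL)
    if (is.null(ct)) next
    rows[[length(rows) + 1L]] <- data.frame(
      res_i = from, res_j = to, kind = ct$kind,
      centroid_distance = ct$centroid_distance,
      plane_separation = ct$plane_separation,
      normal_angle = ct$normal_angle, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(res_i = character(), res_j = character(),
                      kind = character(), centroid_distance = numeric(),
                      plane_separation = numeric(),
                      normal_angle = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# pairwise all-heavy-atom RMSD between duplexes of one model, matching
# residues by position along each duplex
.duplex_rmsd_matrix <- function(model, dups) {
  k <- length(dups)
  if (k < 2) return(matrix(numeric(0), 0, 0))
  m <- matrix(NA_real_, k, k,
              dimnames = list(vapply(dups, `[[`, character(1), "label"),
                              vapply(dups, `[[`, character(1), "label")))
  diag(m) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <- tryCatch(
      .duplex_pair_rmsd(model, dups[[i]], dups[[j]]),
      error = function(e) NA_real_)
  }
  m
}

.duplex_pair_rmsd <- function(model, d1, d2) {
  res1 <- c(d1$strand1, d1$strand2)
  res2 <- c(d2$strand1, d2$strand2)
  if (length(res1) != length(res2))
    stop("duplexes have different lengths")
  A <- list(); B <- list()
  for (k in seq_along(res1)) {
    ra <- .res_atoms(model, res1[k]); rb <- .res_atoms(model, res2[k])
    common <- intersect(ra$name, rb$name)
    common <- common[!grepl("^H", common)]
    if (!length(common)) next
    A[[k]] <- as.matrix(ra[match(common, ra$name), c("x", "y", "z")])
    B[[k]] <- as.matrix(rb[match(common, rb$name), c("x", "y", "z")])
  }
  A <- do.call(rbind, A); B <- do.call(rbind, B)
  if (is.null(A) || nrow(A) < 3) stop("no corresponding atoms")
  .kabsch(A, B)$rmsd
}

#' Superpose two structures and report the RMSD
#'
#' Reads both inputs (paths or structures), takes the first (or named)
#' conformer of each, and reports the optimal rigid-body RMSD over
#' corresponding heavy atoms.  Waters, ions and ligands are excluded
#' unless `include_ligands` is set.
#'
#' @param a,b paths or `nastructure` objects.
#' @param include_ligands include ligand heavy atoms in the selection.
#' @param chain_map,offset_map correspondence adjustments, see
#'   [superpose_rmsd()].
#' @return RMSD in Angstrom.
#' @export
compare_structures <- function(a, b, include_ligands = FALSE,
                               chain_map = NULL, offset_map = NULL) {
  sa <- if (inherits(a, "nastructure")) a else read_structure(a)
  sb <- if (inherits(b, "nastructure")) b else read_structure(b)
  ma <- expand_conformers(sa)[[1]]
  mb <- expand_conformers(sb)[[1]]
  sel <- if (include_ligands)
    function(x) x$category %in% c("nucleotide", "ligand") & x$element != "H"
  else NULL
  superpose_rmsd(ma, mb, selection = sel, chain_map = chain_map,
                 offset_map = offset_map)
}

#' Write an analysis report to TSV and/or JSON
#'
#' TSV tables use two decimals for distances and one for angles, matching
#' crystallographic figure style; the JSON carries full precision.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @param format subset of `c("tsv", "json")`.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir, format = c("tsv", "json")) {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (e in report$entries) {
    base <- file.path(dir, e$entry)
    if ("tsv" %in% format) {
      tab <- e$pairs
      for (cn in c("c1c1", "shear"))
        tab[[cn]] <- round(tab[[cn]], 2)
      for (cn in c("lambda_Y", "lambda_R", "chi_i", "chi_j"))
        tab[[cn]] <- round(tab[[cn]], 1)
      tab$occupancy <- round(tab$occupancy, 2)
      f <- paste0(base, "_pairs.tsv")
      utils::write.table(tab, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, f)
      f <- paste0(base, "_hbonds.tsv")
      hb <- e$hbonds
      hb$distance <- round(hb$distance, 2)
      utils::write.table(hb, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, f)
    }
    if ("json" %in% format) {
      f <- paste0(base, ".json")
      payload <- list(entry = e$entry, pairs = e$pairs, hbonds = e$hbonds,
                      bridges = e$bridges, stacking = e$stacking,
                      methyl = e$methyl,
                      duplex_rmsd = e$duplex_rmsd,
                      parameters = report$thresholds,
                      version = report$version,
                      timestamp = report$timestamp)
      jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA,
                           na = "null")
      written <- c(written, f)
    }
  }
  invisible(written)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>", length(x$entries), "entr",
      if (length(x$entries) == 1) "y" else "ies", "\n")
  for (e in x$entries) {
    cat("--", e$entry, ":", length(e$duplexes), "duplex(es),",
        nrow(e$pairs), "pair record(s)\n")
    lab <- table(e$pairs$label)
    cat("   classes:", paste(names(lab), lab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}
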