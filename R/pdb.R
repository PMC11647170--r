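# Receptor structures: thin data.frame model over bio3d's PDB reader/writer.
# Residue numbering is kept exactly as in the file (the reference compound
# tables cite PDB numbers such as W88 and E265); generic GPCR labels
# (Ballesteros-Weinstein style "3.32") are an optional user-supplied
# annotation map, never computed.

#' Construct a receptor structure
#'
#' @param atoms data.frame with columns `serial`, `name` (PDB atom name),
#'   `resname`, `chain`, `resno`, `element`, `x`, `y`, `z` (Angstrom).
#' @param annotations optional named character vector mapping
#'   `"<chain>:<resno>"` to a generic residue label (e.g. `"7.39"`).
#' @return object of class `receptor_structure`.
#' @export
receptor_structure <- function(atoms, annotations = NULL) {
  needed <- c("serial", "name", "resname", "chain", "resno",
              "element", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0)
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) > 0 && any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite receptor coordinates")
  structure(list(atoms = atoms, annotations = annotations),
            class = "receptor_structure")
}

#' @export
print.receptor_structure <- function(x, ...) {
  cat(sprintf("<receptor_structure: %d atoms, %d residues>\n",
              nrow(x$atoms), nrow(unique(x$atoms[, c("chain", "resno")]))))
  invisible(x)
}

#' Read a PDB file into a receptor structure
#'
#' Fixed-column PDB v3.3 subset (ATOM/HETATM/TER/END), parsed with bio3d
#' after a validation pass that reports the first malformed coordinate
#' field with its line number. An empty file yields an empty structure
#' with a warning.
#'
#' @param path PDB file path.
#' @param include_hetatm also keep HETATM records (default FALSE).
#' @return a [receptor_structure()].
#' @export
read_pdb <- function(path, include_hetatm = FALSE) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) {
    warning("no ATOM/HETATM records in ", path)
    return(receptor_structure(data.frame(
      serial = integer(), name = character(), resname = character(),
      chain = character(), resno = integer(), element = character(),
      x = numeric(), y = numeric(), z = numeric())))
  }
  for (ln in which(is_atom)) {
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      field <- substr(lines[ln], cols[1], cols[2])
      if (is.na(suppressWarnings(as.numeric(field))))
        stop("malformed coordinate field at line ", ln, ": '",
             trimws(field), "'")
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (!include_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  element <- at$elesy
  blank <- is.na(element) | !nzchar(trimws(element))
  # fall back to the leading letter(s) of the atom name
  element[blank] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", at$elety[blank])
  chain <- at$chain
  chain[is.na(chain)] <- " "
  receptor_structure(data.frame(
    serial = at$eleno, name = at$elety, resname = at$resid,
    chain = chain, resno = at$resno, element = trimws(element),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
}

#' Write a receptor structure to a PDB file
#'
#' Delegates to bio3d's writer; round-trips through [read_pdb()].
#'
#' @param receptor a [receptor_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(receptor, path) {
  at <- receptor$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resname,
                   eleno = at$serial, elety = at$name,
                   chain = at$chain, elesy = at$element)
  invisible(path)
}

#' Residue table of a receptor
#' @param receptor a [receptor_structure()].
#' @return data.frame with one row per residue (`chain`, `resno`, `resname`).
#' @export
receptor_residues <- function(receptor) {
  unique(receptor$atoms[, c("chain", "resno", "resname")])
}

#' Construct a receptor-ligand complex pose
#'
#' Container for externally produced docking output: one receptor, one
#' ligand pose with coordinates, and an optional binding-energy score in
#' kcal/mol (more negative = predicted stronger binding).
#'
#' @param receptor a [receptor_structure()].
#' @param ligand a [molecule()] with coordinates.
#' @param score optional pose score, kcal/mol.
#' @return object of class `complex_pose`.
#' @export
complex_pose <- function(receptor, ligand, score = NULL) {
  stopifnot(inherits(receptor, "receptor_structure"),
            inherits(ligand, "molecule"))
  if (is.null(ligand$coords))
    stop("ligand '", ligand$id, "' has no coordinates")
  structure(list(receptor = receptor, ligand = ligand,
                 score = if (is.null(score)) NULL else as.numeric(score)),
            class = "complex_pose")
}

#' @export
print.complex_pose <- function(x, ...) {
  cat(sprintf("<complex_pose: ligand %s, %d receptor atoms%s>\n",
              x$ligand$id, nrow(x$receptor$atoms),
              if (is.null(x$score)) "" else
                sprintf(", score %.2f kcal/mol", x$score)))
  invisible(x)
}
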