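# SMILES and SDF input/output. Parsing is delegated to ChemmineR/ChemmineOB
# (OpenBabel); this layer converts to/from the package's molecule model,
# perceives aromatic rings on the kekulized output, strips salt counter-ions
# and counts implicit hydrogens.

# V2000 charge codes: 1..3 -> +3..+1, 5..7 -> -1..-3, 0/4 -> 0.
.v2000_charge <- function(code) {
  ifelse(code %in% 1:3, 4L - as.integer(code),
         ifelse(code %in% 5:7, 4L - as.integer(code), 0L))
}

# Fallback fixed-field V2000 block reader, used only where ChemmineR's
# reader rejects a block (it cannot represent bond-free molecules, e.g.
# methane). `lines` is one molecule's record without the trailing $$$$.
.parse_v2000 <- function(lines, id) {
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) stop("bad V2000 counts line for record ", id)
  atoms <- lines[4 + seq_len(na)]
  coords <- t(vapply(atoms, function(l) {
    c(as.numeric(substr(l, 1, 10)), as.numeric(substr(l, 11, 20)),
      as.numeric(substr(l, 21, 30)))
  }, numeric(3)))
  elements <- trimws(substr(atoms, 32, 34))
  charges <- .v2000_charge(suppressWarnings(as.integer(substr(atoms, 37, 39))))
  charges[is.na(charges)] <- 0L
  bonds <- NULL
  if (nb > 0) {
    bl <- lines[4 + na + seq_len(nb)]
    bonds <- data.frame(i = as.integer(substr(bl, 1, 3)),
                        j = as.integer(substr(bl, 4, 6)),
                        order = as.character(pmin(as.integer(substr(bl, 7, 9)), 3L)),
                        stringsAsFactors = FALSE)
  }
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    nent <- as.integer(substr(l, 7, 9))
    for (q in seq_len(nent)) {
      off <- 10 + (q - 1) * 8
      charges[as.integer(substr(l, off, off + 3))] <-
        as.integer(substr(l, off + 4, off + 7))
    }
  }
  has_coords <- any(abs(coords[, 3]) > 1e-8) || na == 1
  mol <- molecule(id, elements, charges, bonds = bonds,
                  coords = if (has_coords) unname(coords) else NULL)
  perceive_aromatic(mol)
}

# Convert one ChemmineR SDF object to a molecule.
sdf_to_molecule <- function(sdf, id, keep_largest = TRUE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  charge_col <- if ("C6" %in% colnames(ab)) "C6" else NULL
  charges <- if (!is.null(charge_col)) .v2000_charge(ab[, charge_col]) else
    integer(length(elements))
  bonds <- if (is.matrix(bb) && nrow(bb) > 0) {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.character(pmin(as.integer(bb[, 3]), 3L)),
               stringsAsFactors = FALSE)
  } else NULL
  has_coords <- any(abs(coords[, 3]) > 1e-8) || nrow(coords) == 1
  mol <- molecule(id, elements, charges, bonds = bonds,
                  coords = if (has_coords) coords else NULL)
  mol <- perceive_aromatic(mol)
  if (keep_largest && max(mol_components(mol)) > 1L) {
    message("molecule ", id, ": multiple fragments, keeping the largest")
    mol <- largest_fragment(mol)
  }
  mol
}

#' Parse a single SMILES string into a molecule
#'
#' Parsing uses OpenBabel (via ChemmineR/ChemmineOB); the kekulized output
#' is converted to the heavy-atom graph model and aromatic rings are
#' re-perceived. Multi-fragment input (salts) keeps the largest fragment
#' with a message. Stereo descriptors are accepted but ignored.
#'
#' @param smiles a SMILES string.
#' @param id compound identifier (default the SMILES itself).
#' @return a [molecule()] without coordinates.
#' @export
read_smiles <- function(smiles, id = smiles) {
  smiles <- trimws(smiles)
  if (!nzchar(smiles)) stop("empty SMILES for record ", id)
  raw <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = smiles),
    error = function(e) stop("SMILES parse failure for record '", id, "': ",
                             conditionMessage(e), call. = FALSE))
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 5 || !any(grepl("V2000", lines)))
    stop("SMILES parse failure for record '", id, "'")
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(lines)),
                     error = function(e) NULL)
  mol <- if (!is.null(sdfset) &&
             isTRUE(suppressWarnings(ChemmineR::validSDF(sdfset))[1])) {
    sdf_to_molecule(sdfset[[1]], id, keep_largest = FALSE)
  } else {
    .parse_v2000(lines, id)  # bond-free molecules (ChemmineR limitation)
  }
  if (max(mol_components(mol)) > 1L) {
    message("molecule ", id, ": multiple fragments, keeping the largest")
    mol <- largest_fragment(mol)
  }
  mol$coords <- NULL  # 2D sketch coordinates are not real geometry
  mol
}

#' Read a SMILES file
#'
#' Format: one record per line, `SMILES<whitespace>id`; `#` starts a
#' comment; records lacking an id are numbered. Unparsable records are
#' skipped with a warning naming the record, the batch never aborts.
#'
#' @param path file path.
#' @return named list of [molecule()] objects.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  mols <- list()
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[k], "[[:space:]]+")[[1]]
    id <- if (length(fields) >= 2) fields[2] else paste0("mol_", k)
    m <- tryCatch(read_smiles(fields[1], id), error = function(e) {
      warning("skipping record '", id, "': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(m)) mols[[id]] <- m
  }
  mols
}

#' Write a molecule as canonical SMILES
#'
#' The molecule is serialised to a V2000 block and canonicalised by
#' OpenBabel, so `read_smiles(write_smiles(mol))` reproduces the same graph.
#'
#' @param mol a [molecule()].
#' @return a SMILES string.
#' @export
write_smiles <- function(mol) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  write_sdf(mol, tmp)
  smi <- ChemmineOB::convertFormatFile("SDF", "SMI", tmp,
                                       toFile = paste0(tmp, ".smi"))
  out <- readLines(paste0(tmp, ".smi"), warn = FALSE)
  unlink(paste0(tmp, ".smi"))
  strsplit(trimws(out[1]), "[[:space:]]+")[[1]][1]
}

#' Write molecules to an SDF (V2000) file
#'
#' Minimal V2000 writer: counts line, atom block with coordinates (zero if
#' the molecule has none), bond block (aromatic emitted as order 4), and
#' `M  CHG` lines for formal charges. A `> <score>` data field is written
#' when the molecule carries a `score` attribute (docking pose plumbing).
#'
#' @param mols a [molecule()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    n <- n_atoms(mol)
    nb <- nrow(mol$bonds)
    xyz <- if (is.null(mol$coords)) matrix(0, n, 3) else mol$coords
    writeLines(c(mol$id, "  bitterqsar", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    chg_code <- ifelse(mol$charges >= 1 & mol$charges <= 3, 4L - mol$charges,
                ifelse(mol$charges <= -1 & mol$charges >= -3, 4L - mol$charges,
                       0L))
    for (a in seq_len(n))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                         xyz[a, 1], xyz[a, 2], xyz[a, 3], mol$elements[a],
                         chg_code[a]), con)
    if (nb > 0) {
      ord <- ifelse(mol$bonds$order == "ar", 4L, as.integer(mol$bonds$order))
      for (b in seq_len(nb))
        writeLines(sprintf("%3d%3d%3d  0  0  0  0",
                           mol$bonds$i[b], mol$bonds$j[b], ord[b]), con)
    }
    chg <- which(mol$charges != 0L)
    if (length(chg) > 0) {
      for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
        writeLines(paste0("M  CHG", sprintf("%3d", length(grp)),
                          paste0(sprintf("%4d%4d", grp, mol$charges[grp]),
                                 collapse = "")), con)
      }
    }
    writeLines("M  END", con)
    if (!is.null(attr(mol, "score")))
      writeLines(c(">  <score>", format(attr(mol, "score")), ""), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Read molecules from an SDF (V2000) file
#'
#' Reading is delegated to ChemmineR; molecules with all-zero z coordinates
#' are treated as 2D and returned without coordinates unless
#' `keep_2d_coords = TRUE`. A `<score>` data field is attached as the
#' `score` attribute (kcal/mol, docking pose plumbing).
#'
#' @param path SDF file path.
#' @param keep_2d_coords keep coordinates even when planar.
#' @return named list of [molecule()] objects.
#' @export
read_sdf <- function(path, keep_2d_coords = TRUE) {
  all_lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", all_lines)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- list()
  for (k in seq_along(ends)) {
    block <- all_lines[starts[k]:(ends[k] - 1L)]
    if (!any(nzchar(trimws(block)))) next
    id <- trimws(block[1])
    if (!nzchar(id)) id <- paste0("mol_", k)
    sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(c(block, "$$$$"))),
                       error = function(e) NULL)
    mol <- if (!is.null(sdfset) &&
               isTRUE(suppressWarnings(ChemmineR::validSDF(sdfset))[1])) {
      sdf_to_molecule(sdfset[[1]], id)
    } else {
      .parse_v2000(block, id)
    }
    if (!keep_2d_coords && !is.null(mol$coords) &&
        all(abs(mol$coords[, 3]) < 1e-8)) mol$coords <- NULL
    sc <- grep("^> *<score>", block)
    if (length(sc) == 1 && sc < length(block))
      attr(mol, "score") <- as.numeric(block[sc + 1])
    out[[id]] <- mol
  }
  out
}
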