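#' @importFrom stats optim rnorm runif setNames cor coef cmdscale dist
#' @importFrom utils read.csv write.csv head tail
NULL

# Pinned standard atomic weights (g/mol). Versioned via attr on the table so
# descriptor output metadata can record which weight set produced an MW column.
.ATOMIC_WEIGHTS <- c(
  H = 1.00794, B = 10.811, C = 12.0107, N = 14.0067, O = 15.9994,
  F = 18.9984032, Si = 28.0855, P = 30.973762, S = 32.065,
  Cl = 35.453, Br = 79.904, I = 126.90447
)
attr(.ATOMIC_WEIGHTS, "version") <- "IUPAC-2005-pinned"

# Default valences used for implicit-hydrogen counting on the heavy-atom
# graph. Charge shifts valence by +charge for N/P and by +charge for O/S
# (carboxylate O-, ammonium N+ handled this way).
.DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

#' Construct a molecule
#'
#' The package's molecule model is a heavy-atom graph: element symbols,
#' formal charges and aromatic flags per atom, bonds with order 1, 2, 3 or
#' "ar" (aromatic), and optional 3D coordinates in Angstrom. Hydrogens are
#' implicit; operations that need them (molecular weight, CH-pi donor
#' detection) count them on demand from standard valences. Explicit H atoms
#' are nevertheless allowed (the toy-complex generator places a few to make
#' hydrogen-bond angles checkable).
#'
#' @param id compound identifier.
#' @param elements character vector of element symbols.
#' @param charges integer formal charges, one per atom (default 0).
#' @param aromatic logical aromatic flags, one per atom (default FALSE).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3, or "ar"); each bond stored once.
#' @param coords optional numeric matrix (n x 3) of coordinates in Angstrom.
#' @return an object of class `molecule`.
#' @export
molecule <- function(id, elements, charges = NULL, aromatic = NULL,
                     bonds = NULL, coords = NULL) {
  n <- length(elements)
  if (n < 1L) stop("molecule needs at least one atom")
  unknown <- setdiff(unique(elements), names(.DEFAULT_VALENCE))
  if (length(unknown) > 0)
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  if (is.null(charges)) charges <- integer(n)
  if (is.null(aromatic)) aromatic <- logical(n)
  if (is.null(bonds))
    bonds <- data.frame(i = integer(), j = integer(), order = character(),
                        stringsAsFactors = FALSE)
  bonds$order <- as.character(bonds$order)
  stopifnot(length(charges) == n, length(aromatic) == n)
  if (nrow(bonds) > 0) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond refers to an atom index outside 1..", n)
    if (any(bonds$i == bonds$j)) stop("self-bond not allowed")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3)
      stop("coords must be an n x 3 matrix")
    if (any(!is.finite(coords))) stop("coords must be finite")
    dimnames(coords) <- NULL
  }
  structure(list(id = as.character(id), elements = as.character(elements),
                 charges = as.integer(charges), aromatic = as.logical(aromatic),
                 bonds = bonds, coords = coords),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms, %d bonds%s>\n", x$id,
              n_atoms(x), nrow(x$bonds),
              if (is.null(x$coords)) "" else ", 3D"))
  invisible(x)
}

#' Number of atoms in the molecule graph
#' @param mol a `molecule`.
#' @return integer atom count (explicit atoms only).
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Heavy-atom count (non-hydrogen explicit atoms)
#' @param mol a `molecule`.
#' @return integer.
#' @export
n_heavy_atoms <- function(mol) sum(mol$elements != "H")

# igraph view of the molecule graph (explicit atoms, unit edge weights).
mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (nrow(mol$bonds) > 0)
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  g
}

# Numeric bond order (aromatic counted as 1.5 for valence purposes).
bond_order_num <- function(order) {
  ifelse(order == "ar", 1.5, suppressWarnings(as.numeric(order)))
}

#' Implicit hydrogen count per atom
#'
#' Standard-valence arithmetic on the heavy-atom graph: for each atom the
#' implicit H count is the default valence of its element (shifted by formal
#' charge for N, P, O and S) minus the sum of its bond orders, clamped at
#' zero. Aromatic bonds count 1.5, and an atom with two aromatic bonds plus
#' possibly other single bonds gets the usual aromatic-carbon answer
#' (e.g. benzene carbon: 4 - 3 = 1).
#'
#' @param mol a `molecule`.
#' @return integer vector, one entry per atom (0 for explicit H atoms).
#' @export
implicit_h_counts <- function(mol) {
  n <- n_atoms(mol)
  deg_order <- numeric(n)
  if (nrow(mol$bonds) > 0) {
    ord <- bond_order_num(mol$bonds$order)
    for (k in seq_len(nrow(mol$bonds))) {
      deg_order[mol$bonds$i[k]] <- deg_order[mol$bonds$i[k]] + ord[k]
      deg_order[mol$bonds$j[k]] <- deg_order[mol$bonds$j[k]] + ord[k]
    }
  }
  val <- .DEFAULT_VALENCE[mol$elements]
  shift <- ifelse(mol$elements %in% c("N", "P", "O", "S"), mol$charges, 0L)
  h <- floor(val + shift - deg_order + 1e-9)
  h[mol$elements == "H"] <- 0
  pmax(as.integer(round(h)), 0L)
}

#' Molecular formula as an element count vector
#' @param mol a `molecule`.
#' @return named integer vector of element counts, hydrogens included.
#' @export
element_counts <- function(mol) {
  counts <- table(mol$elements)
  out <- setNames(as.integer(counts), names(counts))
  nh <- sum(implicit_h_counts(mol))
  if (nh > 0) out["H"] <- (if ("H" %in% names(out)) out["H"] else 0L) + nh
  out[order(names(out))]
}

#' Molecular weight in g/mol
#'
#' Sum of pinned standard atomic weights over all atoms including implicit
#' hydrogens. Reproduces the printed MW columns of the reference compound
#' tables to two decimals (e.g. strychnine C21H22N2O2 = 334.41 g/mol).
#'
#' @param mol a `molecule`.
#' @return numeric scalar, g/mol.
#' @export
molecular_weight <- function(mol) {
  counts <- element_counts(mol)
  unknown <- setdiff(names(counts), names(.ATOMIC_WEIGHTS))
  if (length(unknown) > 0)
    stop("no atomic weight for element(s): ", paste(unknown, collapse = ", "))
  sum(.ATOMIC_WEIGHTS[names(counts)] * counts)
}

#' Molecular weight from a molecular formula string
#'
#' Same pinned atomic-weight table as [molecular_weight()], applied to a
#' Hill-style formula such as `"C29H30O13"`.
#'
#' @param formula molecular formula string.
#' @return numeric scalar, g/mol.
#' @export
formula_weight <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (length(parts) == 0 || paste(parts, collapse = "") != formula)
    stop("cannot parse formula: ", formula)
  total <- 0
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    cnt <- sub("^[A-Za-z]+", "", p)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!el %in% names(.ATOMIC_WEIGHTS))
      stop("no atomic weight for element: ", el)
    total <- total + .ATOMIC_WEIGHTS[[el]] * cnt
  }
  total
}

# Connected components of the heavy-atom graph; returns membership vector.
mol_components <- function(mol) {
  igraph::components(mol_graph(mol))$membership
}

# Keep the largest connected fragment (ties -> first); used for salt
# stripping on multi-fragment SMILES input.
largest_fragment <- function(mol) {
  memb <- mol_components(mol)
  if (max(memb) == 1L) return(mol)
  sizes <- tabulate(memb)
  keep_comp <- which.max(sizes)
  keep <- which(memb == keep_comp)
  remap <- match(seq_len(n_atoms(mol)), keep)
  b <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  molecule(mol$id, mol$elements[keep], mol$charges[keep], mol$aromatic[keep],
           b, if (is.null(mol$coords)) NULL else mol$coords[keep, , drop = FALSE])
}

# --- ring perception -------------------------------------------------------

# Smallest set of smallest rings (SSSR-style): for each edge in a cycle,
# find the shortest cycle through it (BFS in the graph minus that edge),
# keep a minimal unique set covering the cycle space.
mol_rings <- function(mol) {
  g <- mol_graph(mol)
  nb <- igraph::ecount(g) - igraph::vcount(g) +
    igraph::components(g)$no  # cyclomatic number
  if (nb <= 0) return(list())
  rings <- list()
  seen <- character()
  el <- igraph::as_edgelist(g)
  for (k in seq_len(nrow(el))) {
    i <- el[k, 1]; j <- el[k, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = i, to = j)$vpath[[1]])
    if (length(sp) == 0) next
    ring <- as.integer(sp)
    key <- paste(sort(ring), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- ring
    }
  }
  # keep smallest rings first, stop once the cycle space is covered
  rings <- rings[order(vapply(rings, length, 1L))]
  if (length(rings) > nb) rings <- rings[seq_len(nb)]
  rings
}

# Aromatic perception on a kekulized graph (OpenBabel output): a ring is
# aromatic if every ring atom is sp2-capable (C/N/O/S) and every ring carbon
# participates in at least one double/aromatic bond, with even alternation
# plausible. This deliberately targets benzenoid and common heteroaromatic
# rings; exotic aromaticity is out of scope.
perceive_aromatic <- function(mol) {
  rings <- mol_rings(mol)
  if (length(rings) == 0) return(mol)
  bkey <- paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
  ord <- bond_order_num(mol$bonds$order)
  has_multiple <- logical(n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    if (ord[k] >= 1.5) {
      has_multiple[mol$bonds$i[k]] <- TRUE
      has_multiple[mol$bonds$j[k]] <- TRUE
    }
  }
  arom_atoms <- logical(n_atoms(mol))
  for (ring in rings) {
    if (!length(ring) %in% c(5L, 6L)) next
    els <- mol$elements[ring]
    if (!all(els %in% c("C", "N", "O", "S"))) next
    carbons <- ring[els == "C"]
    if (!all(has_multiple[carbons])) next
    # count in-ring double bonds: need alternation, i.e. floor(len/2) doubles
    rkeys <- character(length(ring))
    ok <- TRUE
    for (t in seq_along(ring)) {
      a <- ring[t]; b <- ring[if (t == length(ring)) 1L else t + 1L]
      kk <- paste(min(a, b), max(a, b))
      if (!kk %in% bkey) { ok <- FALSE; break }
      rkeys[t] <- kk
    }
    if (!ok) next
    ndouble <- sum(ord[match(rkeys, bkey)] >= 1.5)
    need <- if (length(ring) == 6L) 3L else 2L
    if (ndouble < need) next
    arom_atoms[ring] <- TRUE
  }
  # flags only: kekule bond orders are kept so implicit-H arithmetic on
  # N-H heteroaromatics (pyrrole-type) stays correct
  mol$aromatic <- mol$aromatic | arom_atoms
  mol
}

# Aromatic rings (list of atom-index vectors): SSSR rings whose atoms are
# all flagged aromatic.
aromatic_rings <- function(mol) {
  Filter(function(r) all(mol$aromatic[r]), mol_rings(mol))
}
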