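# Topological and compositional descriptors. The two descriptors the
# published binding-energy model uses are wienerPath (here) and vsurf_S
# (mif module); the descriptor pool pads these with deterministic derived
# columns to emulate a realistic several-hundred-column search space for
# the genetic algorithm.

heavy_atom_graph <- function(mol) {
  keep <- which(mol$elements != "H")
  g <- mol_graph(mol)
  igraph::induced_subgraph(g, keep)
}

#' Wiener path number of the heavy-atom graph
#'
#' Half the sum of all entries of the topological distance matrix: the sum
#' of shortest-path bond distances over unordered heavy-atom pairs. Unit
#' bond lengths regardless of bond order; hydrogens excluded (a
#' hydrogen-inclusive variant can be toggled with `include_h`). A measure
#' of molecular extension/branching: path graphs maximise it at fixed atom
#' count, star graphs minimise it.
#'
#' @param mol a [molecule()].
#' @param include_h include explicit hydrogen atoms in the graph.
#' @param allow_disconnected if TRUE, sum within connected components
#'   instead of raising an error on a disconnected graph.
#' @return non-negative integer.
#' @export
wiener_path <- function(mol, include_h = FALSE, allow_disconnected = FALSE) {
  g <- if (include_h) mol_graph(mol) else heavy_atom_graph(mol)
  if (igraph::vcount(g) <= 1) return(0L)
  D <- igraph::distances(g)
  if (any(is.infinite(D))) {
    if (!allow_disconnected)
      stop("wiener_path: heavy-atom graph of '", mol$id,
           "' is disconnected (set allow_disconnected=TRUE to sum over components)")
    D[is.infinite(D)] <- 0
  }
  as.integer(round(sum(D) / 2))
}

# First and second Zagreb indices on the heavy-atom graph.
zagreb_indices <- function(mol) {
  g <- heavy_atom_graph(mol)
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g)
  m2 <- if (nrow(el) > 0) sum(deg[el[, 1]] * deg[el[, 2]]) else 0
  c(zagreb1 = sum(deg^2), zagreb2 = m2)
}

# Hydrogen-bond donor / acceptor counts: N or O carrying >=1 H donate;
# any N or O accepts. Simple Lipinski-style counting.
hbond_counts <- function(mol) {
  h <- implicit_h_counts(mol)
  expl_h <- vapply(seq_len(n_atoms(mol)), function(a) {
    nb <- c(mol$bonds$j[mol$bonds$i == a], mol$bonds$i[mol$bonds$j == a])
    sum(mol$elements[nb] == "H")
  }, 1L)
  no <- mol$elements %in% c("N", "O")
  c(hbd_count = sum(no & (h + expl_h) > 0), hba_count = sum(no))
}

#' Built-in descriptor block for one molecule
#' @param mol a [molecule()].
#' @return named numeric vector of the built-in descriptors.
#' @export
base_descriptors <- function(mol) {
  g <- heavy_atom_graph(mol)
  deg <- igraph::degree(g)
  ring_count <- igraph::ecount(g) - igraph::vcount(g) +
    igraph::components(g)$no
  c(n_heavy = n_heavy_atoms(mol),
    n_H = sum(implicit_h_counts(mol)) + sum(mol$elements == "H"),
    ring_count = ring_count,
    aromatic_ring_count = length(aromatic_rings(mol)),
    hbond_counts(mol),
    zagreb_indices(mol),
    wienerPath = wiener_path(mol),
    MW = molecular_weight(mol),
    branch_count = sum(deg >= 3))
}

# Deterministic LCG stream for pool padding coefficients; independent of
# the R RNG so padding is a pure function of the column index.
.lcg_stream <- function(seed, k) {
  x <- (as.numeric(seed) * 2654435761 + 97) %% 2147483647
  out <- numeric(k)
  for (q in seq_len(k)) {
    x <- (1103515245 * x + 12345) %% 2147483647
    out[q] <- x / 2147483647
  }
  out
}

#' Compute a descriptor vector with pool padding
#'
#' Computes the built-in descriptors and pads the vector to `pool_width`
#' columns with deterministic nonlinear transforms of the built-ins
#' (`pool_NNN`). The padding emulates the width of a full commercial
#' descriptor table so that descriptor-selection experiments search a
#' realistic space; pad columns carry real (correlated, redundant)
#' molecular signal, not noise. Failed descriptors are omitted with a
#' warning rather than propagating NaN.
#'
#' @param mol a [molecule()].
#' @param pool_width total descriptor count (default 336).
#' @param extra optional named list of functions `mol -> numeric` appended
#'   before padding.
#' @return named numeric vector of length `pool_width` (fewer if some
#'   descriptors failed).
#' @export
descriptor_pool <- function(mol, pool_width = 336L, extra = NULL) {
  vals <- base_descriptors(mol)
  if (!is.null(extra)) {
    for (nm in names(extra)) {
      v <- tryCatch(as.numeric(extra[[nm]](mol)), error = function(e) {
        warning("descriptor '", nm, "' failed for ", mol$id, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (!is.null(v) && is.finite(v)) vals[nm] <- v
    }
  }
  if (pool_width < length(vals))
    stop("pool_width ", pool_width, " smaller than built-in descriptor count ",
         length(vals))
  npad <- pool_width - length(vals)
  if (npad > 0) {
    base <- vals
    pads <- vapply(seq_len(npad), function(k) {
      u <- .lcg_stream(k, 4)
      a <- 1L + as.integer(u[1] * length(base)) %% length(base)
      b <- 1L + as.integer(u[2] * length(base)) %% length(base)
      tr <- 1L + as.integer(u[3] * 3) %% 3L
      x <- switch(tr, log1p(abs(base[[a]])), sqrt(abs(base[[a]])),
                  base[[a]]^2 / (1 + abs(base[[b]])))
      x * (0.5 + u[4]) + sqrt(abs(base[[b]]))
    }, 1.0)
    names(pads) <- sprintf("pool_%03d", seq_len(npad))
    vals <- c(vals, pads)
  }
  bad <- !is.finite(vals)
  if (any(bad)) {
    warning("dropping non-finite descriptor(s) for ", mol$id, ": ",
            paste(names(vals)[bad], collapse = ", "), call. = FALSE)
    vals <- vals[!bad]
  }
  vals
}

# --- descriptor tables -----------------------------------------------------

#' Assemble a descriptor table from per-compound vectors
#'
#' Rows are inner-joined on the descriptor-name set: only descriptors
#' present for every compound are kept, so the table never contains NA.
#'
#' @param vectors named list of named numeric vectors (names = compound ids).
#' @param response optional named numeric vector mapping compound id to the
#'   binding-energy score S (kcal/mol).
#' @return a `descriptor_table`: data.frame with `compound_id` first, one
#'   descriptor per column, and the response in attribute `"response"`.
#' @export
descriptor_table <- function(vectors, response = NULL) {
  stopifnot(length(vectors) > 0)
  common <- Reduce(intersect, lapply(vectors, names))
  if (length(common) == 0) stop("no descriptor shared by all compounds")
  mat <- t(vapply(vectors, function(v) v[common], numeric(length(common))))
  df <- data.frame(compound_id = names(vectors), mat,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   row.names = NULL)
  if (!is.null(response)) {
    miss <- setdiff(df$compound_id, names(response))
    if (length(miss) > 0)
      stop("response missing for compound(s): ", paste(miss, collapse = ", "))
    attr(df, "response") <- response[df$compound_id]
  }
  class(df) <- c("descriptor_table", "data.frame")
  df
}

#' Extract the response (binding-energy score) of a descriptor table
#' @param table a `descriptor_table`.
#' @return named numeric vector or NULL.
#' @export
response_of <- function(table) attr(table, "response")

#' Write a descriptor table to CSV at full float precision
#'
#' `compound_id` first column; the response, when present, is written as a
#' final column named `S`. Numbers are serialised with 17 significant
#' digits so the round-trip through [read_descriptor_table()] is lossless.
#'
#' @param table a `descriptor_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path) {
  df <- as.data.frame(table)
  resp <- response_of(table)
  if (!is.null(resp)) df$S <- as.numeric(resp)
  out <- df
  for (cn in names(out))
    if (is.numeric(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a descriptor table from CSV
#'
#' @param path CSV path (header row, `compound_id` first column).
#' @param response_col name of the response column, or NULL when no
#'   response is expected; an error lists any missing required columns.
#' @param required optional character vector of descriptor columns that
#'   must be present.
#' @return a `descriptor_table`.
#' @export
read_descriptor_table <- function(path, response_col = "S", required = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("compound_id", required,
            if (!is.null(response_col)) response_col)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("descriptor CSV is missing column(s): ", paste(miss, collapse = ", "))
  resp <- NULL
  if (!is.null(response_col)) {
    resp <- stats::setNames(as.numeric(df[[response_col]]), df$compound_id)
    df[[response_col]] <- NULL
  }
  for (cn in setdiff(names(df), "compound_id"))
    df[[cn]] <- as.numeric(df[[cn]])
  attr(df, "response") <- resp
  class(df) <- c("descriptor_table", "data.frame")
  df
}

# Numeric descriptor matrix (compound_id column dropped, ids as rownames).
descriptor_matrix <- function(table) {
  m <- as.matrix(as.data.frame(table)[, setdiff(names(table), "compound_id"),
                                      drop = FALSE])
  rownames(m) <- table$compound_id
  m
}
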