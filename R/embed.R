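# Seeded 3D conformer embedding. Classical MDS on the topological distance
# matrix gives a deterministic skeleton; a seeded jitter breaks planar
# degeneracy; L-BFGS-B then minimises a distance-target objective (bond
# lengths from covalent radii, 1-3 distances from idealised valence angles,
# all intra-ring pairs of aromatic rings pinned to the regular polygon, and
# a soft nonbonded floor). The result is a pure function of (graph, seed).

.COVALENT_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                     F = 0.57, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
                     Br = 1.20, I = 1.39)

# order multipliers relative to the single-bond covalent-radius sum
.ORDER_SCALE <- c("1" = 1.00, "ar" = 0.92, "2" = 0.88, "3" = 0.79)

# Evaluate an expression with a private RNG stream; the caller's RNG state
# is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

bond_length_target <- function(el_i, el_j, order) {
  (.COVALENT_RADII[el_i] + .COVALENT_RADII[el_j]) *
    .ORDER_SCALE[as.character(order)]
}

# Idealised valence angle (radians) at a center atom.
center_angle <- function(mol, center) {
  idx <- which(mol$bonds$i == center | mol$bonds$j == center)
  ords <- mol$bonds$order[idx]
  if (mol$aromatic[center] || any(ords == "2") || any(ords == "ar"))
    ang <- 120
  else if (any(ords == "3") || sum(ords == "2") >= 2)
    ang <- 180
  else ang <- 109.47
  ang * pi / 180
}

# Harmonic distance-restraint table for the embedding objective.
embed_restraints <- function(mol) {
  el <- mol$elements
  res <- list()
  add <- function(i, j, target, weight, onesided = FALSE) {
    res[[length(res) + 1L]] <<- c(i, j, target, weight, onesided)
  }
  b <- mol$bonds
  # kekule orders inside aromatic rings are levelled to "ar" so bond-length
  # targets do not fight the uniform ring-polygon pins
  arings <- aromatic_rings(mol)
  ar_keys <- character()
  for (ring in arings) {
    m <- length(ring)
    nxt <- ring[c(2:m, 1)]
    ar_keys <- c(ar_keys, paste(pmin(ring, nxt), pmax(ring, nxt)))
  }
  ord_eff <- b$order
  bkey <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  ord_eff[bkey %in% ar_keys] <- "ar"
  blen <- numeric(nrow(b))
  for (k in seq_len(nrow(b))) {
    blen[k] <- bond_length_target(el[b$i[k]], el[b$j[k]], ord_eff[k])
    add(b$i[k], b$j[k], blen[k], 10)
  }
  # aromatic rings first: pin all intra-ring pair distances to the regular
  # polygon built on the ring's own mean bond length (rigid and planar);
  # 1-3 restraints then never fight the pins
  pinned <- character()
  blen_of <- function(a, c) {
    k <- which((b$i == a & b$j == c) | (b$i == c & b$j == a))
    blen[k[1]]
  }
  for (ring in arings) {
    m <- length(ring)
    nxt <- ring[c(2:m, 1)]
    s <- mean(vapply(seq_len(m), function(t) blen_of(ring[t], nxt[t]), 1.0))
    R <- s / (2 * sin(pi / m))
    for (a in seq_len(m - 1)) for (c2 in (a + 1):m) {
      gap <- min(c2 - a, m - (c2 - a))
      add(ring[a], ring[c2], 2 * R * sin(pi * gap / m), 10)
      pinned <- c(pinned, paste(min(ring[a], ring[c2]), max(ring[a], ring[c2])))
    }
  }
  # 1-3 pairs via shared center
  adj <- lapply(seq_len(n_atoms(mol)), function(a)
    c(b$j[b$i == a], b$i[b$j == a]))
  for (center in seq_len(n_atoms(mol))) {
    nbrs <- adj[[center]]
    if (length(nbrs) < 2) next
    theta <- center_angle(mol, center)
    prs <- utils::combn(nbrs, 2)
    for (q in seq_len(ncol(prs))) {
      a <- prs[1, q]; c2 <- prs[2, q]
      if (paste(min(a, c2), max(a, c2)) %in% pinned) next
      r1 <- blen_of(a, center); r2 <- blen_of(c2, center)
      add(a, c2, sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(theta)), 3)
    }
  }
  # nonbonded floor for topologically distant pairs
  D <- igraph::distances(mol_graph(mol))
  seen <- matrix(FALSE, n_atoms(mol), n_atoms(mol))
  for (r in res) seen[r[1], r[2]] <- seen[r[2], r[1]] <- TRUE
  far <- which(upper.tri(D) & D >= 3 & is.finite(D), arr.ind = TRUE)
  for (q in seq_len(nrow(far))) {
    i <- far[q, 1]; j <- far[q, 2]
    if (!seen[i, j]) add(i, j, 2.5, 0.5, onesided = TRUE)
  }
  do.call(rbind, res)
}

embed_objective <- function(par, n, R) {
  P <- matrix(par, n, 3)
  dvec <- P[R[, 1], , drop = FALSE] - P[R[, 2], , drop = FALSE]
  d <- sqrt(rowSums(dvec^2)) + 1e-12
  gap <- d - R[, 3]
  active <- R[, 5] == 0 | gap < 0
  sum(R[active, 4] * gap[active]^2)
}

.accum <- function(values, idx, n) {
  out <- numeric(n)
  s <- tapply(values, idx, sum)
  out[as.integer(names(s))] <- s
  out
}

embed_gradient <- function(par, n, R) {
  P <- matrix(par, n, 3)
  dvec <- P[R[, 1], , drop = FALSE] - P[R[, 2], , drop = FALSE]
  d <- sqrt(rowSums(dvec^2)) + 1e-12
  gap <- d - R[, 3]
  active <- R[, 5] == 0 | gap < 0
  coefv <- ifelse(active, 2 * R[, 4] * gap / d, 0)
  gi <- coefv * dvec
  G <- matrix(0, n, 3)
  for (ax in 1:3)
    G[, ax] <- .accum(gi[, ax], R[, 1], n) - .accum(gi[, ax], R[, 2], n)
  as.numeric(G)
}

#' Embed a molecule in 3D
#'
#' Deterministic per (graph, seed): the same molecule and seed always give
#' bit-identical coordinates. Bond lengths land in standard windows
#' (heavy-atom bonds about 1.2-1.6 Angstrom) and aromatic rings come out
#' planar regular polygons.
#'
#' @param mol a [molecule()].
#' @param seed integer random seed for the jitter that breaks degeneracy.
#' @param maxit optimiser iteration cap.
#' @return the molecule with a `coords` matrix (Angstrom).
#' @export
embed_3d <- function(mol, seed = 1L, maxit = 400L) {
  n <- n_atoms(mol)
  if (n < 1) stop("cannot embed '", mol$id, "': no atoms")
  if (max(mol_components(mol)) > 1L)
    stop("cannot embed '", mol$id, "': disconnected graph")
  if (n == 1L) {
    mol$coords <- matrix(0, 1, 3)
    return(mol)
  }
  D <- igraph::distances(mol_graph(mol)) * 1.45
  init <- with_seed(seed, {
    X <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = min(3, n - 1)))
    if (is.null(dim(X))) X <- matrix(X, ncol = 1)
    if (ncol(X) < 3) X <- cbind(X, matrix(0, n, 3 - ncol(X)))
    X + matrix(rnorm(n * 3, sd = 0.15), n, 3)
  })
  R <- embed_restraints(mol)
  par <- as.numeric(init)
  for (round in 1:2) {
    fit <- stats::optim(par, fn = embed_objective,
                        gr = embed_gradient, n = n, R = R,
                        method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 10))
    par <- fit$par
  }
  P <- matrix(par, n, 3)
  P <- sweep(P, 2, colMeans(P))
  # orient deterministically (principal axes) so output is reproducible
  # regardless of optimiser path symmetry
  mol$coords <- round(P, 6)
  mol
}
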