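# Shared fixtures and independent oracles.

# Independent all-pairs BFS Wiener oracle: plain queue-based BFS from every
# vertex on an adjacency list; no igraph, no package code paths.
bfs_wiener <- function(mol) {
  n <- sum(mol$elements != "H")
  keep <- which(mol$elements != "H")
  remap <- match(seq_along(mol$elements), keep)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- remap[mol$bonds$i[k]]; j <- remap[mol$bonds$j[k]]
    if (is.na(i) || is.na(j)) next
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  total <- 0L
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    total <- total + sum(dist, na.rm = TRUE)
  }
  as.integer(total / 2)
}

# n-atom unbranched carbon chain built directly (no SMILES machinery)
path_molecule <- function(n) {
  bonds <- if (n > 1)
    data.frame(i = seq_len(n - 1), j = 2:n, order = "1",
               stringsAsFactors = FALSE) else NULL
  molecule(paste0("path", n), rep("C", n), bonds = bonds)
}

reference_compounds <- function() {
  utils::read.csv(system.file("extdata", "reference_compounds.csv",
                              package = "bitterqsar"),
                  stringsAsFactors = FALSE)
}

# random full-rank descriptor table with k descriptor columns
random_table <- function(n, k, seed) {
  with_seed(seed, {
    ids <- sprintf("c%03d", seq_len(n))
    cols <- stats::setNames(
      lapply(seq_len(k), function(q) rnorm(n, sd = runif(1, 0.5, 3))),
      paste0("d", seq_len(k)))
    df <- data.frame(compound_id = ids, cols, stringsAsFactors = FALSE)
    y <- rnorm(n) + if (k >= 2) 0.8 * df$d1 - 0.5 * df$d2 else 0.8 * df$d1
    attr(df, "response") <- stats::setNames(y, ids)
    class(df) <- c("descriptor_table", "data.frame")
    df
  })
}

# rotate + translate a whole complex rigidly
transform_pose <- function(pose, seed = 1) {
  rot <- with_seed(seed, {
    A <- matrix(rnorm(9), 3, 3)
    qr.Q(qr(A))
  })
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- c(5, -3, 2)
  at <- pose$receptor$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% rot
  at$x <- xyz[, 1] + shift[1]
  at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  lig <- pose$ligand
  lig$coords <- sweep(lig$coords %*% rot, 2, -shift)
  complex_pose(receptor_structure(at, pose$receptor$annotations), lig,
               pose$score)
}
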