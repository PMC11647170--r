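# Synthetic study-condition generators. The descriptor-table generator
# plants the published two-descriptor linear relationship as generative
# truth inside a wide decoy pool, at sample size and fit quality matching
# the study (490 compounds, population R^2 about 0.93); the molecular-graph
# and toy-complex generators provide exactly solvable fixtures for the
# Wiener and interaction-typing machinery. All generators are pure
# functions of their seed.

#' Specification for a planted-model descriptor table
#'
#' Defaults reproduce the study conditions: 490 compounds, a 336-column
#' pool, planted coefficients equal to the published model's constants,
#' interaction-surface values uniform on 150-1500 Angstrom^2, Wiener path
#' numbers log-uniform on 50-60000 (the dynamic range implied by the
#' compound-size span of the ranking table, 94-2806 g/mol), and Gaussian
#' noise sized so the population R^2 is `target_r2` (0.93, echoing the
#' reported fit quality). Give `noise_sd` to override the noise directly.
#'
#' @param n number of compounds.
#' @param pool_width total descriptor columns.
#' @param intercept planted intercept, kcal/mol.
#' @param coefficients named planted coefficients.
#' @param vsurf_range uniform range for the surface descriptor.
#' @param wiener_range log-uniform integer range for the Wiener descriptor.
#' @param target_r2 population R^2 the noise is sized for.
#' @param noise_sd explicit noise standard deviation (kcal/mol); overrides
#'   `target_r2` when non-NULL.
#' @param seed integer seed.
#' @return object of class `planted_model_spec`.
#' @export
planted_model_spec <- function(n = 490L, pool_width = 336L,
                               intercept = -1.26777,
                               coefficients = c(vsurf_S = -0.01161,
                                                wienerPath = 0.00007),
                               vsurf_range = c(150, 1500),
                               wiener_range = c(50, 60000),
                               target_r2 = 0.93, noise_sd = NULL,
                               seed = 1L) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop("planted coefficients must be named")
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n = as.integer(n), pool_width = as.integer(pool_width),
                 intercept = intercept, coefficients = coefficients,
                 vsurf_range = vsurf_range, wiener_range = wiener_range,
                 target_r2 = target_r2, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "planted_model_spec")
}

# analytic signal variance of the planted part (independent columns)
planted_signal_var <- function(spec) {
  v <- 0
  for (nm in names(spec$coefficients)) {
    cf <- spec$coefficients[[nm]]
    if (nm == "vsurf_S") {
      w <- diff(spec$vsurf_range)
      v <- v + cf^2 * w^2 / 12
    } else if (nm == "wienerPath") {
      a <- spec$wiener_range[1]; b <- spec$wiener_range[2]
      lw <- log(b / a)
      m1 <- (b - a) / lw
      m2 <- (b^2 - a^2) / (2 * lw)
      v <- v + cf^2 * (m2 - m1^2)
    } else {
      v <- v + cf^2  # custom planted columns are standard normal
    }
  }
  v
}

#' Noise standard deviation implied by a planted-model specification
#' @param spec a [planted_model_spec()].
#' @return numeric, kcal/mol.
#' @export
implied_noise_sd <- function(spec) {
  if (!is.null(spec$noise_sd)) return(spec$noise_sd)
  sv <- planted_signal_var(spec)
  sqrt(sv * (1 - spec$target_r2) / spec$target_r2)
}

#' Generate a descriptor table with a planted linear model
#'
#' Signal columns are drawn from the spec's distributions; the response is
#' the planted linear combination plus Gaussian noise; all remaining
#' columns are decoys drawn independently of the response (mixed uniform,
#' normal and log-normal shapes on varying scales). Deterministic per seed.
#'
#' @param spec a [planted_model_spec()].
#' @return a `descriptor_table` (response attached) whose attribute
#'   `"truth"` records the planted intercept, coefficients and noise sd.
#' @export
gen_descriptor_table <- function(spec = planted_model_spec()) {
  nm <- names(spec$coefficients)
  if (spec$pool_width < length(nm))
    stop("pool_width smaller than the number of planted descriptors")
  sd_noise <- implied_noise_sd(spec)
  with_seed(spec$seed, {
    n <- spec$n
    cols <- list()
    for (d in nm) {
      cols[[d]] <- if (d == "vsurf_S")
        runif(n, spec$vsurf_range[1], spec$vsurf_range[2])
      else if (d == "wienerPath")
        round(exp(runif(n, log(spec$wiener_range[1]),
                        log(spec$wiener_range[2]))))
      else rnorm(n)
    }
    ndecoy <- spec$pool_width - length(nm)
    for (q in seq_len(ndecoy)) {
      shape <- sample(3, 1)
      scale <- exp(runif(1, -1, 4))
      cols[[sprintf("pool_%03d", q)]] <- switch(shape,
        runif(n, 0, scale),
        rnorm(n, sd = scale),
        exp(rnorm(n, sd = 1)) * scale)
    }
    S <- spec$intercept + rnorm(n, sd = sd_noise)
    for (d in nm) S <- S + spec$coefficients[[d]] * cols[[d]]
    ids <- sprintf("cmpd_%04d", seq_len(n))
    df <- data.frame(compound_id = ids, cols, check.names = FALSE,
                     stringsAsFactors = FALSE)
    attr(df, "response") <- stats::setNames(S, ids)
    attr(df, "truth") <- list(intercept = spec$intercept,
                              coefficients = spec$coefficients,
                              noise_sd = sd_noise)
    class(df) <- c("descriptor_table", "data.frame")
    df
  })
}

#' Generate a random connected valence-legal molecular graph
#'
#' A random tree grown atom by atom (each new atom attaches to the
#' previous atom, or with probability `branch_prob` to a random earlier
#' atom with free valence), optionally closed into rings. Elements are
#' assigned degree-compatibly (C everywhere it is needed, N/O sprinkled on
#' low-degree positions); all bonds are single, so the graph is always
#' valence-legal. `branch_prob = 0` with no ring closures gives the path
#' graph.
#'
#' @param n_atoms number of heavy atoms (>= 1).
#' @param branch_prob probability a new atom attaches off-path.
#' @param ring_prob probability of attempting one ring closure per excess
#'   atom pair (default 0).
#' @param seed integer seed.
#' @return a [molecule()] without coordinates.
#' @export
gen_random_molgraph <- function(n_atoms, branch_prob = 0, ring_prob = 0,
                                seed = 1L) {
  stopifnot(n_atoms >= 1)
  with_seed(seed, {
    deg <- integer(n_atoms)
    bonds <- NULL
    if (n_atoms > 1) {
      parents <- integer(n_atoms - 1L)
      for (k in 2:n_atoms) {
        parent <- k - 1L
        if (branch_prob > 0 && k > 2 && runif(1) < branch_prob) {
          free <- which(deg[seq_len(k - 1L)] < 3L)
          if (length(free) > 0)
            parent <- free[sample.int(length(free), 1L)]
        }
        parents[k - 1L] <- parent
        deg[parent] <- deg[parent] + 1L
        deg[k] <- deg[k] + 1L
      }
      bonds <- data.frame(i = parents, j = 2:n_atoms, order = "1",
                          stringsAsFactors = FALSE)
      if (ring_prob > 0 && n_atoms >= 4) {
        key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
        n_try <- stats::rbinom(1, n_atoms, ring_prob)
        for (t in seq_len(n_try)) {
          cand <- which(deg < 3L)
          if (length(cand) < 2) break
          pick <- sample(cand, 2)
          kk <- paste(min(pick), max(pick))
          if (kk %in% key) next
          bonds <- rbind(bonds, data.frame(i = pick[1], j = pick[2],
                                           order = "1"))
          key <- c(key, kk)
          deg[pick] <- deg[pick] + 1L
        }
      }
    }
    elements <- rep("C", n_atoms)
    low <- which(deg <= 2L)
    if (length(low) > 0) {
      pickN <- runif(length(low))
      elements[low[pickN < 0.15]] <- "N"
      elements[low[pickN > 0.85 & deg[low] <= 1L]] <- "O"
    }
    molecule(sprintf("randmol_s%d_n%d", seed, n_atoms), elements,
             bonds = bonds)
  })
}

# --- toy receptor-ligand complexes ----------------------------------------

.res_template <- function(resname, resno, atoms_xyz) {
  df <- data.frame(serial = seq_len(nrow(atoms_xyz)),
                   name = rownames(atoms_xyz), resname = resname,
                   chain = "A", resno = resno,
                   element = substr(rownames(atoms_xyz), 1, 1),
                   x = atoms_xyz[, 1], y = atoms_xyz[, 2],
                   z = atoms_xyz[, 3],
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

.hexagon <- function(radius = 1.39, z = 0) {
  th <- (90 - 60 * (0:5)) * pi / 180
  cbind(radius * cos(th), radius * sin(th), z)
}

#' Generate a toy receptor-ligand complex with a prescribed contact
#'
#' Minimal one-residue receptors with correctly named atoms, and a ligand
#' placed to satisfy (or, for `"none"`, violate) the corresponding
#' detection rule:
#' * `salt_bridge` - glutamate-like residue (numbered 265) and a
#'   methylammonium ligand with an in-line N-H 2.9 A from OE1: designed
#'   records are one H-Donor plus one Ionic, the classic glutamate
#'   pattern.
#' * `hbond` - backbone carbonyl acceptor (glycine, 180) and a methanol
#'   donor at 2.9 A: one H-Donor.
#' * `pi_stack` - phenylalanine ring (252) with a parallel benzene 3.6 A
#'   above it: one pi-pi.
#' * `ch_pi` - tryptophan indole (88) with methane 3.8 A above the
#'   six-membered ring face: one H-pi.
#' * `none` - glycine with methane 12 A away: no records.
#'
#' @param kind one of `"salt_bridge"`, `"hbond"`, `"pi_stack"`, `"ch_pi"`,
#'   `"none"`.
#' @param jitter Gaussian positional noise (A) added to the ligand atoms.
#' @param seed seed for the jitter.
#' @param dir optional directory; when given, `receptor.pdb` and
#'   `ligand.sdf` are written there.
#' @return a [complex_pose()]; the designed record kinds are in attribute
#'   `"designed_kinds"`.
#' @export
gen_toy_complex <- function(kind = c("salt_bridge", "hbond", "pi_stack",
                                     "ch_pi", "none"),
                            jitter = 0, seed = 1L, dir = NULL) {
  kind <- match.arg(kind)
  if (kind == "salt_bridge") {
    rec_xyz <- rbind(N = c(-4.9, -1.0, 0), CA = c(-4.0, 0.1, 0),
                     C = c(-4.6, 1.5, 0), O = c(-5.8, 1.7, 0),
                     CB = c(-2.6, -0.4, 0), CG = c(-1.5, 0.6, 0),
                     CD = c(0, 0, 0),
                     OE1 = c(0.567, 1.114, 0), OE2 = c(0.567, -1.114, 0))
    res <- .res_template("GLU", 265L, rec_xyz)
    u <- c(0.4536, 0.8912, 0)  # CD -> OE1 direction
    Npos <- rec_xyz["OE1", ] + 2.9 * u
    lig <- molecule("lig_ammonium", c("N", "C", "H", "H", "H"),
                    charges = c(1L, 0L, 0L, 0L, 0L),
                    bonds = data.frame(i = c(1, 1, 1, 1), j = c(2, 3, 4, 5),
                                       order = "1"),
                    coords = rbind(Npos, Npos + 1.5 * u,
                                   Npos - 1.0 * u,
                                   Npos + c(0.95, -0.2, 0.45),
                                   Npos + c(-0.2, 0.45, -0.95)))
    designed <- c("H-Donor", "Ionic")
  } else if (kind == "hbond") {
    rec_xyz <- rbind(N = c(-3.6, 0.2, 0), CA = c(-2.4, 1.0, 0),
                     C = c(-1.23, 0, 0), O = c(0, 0, 0))
    res <- .res_template("GLY", 180L, rec_xyz)
    lig <- molecule("lig_methanol", c("O", "C", "H"),
                    bonds = data.frame(i = c(1, 1), j = c(2, 3), order = "1"),
                    coords = rbind(c(2.9, 0.4, 0), c(3.9, 1.4, 0.3),
                                   c(1.95, 0.27, 0)))
    designed <- "H-Donor"
  } else if (kind == "pi_stack") {
    ring <- .hexagon()
    rownames(ring) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    rec_xyz <- rbind(ring,
                     CB = c(0, 2.9, 0), CA = c(0.2, 4.4, 0),
                     N = c(1.5, 5.0, 0), C = c(-1.0, 5.3, 0),
                     O = c(-2.2, 5.0, 0))
    res <- .res_template("PHE", 252L, rec_xyz)
    lring <- .hexagon(z = 3.6)
    lig <- molecule("lig_benzene", rep("C", 6),
                    aromatic = rep(TRUE, 6),
                    bonds = data.frame(i = 1:6, j = c(2:6, 1), order = "ar"),
                    coords = lring)
    designed <- "pi-pi"
  } else if (kind == "ch_pi") {
    hexa <- .hexagon()
    rownames(hexa) <- c("CE2", "CZ2", "CH2", "CZ3", "CE3", "CD2")
    five <- rbind(CG = c(-2.25, 0.37, 0), CD1 = c(-2.93, 1.57, 0),
                  NE1 = c(-2.17, 2.72, 0))
    rec_xyz <- rbind(hexa, five,
                     CB = c(-2.95, -0.9, 0), CA = c(-4.4, -0.7, 0),
                     N = c(-5.1, -2.0, 0), C = c(-5.0, 0.5, 0),
                     O = c(-6.2, 0.7, 0))
    res <- .res_template("TRP", 88L, rec_xyz)
    lig <- molecule("lig_methane", "C",
                    coords = matrix(c(0.8, -0.5, 3.8), 1, 3))
    designed <- "H-pi"
  } else {
    rec_xyz <- rbind(N = c(-3.6, 0.2, 0), CA = c(-2.4, 1.0, 0),
                     C = c(-1.23, 0, 0), O = c(0, 0, 0))
    res <- .res_template("GLY", 1L, rec_xyz)
    lig <- molecule("lig_far", "C", coords = matrix(c(12, 0, 0), 1, 3))
    designed <- character(0)
  }
  if (jitter > 0)
    lig$coords <- lig$coords +
      with_seed(seed, matrix(rnorm(length(lig$coords), sd = jitter),
                             nrow(lig$coords), 3))
  receptor <- receptor_structure(res)
  pose <- complex_pose(receptor, lig)
  attr(pose, "designed_kinds") <- designed
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_pdb(receptor, file.path(dir, "receptor.pdb"))
    write_sdf(lig, file.path(dir, "ligand.sdf"))
  }
  pose
}
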