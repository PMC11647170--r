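# Geometric typing of receptor-ligand contacts. Kinds use the vocabulary
# of the reference interaction tables: H-Donor / H-Acceptor (named from the
# ligand's role), Ionic (salt bridge), H-pi (ligand C-H into a receptor
# ring), pi-H (receptor C-H into a ligand ring) and pi-pi (parallel
# stacking). Typing is purely geometric: records carry distances, never
# energies (externally supplied pose energies pass through untouched).

#' Default interaction-typing thresholds
#'
#' Distances in Angstrom, angles in degrees. Defaults accept every contact
#' distance printed in the reference tables (hydrogen bonds to 3.5, salt
#' bridges to 4.0, CH-pi to 4.5, ring stacking to 5.5).
#'
#' @return named list of thresholds.
#' @export
interaction_thresholds <- function() {
  list(hbond_dist = 3.5, hbond_angle = 120,
       ionic_dist = 4.0,
       pipi_dist = 5.5, pipi_angle = 30,
       hpi_dist = 4.5, hpi_elev = 45,
       consider_dist = 8.0)
}

# side-chain feature definitions by residue name
.RES_DONORS <- list(SER = "OG", THR = "OG1", TYR = "OH", TRP = "NE1",
                    LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                    HIS = c("ND1", "NE2"), ASN = "ND2", GLN = "NE2")
.RES_ACCEPTORS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                       SER = "OG", THR = "OG1", TYR = "OH",
                       ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"))
.RES_CHARGE <- list(GLU = list(atoms = c("OE1", "OE2"), sign = -1),
                    ASP = list(atoms = c("OD1", "OD2"), sign = -1),
                    LYS = list(atoms = "NZ", sign = +1),
                    ARG = list(atoms = c("NH1", "NH2", "CZ"), sign = +1))
.RES_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))
# backbone / sp2 carbons that are not CH-pi donors
.NON_CH_CARBONS <- c("C", "CG.ASP", "CG.ASN", "CD.GLU", "CD.GLN", "CZ.ARG")

.angle_deg <- function(v1, v2) {
  cosv <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
}

ring_geometry <- function(coords) {
  centroid <- colMeans(coords)
  sv <- svd(sweep(coords, 2, centroid))
  list(centroid = centroid, normal = sv$v[, 3])
}

# elevation of point p above the ring plane, degrees; side-agnostic (the
# SVD normal's sign is arbitrary)
.elevation_deg <- function(p, ring) {
  v <- p - ring$centroid
  abs(90 - .angle_deg(v, ring$normal))
}

residue_key <- function(resname, resno) paste0(resname, resno)

#' Detect and type receptor-ligand interactions in a pose
#'
#' Applies, in order: hydrogen bonds (donor-to-acceptor heavy-atom
#' distance, donor-H-acceptor angle where an explicit H is placeable),
#' salt bridges between opposite charge-group centers, pi-pi stacking
#' (ring centroid distance and inter-plane angle) and CH-pi contacts
#' (carbon carrier to ring centroid with an elevation-angle gate). Only
#' receptor residues with an atom within `thresholds$consider_dist` of the
#' ligand are examined. A residue pair may legitimately yield both an
#' H-Donor and an Ionic record (the classic glutamate salt-bridge
#' pattern). Residues lacking the atoms a group definition needs are
#' skipped with a warning.
#'
#' @param pose a [complex_pose()].
#' @param thresholds see [interaction_thresholds()].
#' @return data.frame with columns `compound_id`, `chain`, `resno`,
#'   `resname`, `generic_label`, `kind`, `distance_A`, `lig_part`,
#'   `rec_part`.
#' @export
detect_interactions <- function(pose, thresholds = interaction_thresholds()) {
  th <- utils::modifyList(interaction_thresholds(), thresholds)
  lig <- pose$ligand
  rec <- pose$receptor
  lxyz <- lig$coords
  out <- list()
  emit <- function(chain, resno, resname, kind, dist, lig_part, rec_part) {
    lab <- NA_character_
    if (!is.null(rec$annotations)) {
      key <- paste0(chain, ":", resno)
      if (key %in% names(rec$annotations)) lab <- rec$annotations[[key]]
    }
    out[[length(out) + 1L]] <<- data.frame(
      compound_id = lig$id, chain = chain, resno = resno, resname = resname,
      generic_label = lab, kind = kind, distance_A = dist,
      lig_part = lig_part, rec_part = rec_part, stringsAsFactors = FALSE)
  }

  # ligand features
  nh <- implicit_h_counts(lig)
  expl_h_of <- function(a) {
    nb <- c(lig$bonds$j[lig$bonds$i == a], lig$bonds$i[lig$bonds$j == a])
    nb[lig$elements[nb] == "H"]
  }
  h_count <- nh + vapply(seq_len(n_atoms(lig)), function(a)
    length(expl_h_of(a)), 1L)
  lig_heavy <- which(lig$elements != "H")
  lig_donors <- lig_heavy[lig$elements[lig_heavy] %in% c("N", "O") &
                            h_count[lig_heavy] > 0]
  lig_acceptors <- lig_heavy[lig$elements[lig_heavy] %in% c("N", "O") &
                               !(lig$elements[lig_heavy] == "N" &
                                   lig$charges[lig_heavy] > 0)]
  # CH-pi carriers: carbons with >=1 H, excluding aromatic carbons (their
  # C-H lies in the ring plane and cannot point at a stacked ring face;
  # stacked aromatic pairs are typed pi-pi instead)
  lig_ch <- lig_heavy[lig$elements[lig_heavy] == "C" & h_count[lig_heavy] > 0 &
                        !lig$aromatic[lig_heavy]]
  # ligand charge-group centers
  lig_charge <- list()
  pos_atoms <- which(lig$charges > 0)
  for (a in pos_atoms)
    lig_charge[[length(lig_charge) + 1L]] <-
      list(center = lxyz[a, ], sign = +1, part = paste0("atom", a))
  neg_o <- which(lig$charges < 0 & lig$elements == "O")
  used <- logical(n_atoms(lig))
  for (a in neg_o) {
    if (used[a]) next
    nb <- c(lig$bonds$j[lig$bonds$i == a], lig$bonds$i[lig$bonds$j == a])
    cc <- nb[lig$elements[nb] == "C"][1]
    grp <- a
    if (!is.na(cc)) {
      onb <- c(lig$bonds$j[lig$bonds$i == cc], lig$bonds$i[lig$bonds$j == cc])
      grp <- onb[lig$elements[onb] == "O"]
      if (length(grp) == 0) grp <- a
    }
    used[grp] <- TRUE
    lig_charge[[length(lig_charge) + 1L]] <-
      list(center = if (length(grp) > 1) colMeans(lxyz[grp, , drop = FALSE])
           else lxyz[grp, ],
           sign = -1, part = paste0("atom", paste(grp, collapse = "+")))
  }
  lig_rings <- lapply(aromatic_rings(lig), function(r)
    c(ring_geometry(lxyz[r, , drop = FALSE]),
      list(part = paste0("ring:", paste(r, collapse = ",")))))

  # candidate residues within the consideration shell
  at <- rec$atoms
  rxyz <- as.matrix(at[, c("x", "y", "z")])
  mind <- vapply(seq_len(nrow(at)), function(k)
    min(sqrt(colSums((t(lxyz) - rxyz[k, ])^2))), 1.0)
  at$._mind <- mind
  resdf <- unique(at[, c("chain", "resno", "resname")])
  for (rr in seq_len(nrow(resdf))) {
    sel <- at$chain == resdf$chain[rr] & at$resno == resdf$resno[rr]
    if (min(at$._mind[sel]) > th$consider_dist) next
    res <- at[sel, , drop = FALSE]
    rname <- resdf$resname[rr]
    rnum <- resdf$resno[rr]
    rchain <- resdf$chain[rr]
    coords_of <- function(names_) {
      idx <- match(names_, res$name)
      if (any(is.na(idx))) return(NULL)
      as.matrix(res[idx, c("x", "y", "z"), drop = FALSE])
    }
    # hydrogen bonds: ligand donor -> receptor acceptor
    acc_names <- c(if (!is.null(.RES_ACCEPTORS[[rname]])) .RES_ACCEPTORS[[rname]],
                   "O")
    for (an in acc_names) {
      axyz <- coords_of(an)
      if (is.null(axyz)) next
      for (d in lig_donors) {
        dist <- sqrt(sum((lxyz[d, ] - axyz[1, ])^2))
        if (dist > th$hbond_dist) next
        hs <- expl_h_of(d)
        if (length(hs) > 0) {
          best <- max(vapply(hs, function(h)
            .angle_deg(lxyz[d, ] - lxyz[h, ], axyz[1, ] - lxyz[h, ]), 1.0))
          if (best < th$hbond_angle) next
        }
        emit(rchain, rnum, rname, "H-Donor", dist,
             paste0("atom", d), an)
      }
    }
    # hydrogen bonds: receptor donor -> ligand acceptor (H not placeable)
    don_names <- c(if (!is.null(.RES_DONORS[[rname]])) .RES_DONORS[[rname]],
                   "N")
    for (dn in don_names) {
      dxyz <- coords_of(dn)
      if (is.null(dxyz)) next
      for (a in lig_acceptors) {
        dist <- sqrt(sum((lxyz[a, ] - dxyz[1, ])^2))
        if (dist <= th$hbond_dist)
          emit(rchain, rnum, rname, "H-Acceptor", dist,
               paste0("atom", a), dn)
      }
    }
    # salt bridges
    cg <- .RES_CHARGE[[rname]]
    if (!is.null(cg) && length(lig_charge) > 0) {
      gxyz <- coords_of(cg$atoms)
      if (is.null(gxyz)) {
        warning("residue ", rname, rnum, " lacks atoms ",
                paste(cg$atoms, collapse = "/"), "; skipped", call. = FALSE)
      } else {
        center <- colMeans(gxyz)
        for (lc in lig_charge) {
          if (lc$sign * cg$sign >= 0) next
          dist <- sqrt(sum((lc$center - center)^2))
          if (dist <= th$ionic_dist)
            emit(rchain, rnum, rname, "Ionic", dist, lc$part,
                 paste(cg$atoms, collapse = "+"))
        }
      }
    }
    # rings: pi-pi and CH-pi both ways
    rring_defs <- .RES_RINGS[[rname]]
    rrings <- list()
    if (!is.null(rring_defs)) {
      for (q in seq_along(rring_defs)) {
        rxyz_ring <- coords_of(rring_defs[[q]])
        if (is.null(rxyz_ring)) {
          warning("residue ", rname, rnum, " lacks ring atoms; skipped",
                  call. = FALSE)
          next
        }
        rrings[[length(rrings) + 1L]] <-
          c(ring_geometry(rxyz_ring),
            list(part = paste0("ring:", paste(rring_defs[[q]], collapse = ","))))
      }
    }
    for (rg in rrings) {
      for (lr in lig_rings) {
        dist <- sqrt(sum((rg$centroid - lr$centroid)^2))
        ang <- .angle_deg(rg$normal, lr$normal)
        ang <- min(ang, 180 - ang)
        if (dist <= th$pipi_dist && ang <= th$pipi_angle)
          emit(rchain, rnum, rname, "pi-pi", dist, lr$part, rg$part)
      }
      for (d in lig_ch) {
        dist <- sqrt(sum((lxyz[d, ] - rg$centroid)^2))
        if (dist <= th$hpi_dist &&
            .elevation_deg(lxyz[d, ], rg) >= th$hpi_elev)
          emit(rchain, rnum, rname, "H-pi", dist, paste0("atom", d), rg$part)
      }
    }
    if (length(lig_rings) > 0) {
      ring_atom_names <- unlist(.RES_RINGS[[rname]])
      ch_atoms <- which(res$element == "C" &
                          !(res$name %in% c("C", ring_atom_names)) &
                          !(paste0(res$name, ".", rname) %in% .NON_CH_CARBONS))
      for (k in ch_atoms) {
        p <- as.numeric(res[k, c("x", "y", "z")])
        for (lr in lig_rings) {
          dist <- sqrt(sum((p - lr$centroid)^2))
          if (dist <= th$hpi_dist && .elevation_deg(p, lr) >= th$hpi_elev)
            emit(rchain, rnum, rname, "pi-H", dist, lr$part, res$name[k])
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(compound_id = character(), chain = character(),
                      resno = integer(), resname = character(),
                      generic_label = character(), kind = character(),
                      distance_A = numeric(), lig_part = character(),
                      rec_part = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Select the lowest-energy pose per compound
#'
#' @param poses list of [complex_pose()] objects (each must carry a score);
#'   poses of the same compound share `ligand$id`.
#' @return named list, one pose per compound (minimum score; ties keep the
#'   earliest pose in input order, with a message). Compounds with no
#'   scored pose are excluded with a warning.
#' @export
lowest_energy_selection <- function(poses) {
  ids <- vapply(poses, function(p) p$ligand$id, "")
  out <- list()
  for (id in unique(ids)) {
    grp <- poses[ids == id]
    scores <- vapply(grp, function(p)
      if (is.null(p$score)) NA_real_ else p$score, 1.0)
    if (all(is.na(scores))) {
      warning("compound '", id, "' has no scored pose; excluded",
              call. = FALSE)
      next
    }
    best <- which.min(scores)  # which.min takes the first minimum
    if (sum(scores == scores[best], na.rm = TRUE) > 1)
      message("compound '", id, "': tied scores, keeping the first pose")
    out[[id]] <- grp[[best]]
  }
  out
}

#' Per-residue population map of interaction records
#'
#' Counts records per residue over all compounds and reports each
#' residue's share of all typed contacts as a percentage rounded to one
#' decimal (e.g. 250 of 453 records at one glutamate = 55.2%).
#'
#' @param records a records data.frame from [detect_interactions()] (rows
#'   from several compounds may be concatenated).
#' @return object of class `population_map`: list with `counts`, `total`
#'   and `percentages` (named by `resname+resno`, e.g. `"GLU265"`).
#' @export
population_map <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    return(structure(list(counts = integer(0), total = 0L,
                          percentages = numeric(0)),
                     class = "population_map"))
  key <- residue_key(records$resname, records$resno)
  counts <- sort(table(key), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  structure(list(counts = counts, total = total,
                 percentages = round(100 * counts / total, 1)),
            class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  cat("<population_map:", x$total, "records>\n")
  for (k in names(x$counts))
    cat(sprintf("  %-8s %4d/%d; %.1f%%\n", k, x$counts[[k]], x$total,
                x$percentages[[k]]))
  invisible(x)
}

#' Arene-interaction summary table
#'
#' Per compound and residue of interest: `"R"` when any arene contact
#' (H-pi, pi-H or pi-pi) is present, `"-"` otherwise, following the
#' methoxyflavonoid summary-table convention. Polar contacts (H-Donor,
#' H-Acceptor, Ionic) are flagged in separate `<residue>_polar` columns.
#'
#' @param records concatenated records data.frame.
#' @param residues character vector of residue keys (`"GLU265"` style).
#' @param compounds optional compound ids to report (default those in
#'   `records`).
#' @return data.frame, one row per compound.
#' @export
arene_vs_polar_summary <- function(records, residues,
                                   compounds = NULL) {
  arene_kinds <- c("H-pi", "pi-H", "pi-pi")
  polar_kinds <- c("H-Donor", "H-Acceptor", "Ionic")
  if (is.null(compounds)) compounds <- unique(records$compound_id)
  key <- if (nrow(records) > 0)
    residue_key(records$resname, records$resno) else character(0)
  rows <- lapply(compounds, function(cid) {
    rec_c <- records[records$compound_id == cid, , drop = FALSE]
    key_c <- if (nrow(rec_c) > 0)
      residue_key(rec_c$resname, rec_c$resno) else character(0)
    vals <- vapply(residues, function(rk)
      if (any(key_c == rk & rec_c$kind %in% arene_kinds)) "R" else "-", "")
    pol <- vapply(residues, function(rk)
      any(key_c == rk & rec_c$kind %in% polar_kinds), TRUE)
    df <- data.frame(compound_id = cid, stringsAsFactors = FALSE)
    for (q in seq_along(residues)) {
      df[[residues[q]]] <- vals[q]
      df[[paste0(residues[q], "_polar")]] <- pol[q]
    }
    df
  })
  do.call(rbind, rows)
}
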