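# Geometric interaction fingerprinting: hydrogen bonds, pi-stacking, and
# electrophile/nucleophile proximities, with an empirical per-bond energy.

#' Empirical hydrogen-bond energy
#'
#' A 12-10 radial profile with optimum at `d_opt` (donor--acceptor
#' distance), an angular factor that vanishes at the detection boundary
#' (`cos^2` scaled to reach zero at `angle_min`), and a smooth distance
#' taper to zero at the detection cutoff. At ideal geometry (2.8 A, 180 deg)
#' the energy is exactly `-e0`; it is never positive and weakens
#' monotonically as geometry degrades.
#'
#' @param d_da Donor--acceptor distance (A).
#' @param angle Donor--hydrogen--acceptor angle (degrees).
#' @param e0 Well depth (kcal/mol), default 5.
#' @param d_opt Optimal donor--acceptor distance (A), default 2.8.
#' @param d_cut Detection cutoff (A), default 3.5; taper begins at
#'   `taper_start`.
#' @param angle_min Detection angle boundary (degrees), default 120.
#' @param taper_start Start of the distance taper (A), default 3.2.
#' @return Energy in kcal/mol (<= 0).
#' @export
hbond_energy <- function(d_da, angle, e0 = 5.0, d_opt = 2.8, d_cut = 3.5,
                         angle_min = 120, taper_start = 3.2) {
  x <- d_opt / d_da
  radial <- pmax(-(5 * x^12 - 6 * x^10), 0)
  dev <- 180 - angle
  span <- 180 - angle_min
  ang <- ifelse(angle < angle_min, 0, cos(pi / 2 * dev / span)^2)
  taper <- .switch_fn(d_da, taper_start, d_cut)
  -e0 * radial * ang * taper
}

# ring atom-name templates for receptor aromatic residues
.receptor_rings <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)

.ring_plane <- function(X) {
  cen <- colMeans(X)
  sv <- svd(sweep(X, 2, cen))
  list(centroid = cen, normal = sv$v[, 3],
       rms = sqrt(mean((sweep(X, 2, cen) %*% sv$v[, 3])^2)))
}

#' Detect protein--ligand interactions
#'
#' Geometric detection with PLIP-like conventions: a hydrogen bond requires
#' donor--acceptor distance of at most `hb_dist` and a D-H...A angle of at
#' least `hb_angle`; a pi-stack requires ring-centroid distance of at most
#' `stack_dist` and an interplane angle of at most 30 degrees (parallel) or
#' between 60 and 90 degrees (T-shaped); a reactive proximity is flagged
#' when a Michael-acceptor beta-carbon of the ligand lies within
#' `reactive_dist` of a catalytic Ser/Cys nucleophile. The per-bond
#' empirical energy and its classification against the existence threshold
#' (bonds weaker than `exist_threshold` are labelled as not energetically
#' real) are included in the report.
#'
#' @param receptor A protonated `gridock_receptor`.
#' @param ligand_coords Ligand coordinates (A), ordered as in `topology`.
#' @param topology The ligand `gridock_ligand` (supplies bonds, rings,
#'   elements).
#' @param hb_dist,hb_angle H-bond detection cutoffs (A, degrees).
#' @param stack_dist Pi-stack centroid cutoff (A).
#' @param reactive_dist Electrophile--nucleophile cutoff (A).
#' @param exist_threshold Energy (kcal/mol) below which an H-bond counts as
#'   energetically real; default -1.0.
#' @return A `gridock_interactions` object holding tibbles `hbonds`,
#'   `pi_stacks` and `reactive`.
#' @export
detect_interactions <- function(receptor, ligand_coords, topology,
                                hb_dist = 3.5, hb_angle = 120,
                                stack_dist = 5.5, reactive_dist = 4.0,
                                exist_threshold = -1.0) {
  L <- as.matrix(ligand_coords)
  ra <- receptor$atoms
  R <- receptor_coords(receptor)
  log <- character(0)

  # donors/acceptors on the receptor
  rec_H <- which(ra$element == "H")
  rec_heavy_NO <- which(ra$element %in% c("N", "O"))
  rec_donors <- list()
  for (i in rec_heavy_NO) {
    hs <- rec_H[colSums((t(R[rec_H, , drop = FALSE]) - R[i, ])^2) < 1.21]
    for (h in hs) rec_donors[[length(rec_donors) + 1]] <- c(i, h)
  }
  # donors/acceptors on the ligand (explicit hydrogens via the bond graph)
  el <- topology$atoms$element
  adj <- .adjacency(length(el), topology$bonds)
  lig_donors <- list()
  lig_acceptors <- integer(0)
  for (i in which(el %in% c("N", "O"))) {
    hs <- adj[[i]][el[adj[[i]]] == "H"]
    for (h in hs) lig_donors[[length(lig_donors) + 1]] <- c(i, h)
    if (!(el[i] == "N" && length(adj[[i]]) >= 4)) {
      lig_acceptors <- c(lig_acceptors, i)
    }
  }
  if (length(lig_donors) == 0 && any(el %in% c("N", "O")) &&
      !any(el == "H")) {
    log <- c(log, "ligand has no explicit hydrogens; donors skipped")
  }

  hb <- list()
  add_hb <- function(D, H, A, donor_label, acceptor_label, side) {
    d_da <- sqrt(sum((D - A)^2))
    if (d_da > hb_dist) return(invisible(NULL))
    v1 <- D - H; v2 <- A - H
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                               (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
    if (ang < hb_angle) return(invisible(NULL))
    en <- hbond_energy(d_da, ang, d_cut = hb_dist, angle_min = hb_angle)
    hb[[length(hb) + 1]] <<- tibble(
      donor = donor_label, acceptor = acceptor_label, side = side,
      d_donor_acceptor = d_da, d_hydrogen_acceptor = sqrt(sum((H - A)^2)),
      angle = ang, energy = en, exists = en <= exist_threshold)
  }
  rec_label <- function(i) sprintf("%s%d:%s", ra$residue[i], ra$resno[i],
                                   ra$atom_name[i])
  lig_label <- function(i) sprintf("%s:%s%d", topology$name, el[i], i)
  for (dh in rec_donors) {
    for (aidx in lig_acceptors) {
      add_hb(R[dh[1], ], R[dh[2], ], L[aidx, ], rec_label(dh[1]),
             lig_label(aidx), "receptor-donor")
    }
  }
  for (dh in lig_donors) {
    for (aidx in rec_heavy_NO) {
      add_hb(L[dh[1], ], L[dh[2], ], R[aidx, ], lig_label(dh[1]),
             rec_label(aidx), "ligand-donor")
    }
  }
  hbonds <- if (length(hb) > 0) bind_rows(hb) else
    tibble(donor = character(0), acceptor = character(0), side = character(0),
           d_donor_acceptor = numeric(0), d_hydrogen_acceptor = numeric(0),
           angle = numeric(0), energy = numeric(0), exists = logical(0))

  # pi-stacking: planar 5/6-membered ligand rings vs aromatic residue rings
  lig_rings <- keep(topology$rings, function(r) {
    length(r) %in% c(5, 6) && .ring_plane(L[r, , drop = FALSE])$rms < 0.3
  })
  stacks <- list()
  res_key <- paste(ra$chain, ra$resno)
  for (rk in unique(res_key)) {
    sel <- which(res_key == rk)
    res <- ra$residue[sel[1]]
    tmpl <- .receptor_rings[[res]]
    if (is.null(tmpl)) next
    for (names_ring in tmpl) {
      ridx <- sel[match(names_ring, ra$atom_name[sel])]
      if (anyNA(ridx)) next
      pr <- .ring_plane(R[ridx, , drop = FALSE])
      for (li in seq_along(lig_rings)) {
        pl <- .ring_plane(L[lig_rings[[li]], , drop = FALSE])
        dcen <- sqrt(sum((pr$centroid - pl$centroid)^2))
        if (dcen > stack_dist) next
        cosang <- abs(sum(pr$normal * pl$normal))
        ang <- acos(pmin(1, cosang)) * 180 / pi
        if (ang <= 30 || (ang >= 60 && ang <= 90)) {
          stacks[[length(stacks) + 1]] <- tibble(
            receptor_ring = sprintf("%s%d", res, ra$resno[sel[1]]),
            ligand_ring = paste(lig_rings[[li]], collapse = "-"),
            centroid_distance = dcen, interplane_angle = ang,
            geometry = if (ang <= 30) "parallel" else "t-shaped")
        }
      }
    }
  }
  pi_stacks <- if (length(stacks) > 0) bind_rows(stacks) else
    tibble(receptor_ring = character(0), ligand_ring = character(0),
           centroid_distance = numeric(0), interplane_angle = numeric(0),
           geometry = character(0))

  # Michael-acceptor beta carbons vs catalytic Ser/Cys nucleophiles
  elec <- michael_acceptor_carbons(topology)
  nuc <- which((ra$residue == "SER" & ra$atom_name == "OG") |
                 (ra$residue == "CYS" & ra$atom_name == "SG"))
  reactive <- list()
  for (ei in elec) {
    for (ni in nuc) {
      dd <- sqrt(sum((L[ei, ] - R[ni, ])^2))
      if (dd <= reactive_dist) {
        reactive[[length(reactive) + 1]] <- tibble(
          electrophile = lig_label(ei), nucleophile = rec_label(ni),
          distance = dd)
      }
    }
  }
  reactive <- if (length(reactive) > 0) bind_rows(reactive) else
    tibble(electrophile = character(0), nucleophile = character(0),
           distance = numeric(0))

  structure(list(hbonds = hbonds, pi_stacks = pi_stacks, reactive = reactive,
                 log = log, exist_threshold = exist_threshold),
            class = "gridock_interactions")
}

#' @export
print.gridock_interactions <- function(x, ...) {
  cat(sprintf("<gridock_interactions> %d H-bond(s), %d pi-stack(s), %d reactive proximity(ies)\n",
              nrow(x$hbonds), nrow(x$pi_stacks), nrow(x$reactive)))
  if (nrow(x$hbonds) > 0) {
    for (i in seq_len(nrow(x$hbonds))) {
      cat(sprintf("  H-bond %s -> %s: %.2f A, %.0f deg, %.2f kcal/mol%s\n",
                  x$hbonds$donor[i], x$hbonds$acceptor[i],
                  x$hbonds$d_donor_acceptor[i], x$hbonds$angle[i],
                  x$hbonds$energy[i],
                  if (x$hbonds$exists[i]) "" else " (below existence threshold)"))
    }
  }
  invisible(x)
}

#' @export
tidy.gridock_interactions <- function(x, ...) {
  bind_rows(
    if (nrow(x$hbonds) > 0) mutate(select(x$hbonds, partner_a = "donor",
                                          partner_b = "acceptor",
                                          distance = "d_donor_acceptor",
                                          "energy"),
                                   type = "hbond") else NULL,
    if (nrow(x$pi_stacks) > 0) mutate(select(x$pi_stacks,
                                             partner_a = "receptor_ring",
                                             partner_b = "ligand_ring",
                                             distance = "centroid_distance"),
                                      energy = NA_real_,
                                      type = "pi_stack") else NULL,
    if (nrow(x$reactive) > 0) mutate(select(x$reactive,
                                            partner_a = "electrophile",
                                            partner_b = "nucleophile",
                                            "distance"),
                                     energy = NA_real_,
                                     type = "reactive_proximity") else NULL
  )
}

#' Flag Michael-acceptor beta-carbons
#'
#' Substructure search for an alpha,beta-unsaturated carbonyl
#' (C_beta=C_alpha-C=O): returns the indices of beta carbons, the
#' electrophilic sites capable of covalent attack on a catalytic serine.
#'
#' @param topology A `gridock_ligand`.
#' @return Integer vector of atom indices.
#' @export
michael_acceptor_carbons <- function(topology) {
  el <- topology$atoms$element
  b <- topology$bonds
  if (nrow(b) == 0) return(integer(0))
  # carbonyl carbons: C double-bonded to O
  carbonyl <- unique(unlist(lapply(seq_len(nrow(b)), function(k) {
    if (b$order[k] != 2) return(NULL)
    i <- b$i[k]; j <- b$j[k]
    if (el[i] == "C" && el[j] == "O") return(i)
    if (el[j] == "C" && el[i] == "O") return(j)
    NULL
  })))
  if (length(carbonyl) == 0) return(integer(0))
  out <- integer(0)
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 2) next
    i <- b$i[k]; j <- b$j[k]
    if (el[i] != "C" || el[j] != "C") next
    for (ord in list(c(i, j), c(j, i))) {
      alpha <- ord[1]; beta <- ord[2]
      nb <- setdiff(.adjacency(length(el), b)[[alpha]], beta)
      if (any(nb %in% carbonyl)) out <- c(out, beta)
    }
  }
  sort(unique(out))
}
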