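# Synthetic fixtures: toy receptors with a concave charged pocket, small
# ligands with a complementary cationic head, planted complexes whose global
# minimum is verified by brute force, and the brute-force search oracle.
#
# Fixtures use the production force-field terms throughout, so they exercise
# the real docking path rather than a mock.

#' Generate a toy pocket receptor
#'
#' Places `n_atoms - 1` neutral carbon atoms on a hemispherical shell that
#' opens along +z, forming a concave cavity, plus one negatively charged
#' oxygen "anchor" at the cavity base (playing the role of the S1 Asp
#' specificity anchor of a serine protease). Deterministic per seed.
#'
#' @param n_atoms Total atom count (>= 4).
#' @param seed Integer seed.
#' @param radius Shell radius (A); default 6.
#' @param anchor_charge Anchor partial charge; default -1.
#' @return A `gridock_receptor` centred at the origin with `center_hint` at
#'   the cavity mouth.
#' @export
make_toy_pocket <- function(n_atoms = 30, seed = 1, radius = 6,
                            anchor_charge = -1) {
  stopifnot(n_atoms >= 4)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  n_shell <- n_atoms - 1
  # quasi-even hemispherical placement (golden-angle spiral, lower half),
  # jittered slightly so distinct seeds give distinct pockets
  k <- seq_len(n_shell)
  golden <- pi * (3 - sqrt(5))
  cosphi <- -k / (n_shell + 1)           # z < 0: bowl opening upward
  sinphi <- sqrt(1 - cosphi^2)
  theta <- k * golden + runif(1, 0, 2 * pi)
  pts <- radius * cbind(sinphi * cos(theta), sinphi * sin(theta), cosphi)
  pts <- pts + matrix(rnorm(3 * n_shell, sd = 0.15), ncol = 3)
  anchor <- c(0, 0, -radius)
  atoms <- tibble(
    element = c(rep("C", n_shell), "O"),
    x = c(pts[, 1], anchor[1]), y = c(pts[, 2], anchor[2]),
    z = c(pts[, 3], anchor[3]),
    charge = c(rep(0, n_shell), anchor_charge),
    residue = c(rep("SHL", n_shell), "ANC"),
    resno = c(seq_len(n_shell), 999L),
    atom_name = c(sprintf("C%d", seq_len(n_shell)), "OAN")
  )
  new_receptor(atoms, center_hint = c(0, 0, 0),
               log = sprintf("toy pocket, seed %d", seed))
}

# Small rigid-core ligand: a cationic nitrogen "head" plus carbon tail; with
# torsions, extra CH2-like beads are chained on rotatable bonds.
.make_toy_ligand <- function(n_torsions, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed + 1000)
  # rigid chiral 5-atom core: no mirror or rotational symmetry, and the
  # branches differ in element and charge, so poses are energetically
  # distinguishable and clustering is unambiguous
  core <- rbind(
    c(0, 0, 0),           # N+ head
    c(0, 0, 1.5),         # C
    c(0.45, 1.30, 2.15),  # O branch
    c(-0.20, -1.35, 2.25),# C branch
    c(0.10, 0.15, 2.95)   # C stem
  )
  el <- c("N", "C", "O", "C", "C")
  bonds <- tibble(i = c(1L, 2L, 2L, 2L), j = c(2L, 3L, 4L, 5L),
                  order = c(1L, 1L, 1L, 1L))
  coords <- core
  prev <- 5L
  # kinked linear extension: each added atom turns the previous chain bond
  # into a rotatable torsion (the terminal bond itself never rotates), so
  # exactly n_torsions rotatable bonds result
  for (t in seq_len(n_torsions)) {
    base <- coords[prev, ]
    side <- if (t %% 2 == 1) c(0.9, 0, 1.1) else c(-0.9, 0.3, 1.1)
    newpos <- base + side / sqrt(sum(side^2)) * 1.5
    coords <- rbind(coords, newpos)
    el <- c(el, "C")
    bonds <- bind_rows(bonds, tibble(i = prev, j = nrow(coords), order = 1L))
    prev <- nrow(coords)
  }
  charges <- c(1, 0, -0.3, 0.15, 0.15, rep(0, nrow(coords) - 5))
  new_ligand(tibble(element = el, charge = charges,
                    formal_charge = c(1L, rep(0L, nrow(coords) - 1))),
             bonds, coords, name = sprintf("toy-ligand-t%d-s%d", n_torsions,
                                           seed))
}

#' Quasi-uniform orientation set
#'
#' Deterministic low-discrepancy quaternion lattice (generalized Halton-style
#' construction on the 3-sphere via the subgroup algorithm), used by the
#' brute-force pose search to avoid pole bias.
#'
#' @param n Number of orientations.
#' @return An `n x 4` matrix of unit quaternions.
#' @export
orientation_lattice <- function(n) {
  # Halton sequences in bases 2, 3, 5 mapped by the uniform-quaternion
  # construction q = (sqrt(1-u1) sin 2pi u2, sqrt(1-u1) cos 2pi u2,
  #                   sqrt(u1) sin 2pi u3, sqrt(u1) cos 2pi u3)
  halton <- function(i, b) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / b
      r <- r + f * (i %% b)
      i <- i %/% b
    }
    r
  }
  u1 <- vapply(seq_len(n), halton, numeric(1), b = 2)
  u2 <- vapply(seq_len(n), halton, numeric(1), b = 3)
  u3 <- vapply(seq_len(n), halton, numeric(1), b = 5)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2), sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3), sqrt(u1) * cos(2 * pi * u3))
}

#' Brute-force pose search
#'
#' Exhaustive enumeration over a translation lattice (spacing `resolution`
#' A across the docking cube interior), a quasi-uniform orientation set
#' (angular spacing approximately `angular_resolution`), and a torsion grid.
#' Intended as an oracle for the genetic algorithm on rigid or at most
#' 2-torsion ligands; larger search spaces raise an error.
#'
#' @param grid A `gridock_grid`.
#' @param topology A `gridock_ligand` with at most 2 rotatable torsions.
#' @param resolution Translation lattice spacing (A); default 0.5.
#' @param angular_resolution Approximate orientation/torsion spacing
#'   (degrees); default 30.
#' @param torsion_strength Torsion restraint constant, as in [ga_config()].
#' @param max_poses Cap on the enumeration size; default 5e7.
#' @param extent Half-width of the translation lattice (A); defaults to the
#'   usable cube half-extent.
#' @param n_keep Number of leading lattice poses to return (the planted
#'   -complex builder polishes several basins).
#' @return List with `pose`, `energy`, and the `n_keep` leading lattice
#'   `candidates` with their `candidate_energies`.
#' @export
brute_force_search <- function(grid, topology, resolution = 0.5,
                               angular_resolution = 30,
                               torsion_strength = 1.5, max_poses = 5e7,
                               extent = NULL, n_keep = 1) {
  nt <- nrow(topology$torsions)
  if (nt > 2) abort("Brute-force search supports at most 2 torsions; use the GA.")
  span <- if (nrow(topology$coords) > 1) max(stats::dist(topology$coords)) else 0
  if (is.null(extent)) extent <- max(grid$config$edge / 2 - span / 2, 1)
  steps <- seq(-extent, extent, by = resolution)
  trans <- as.matrix(expand.grid(x = steps, y = steps, z = steps))
  n_orient <- max(1, round(2 * pi^2 / (angular_resolution * pi / 180)^3))
  quats <- orientation_lattice(n_orient)
  tor_vals <- seq(-pi, pi - angular_resolution * pi / 180,
                  by = angular_resolution * pi / 180)
  torgrid <- if (nt == 0) matrix(numeric(0), 0, 0) else
    as.matrix(expand.grid(rep(list(tor_vals), nt)))
  total <- nrow(trans) * nrow(quats) * max(1, nrow(torgrid))
  if (total > max_poses) {
    abort(sprintf("Search space (%g poses) exceeds the cap; use the GA.", total))
  }
  a <- .lig_eval_args(grid, topology)
  u_ref <- .u_ref(topology, grid$config)
  res <- cpp_brute_force(a$elec, a$vdw_rep, a$vdw_att, a$desolv, a$origin,
                         a$spacing, a$nn, a$ref, grid$config$center, a$lq,
                         a$vdw_col, a$tq, a$tmov, a$pairs, a$pqq, a$peps,
                         a$prmin, torsion_strength, u_ref, a$eps_in, a$a_vdw,
                         a$cap, trans, quats, torgrid, a$penalty,
                         as.integer(n_keep))
  mk <- function(k) {
    tor <- if (nt == 0) numeric(0) else as.numeric(torgrid[res$i_tor[k], ])
    new_pose(trans[res$i_trans[k], ], quats[res$i_quat[k], ], tor)
  }
  cands <- lapply(seq_along(res$energy), mk)
  list(pose = cands[[1]], energy = res$energy[1],
       candidates = cands, candidate_energies = res$energy)
}

#' Generate a planted receptor--ligand complex
#'
#' Builds a toy pocket and a complementary ligand (cationic head toward the
#' anchor), places the ligand by a short local search, and verifies by
#' [brute_force_search()] (0.5 A / 30 degrees) that the planted pose is the
#' global minimum of the toy objective within the stated tolerance. If
#' verification fails the next seed is tried (logged).
#'
#' @param n_torsions Number of rotatable ligand torsions (0 to 6; brute-force
#'   verification requires <= 2).
#' @param seed Integer seed.
#' @param edge Docking-cube edge for the fixture grid (A); default 11.
#' @param n_receptor_atoms Toy receptor size; default 30.
#' @param verify Verify global optimality by brute force (default TRUE for
#'   <= 2 torsions).
#' @return A `gridock_planted_complex`: receptor, topology, grid,
#'   `planted_pose`, `planted_energy`, `seed`, `log`.
#' @export
make_planted_complex <- function(n_torsions = 0, seed = 1, edge = 11,
                                 n_receptor_atoms = 30,
                                 verify = n_torsions <= 2) {
  stopifnot(n_torsions >= 0, n_torsions <= 6)
  log <- character(0)
  for (attempt in 0:4) {
    s <- seed + attempt
    receptor <- make_toy_pocket(n_receptor_atoms, seed = s)
    topology <- .make_toy_ligand(n_torsions, seed = s)
    config <- grid_config(center = receptor$center_hint, edge = edge,
                          spacing = 0.22)
    grid <- suppressWarnings(build_grids(receptor, config))
    # plant: coarse lattice search keeping the leading basins, then
    # continuum polish (all pose degrees of freedom) of each candidate;
    # polishing several lattice leaders guards against the lattice
    # misranking energetically close orientation basins. Beyond the
    # brute-force torsion bound the plant is seeded by GA searches instead.
    nt <- nrow(topology$torsions)
    ecfg <- ga_config(population_size = 2, independent_runs = 1)
    obj_genome <- function(gen) {
      objective(grid, topology, genome_pose(gen, nt), ecfg)
    }
    starts <- if (nt <= 2) {
      coarse <- brute_force_search(grid, topology, resolution = 0.5,
                                   angular_resolution = 30, n_keep = 16)
      keep <- which(coarse$candidate_energies <=
                      coarse$candidate_energies[1] + 5)
      lapply(coarse$candidates[keep], pose_genome)
    } else {
      gcfg <- ga_config(population_size = 300, generations = 120,
                        independent_runs = 1)
      lapply(1:4, function(k) {
        pose_genome(run_ga(grid, topology, gcfg,
                           run_seed = s * 1000 + k)$pose)
      })
    }
    polished <- lapply(starts, function(g0) {
      stats::optim(g0, obj_genome, method = "Nelder-Mead",
                   control = list(maxit = 1500, reltol = 1e-10))
    })
    vals <- vapply(polished, `[[`, numeric(1), "value")
    fit <- polished[[which.min(vals)]]
    planted <- genome_pose(fit$par, nt)
    planted_energy <- fit$value
    if (nt > 2) verify <- FALSE
    if (!verify || planted_energy <= coarse$energy + 1e-9) {
      if (attempt > 0) log <- c(log, sprintf("regenerated with seed %d", s))
      return(structure(list(receptor = receptor, topology = topology,
                            grid = grid, planted_pose = planted,
                            planted_energy = planted_energy, seed = s,
                            log = log),
                       class = "gridock_planted_complex"))
    }
    log <- c(log, sprintf("seed %d failed brute-force verification", s))
  }
  abort("Could not construct a verified planted complex in 5 attempts.")
}

#' @export
print.gridock_planted_complex <- function(x, ...) {
  cat(sprintf("<gridock_planted_complex> seed %d: %d receptor atoms, %d-torsion ligand\n",
              x$seed, nrow(x$receptor$atoms), nrow(x$topology$torsions)))
  cat(sprintf("  planted objective %.2f kcal/mol\n", x$planted_energy))
  invisible(x)
}

#' Write fixture files to a directory
#'
#' Serializes a planted complex to standard formats: receptor as PDB, ligand
#' as SDF (reference conformer), and the planted pose as a second SDF.
#'
#' @param complex A `gridock_planted_complex`.
#' @param dir Output directory (created if needed).
#' @export
write_fixture <- function(complex, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_receptor(complex$receptor, file.path(dir, "receptor.pdb"))
  write_ligands(complex$topology, file.path(dir, "ligand.sdf"))
  planted_coords <- pose_to_coordinates(complex$topology, complex$planted_pose,
                                        centre = complex$grid$config$center)
  write_ligands(complex$topology, file.path(dir, "planted_pose.sdf"),
                coords = list(planted_coords))
  invisible(dir)
}
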