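# Global pose optimization by genetic algorithm, multi-run clustering and
# success assessment.

#' Genetic-algorithm configuration
#'
#' Defaults correspond to the full production search (population 30,000 over
#' 1,000 generations, 50 independent runs, 1 A RMSD clustering, success when
#' the first cluster holds at least 10 run-best poses). Test and example code
#' uses much smaller populations.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param generations Number of generations.
#' @param independent_runs Independent GA runs whose best poses are clustered.
#' @param cluster_rmsd Clustering threshold (A).
#' @param success_min_population Minimum first-cluster population for the
#'   docking to count as reliable.
#' @param crossover_rate Probability that a parent pair undergoes uniform
#'   crossover.
#' @param mutation_rate Per-gene mutation probability.
#' @param tournament_size Tournament selection size.
#' @param sigma_translation,sigma_quaternion,sigma_torsion Gaussian mutation
#'   widths (A, unitless, radians).
#' @param elitism Number of best individuals copied unchanged.
#' @param torsion_strength Torsion restraint constant (kcal/mol) of the
#'   internal-strain term.
#' @param seed Master seed; per-run seeds are derived from it.
#' @return A `gridock_ga_config`.
#' @export
ga_config <- function(population_size = 30000, generations = 1000,
                      independent_runs = 50, cluster_rmsd = 1.0,
                      success_min_population = 10, crossover_rate = 0.8,
                      mutation_rate = 0.05, tournament_size = 3,
                      sigma_translation = 0.5, sigma_quaternion = 0.1,
                      sigma_torsion = 15 * pi / 180, elitism = 1,
                      torsion_strength = 1.5, seed = 1L) {
  stopifnot(population_size >= 2, independent_runs >= 1, cluster_rmsd > 0,
            generations >= 1)
  structure(as.list(environment()), class = "gridock_ga_config")
}

# Deterministic per-run seed derivation from the master seed.
.derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

.lig_eval_args <- function(grid, topology) {
  list(elec = grid$elec, vdw_rep = grid$vdw_rep, vdw_att = grid$vdw_att,
       desolv = grid$desolv,
       origin = grid$origin, spacing = grid$config$spacing, nn = grid$n,
       ref = topology$coords, lq = topology$atoms$charge,
       vdw_col = .vdw_columns(grid, topology$atoms$element),
       tq = topology$torsion_quads0, tmov = topology$torsion_moving0,
       pairs = topology$nb_pairs0, pqq = topology$nb_qq,
       peps = topology$nb_eps, prmin = topology$nb_rmin,
       eps_in = grid$config$interior_dielectric,
       a_vdw = grid$config$cap_start_vdw, cap = grid$config$cap,
       penalty = grid$config$outside_penalty)
}

.u_ref <- function(topology, config) {
  if (nrow(topology$torsions) == 0) return(0)
  cpp_intra_nb_ref(topology$coords, topology$nb_pairs0, topology$nb_qq,
                   topology$nb_eps, topology$nb_rmin,
                   config$interior_dielectric, config$cap_start_vdw,
                   config$cap)
}

.eval_genomes <- function(grid, topology, genomes, kt,
                          interaction_only = FALSE) {
  a <- .lig_eval_args(grid, topology)
  u_ref <- .u_ref(topology, grid$config)
  cpp_eval_population(a$elec, a$vdw_rep, a$vdw_att, a$desolv, a$origin,
                      a$spacing, a$nn, a$ref, grid$config$center, a$lq,
                      a$vdw_col, a$tq, a$tmov, a$pairs, a$pqq, a$peps,
                      a$prmin, kt, u_ref, a$eps_in, a$a_vdw, a$cap, genomes,
                      a$penalty, interaction_only)
}

#' Ligand internal strain energy
#'
#' Torsion restraint `k_t * (1 - cos(delta))` per rotatable torsion plus the
#' change in intramolecular nonbonded energy (Coulomb and Lennard-Jones over
#' atom pairs separated by more than three bonds) relative to the reference
#' conformer. The reference pose therefore has zero strain by construction.
#'
#' @param topology A `gridock_ligand`.
#' @param pose A `gridock_pose`.
#' @param config A `gridock_ga_config` (supplies the torsion constant); a
#'   `gridock_grid_config` governs the nonbonded caps via `grid`.
#' @param grid Optional `gridock_grid` whose configuration sets dielectric
#'   and cap parameters; defaults to a standard configuration.
#' @return Strain energy (kcal/mol).
#' @export
internal_strain <- function(topology, pose, config = ga_config(),
                            grid = NULL) {
  gcfg <- if (is.null(grid)) grid_config(c(0, 0, 0)) else grid$config
  nt <- nrow(topology$torsions)
  if (length(pose$torsions) != nt) abort("Torsion count mismatch.")
  if (nt == 0) return(0)
  tors <- sum(config$torsion_strength * (1 - cos(pose$torsions)))
  X <- pose_to_coordinates(topology, pose)
  u <- cpp_intra_nb_ref(X, topology$nb_pairs0, topology$nb_qq,
                        topology$nb_eps, topology$nb_rmin,
                        gcfg$interior_dielectric, gcfg$cap_start_vdw,
                        gcfg$cap)
  u0 <- cpp_intra_nb_ref(topology$coords, topology$nb_pairs0, topology$nb_qq,
                         topology$nb_eps, topology$nb_rmin,
                         gcfg$interior_dielectric, gcfg$cap_start_vdw,
                         gcfg$cap)
  tors + u - u0
}

#' Docking objective: interaction energy plus internal strain
#'
#' The target function of the global optimization. For a rigid ligand it
#' equals the grid interaction energy exactly.
#'
#' @inheritParams internal_strain
#' @param grid A `gridock_grid` built for the receptor.
#' @return Objective value (kcal/mol).
#' @export
objective <- function(grid, topology, pose, config = ga_config()) {
  genome <- matrix(pose_genome(pose), nrow = 1)
  .eval_genomes(grid, topology, genome, config$torsion_strength)[1]
}

#' Pose score: grid interaction energy only
#'
#' The reported score of a pose is the protein-ligand interaction component
#' of the objective (without internal strain), in kcal/mol; more negative is
#' better. The scale is that of this package's grid force field.
#'
#' @inheritParams objective
#' @export
score_pose <- function(grid, topology, pose) {
  genome <- matrix(pose_genome(pose), nrow = 1)
  .eval_genomes(grid, topology, genome, 0, interaction_only = TRUE)[1]
}

# Random initial population: centroid displaced uniformly within the cube
# (with a small wall margin), uniform random orientations, uniform torsions.
.init_population <- function(n, n_torsions, half_extent) {
  g <- matrix(0, n, 7 + n_torsions)
  g[, 1:3] <- matrix(runif(3 * n, -half_extent, half_extent), ncol = 3)
  g[, 4:7] <- quat_random(n)
  if (n_torsions > 0) {
    g[, 7 + seq_len(n_torsions)] <- matrix(runif(n * n_torsions, -pi, pi),
                                           ncol = n_torsions)
  }
  g
}

#' Run a single genetic-algorithm search
#'
#' Genome: translation (3), orientation quaternion (4, renormalized after
#' every mutation), torsion deltas. Tournament selection, uniform crossover,
#' per-gene Gaussian mutation, elitism. Fully reproducible for a fixed
#' `run_seed`.
#'
#' @param grid A `gridock_grid`.
#' @param topology A `gridock_ligand`.
#' @param config A `gridock_ga_config`.
#' @param run_seed Integer seed for this run.
#' @return List with `pose`, `objective`, and the per-generation best-so-far
#'   trace `history`.
#' @export
run_ga <- function(grid, topology, config = ga_config(), run_seed = 1L) {
  nt <- nrow(topology$torsions)
  # require that the ligand fits in the cube
  span <- if (nrow(topology$coords) > 1) max(stats::dist(topology$coords)) else 0
  if (is.na(span)) span <- 0
  if (span > grid$config$edge) {
    abort(sprintf("Ligand span %.1f A exceeds the docking cube edge %.1f A.",
                  span, grid$config$edge))
  }
  half_extent <- max(grid$config$edge / 2 - span / 2, 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(run_seed)

  np <- config$population_size
  pop <- .init_population(np, nt, half_extent)
  fit <- .eval_genomes(grid, topology, pop, config$torsion_strength)
  best_i <- which.min(fit)
  best_genome <- pop[best_i, ]
  best_fit <- fit[best_i]
  history <- numeric(config$generations)

  ngene <- 7 + nt
  for (gen in seq_len(config$generations)) {
    # tournament selection
    idx <- matrix(sample.int(np, np * config$tournament_size, replace = TRUE),
                  ncol = config$tournament_size)
    sel <- idx[cbind(seq_len(np), max.col(-matrix(fit[idx], ncol = config$tournament_size)))]
    parents <- pop[sel, , drop = FALSE]
    # uniform crossover on consecutive pairs
    off <- parents
    npair <- np %/% 2
    do_cx <- runif(npair) < config$crossover_rate
    for (p in which(do_cx)) {
      i1 <- 2 * p - 1; i2 <- 2 * p
      mask <- runif(ngene) < 0.5
      tmp <- off[i1, mask]
      off[i1, mask] <- off[i2, mask]
      off[i2, mask] <- tmp
    }
    # per-gene Gaussian mutation
    mut <- matrix(runif(np * ngene) < config$mutation_rate, np, ngene)
    noise <- matrix(0, np, ngene)
    noise[, 1:3] <- config$sigma_translation
    noise[, 4:7] <- config$sigma_quaternion
    if (nt > 0) noise[, 7 + seq_len(nt)] <- config$sigma_torsion
    off <- off + mut * noise * matrix(rnorm(np * ngene), np, ngene)
    # renormalize quaternions; wrap torsions; keep translations in the cube
    qn <- sqrt(rowSums(off[, 4:7, drop = FALSE]^2))
    qn[qn < 1e-12] <- 1
    off[, 4:7] <- off[, 4:7, drop = FALSE] / qn
    off[, 1:3] <- pmin(pmax(off[, 1:3, drop = FALSE], -half_extent), half_extent)
    if (nt > 0) {
      tcol <- 7 + seq_len(nt)
      off[, tcol] <- ((off[, tcol, drop = FALSE] + pi) %% (2 * pi)) - pi
    }
    # elitism
    if (config$elitism > 0) off[1, ] <- best_genome
    pop <- off
    fit <- .eval_genomes(grid, topology, pop, config$torsion_strength)
    gi <- which.min(fit)
    if (fit[gi] < best_fit) {
      best_fit <- fit[gi]
      best_genome <- pop[gi, ]
    }
    history[gen] <- best_fit
  }
  list(pose = genome_pose(best_genome, nt), objective = best_fit,
       history = history)
}

#' Greedy energy-ordered pose clustering
#'
#' The lowest-energy unassigned pose seeds a cluster; every unassigned pose
#' within the RMSD threshold of the seed joins it; repeat. Clusters are
#' ordered by seed energy; ties break by input order.
#'
#' @param pose_coords List of coordinate matrices (equal atom ordering).
#' @param energies Numeric vector of pose energies.
#' @param rmsd_threshold Clustering threshold (A).
#' @return A list of integer vectors (indices into the input), ordered by
#'   seed energy; each cluster's first element is its seed.
#' @export
cluster_poses <- function(pose_coords, energies, rmsd_threshold = 1.0) {
  n <- length(pose_coords)
  stopifnot(length(energies) == n)
  if (n == 0) return(list())
  unassigned <- rep(TRUE, n)
  ord <- order(energies, seq_len(n))
  clusters <- list()
  for (s in ord) {
    if (!unassigned[s]) next
    members <- s
    unassigned[s] <- FALSE
    for (t in ord) {
      if (!unassigned[t]) next
      if (rmsd_all_atoms(pose_coords[[s]], pose_coords[[t]]) < rmsd_threshold) {
        members <- c(members, t)
        unassigned[t] <- FALSE
      }
    }
    clusters[[length(clusters) + 1]] <- members
  }
  clusters
}

#' Dock a ligand: multi-run GA search with cluster-based reliability
#'
#' Runs `independent_runs` GA searches (seeds derived deterministically from
#' the master seed), clusters the run-best poses by all-atom RMSD, and
#' reports the best pose, its score (interaction energy), the
#' interaction/strain breakdown, and the success flag (first-cluster
#' population at least `success_min_population`).
#'
#' @inheritParams run_ga
#' @return A `gridock_docking` result.
#' @export
dock <- function(grid, topology, config = ga_config()) {
  seeds <- .derive_seeds(config$seed, config$independent_runs)
  runs <- lapply(seq_len(config$independent_runs), function(k) {
    run_ga(grid, topology, config, run_seed = seeds[k])
  })
  objectives <- map_dbl(runs, "objective")
  poses <- map(runs, "pose")
  coords <- map(poses, ~ pose_to_coordinates(topology, .x,
                                             centre = grid$config$center))
  clusters <- cluster_poses(coords, objectives, config$cluster_rmsd)
  best_idx <- clusters[[1]][1]
  best_pose <- poses[[best_idx]]
  score <- score_pose(grid, topology, best_pose)
  strain <- objectives[best_idx] - score
  structure(list(
    ligand = topology$name,
    run_best = tibble(run = seq_along(poses), objective = objectives,
                      pose = poses,
                      cluster = .cluster_assignment(clusters, length(poses))),
    clusters = clusters,
    best_pose = best_pose,
    best_coords = coords[[best_idx]],
    objective = objectives[best_idx],
    score = score,
    breakdown = c(interaction = score, strain = strain),
    success = length(clusters[[1]]) >= config$success_min_population,
    first_cluster_population = length(clusters[[1]]),
    config = config
  ), class = "gridock_docking")
}

.cluster_assignment <- function(clusters, n) {
  a <- integer(n)
  for (k in seq_along(clusters)) a[clusters[[k]]] <- k
  a
}

#' @export
print.gridock_docking <- function(x, ...) {
  cat(sprintf("<gridock_docking> %s\n", x$ligand))
  cat(sprintf("  score %.2f kcal/mol (interaction %.2f, strain %.2f)\n",
              x$score, x$breakdown["interaction"], x$breakdown["strain"]))
  cat(sprintf("  %d runs -> %d clusters; first cluster population %d; %s\n",
              nrow(x$run_best), length(x$clusters),
              x$first_cluster_population,
              if (x$success) "docking successful" else "docking NOT reliable"))
  invisible(x)
}

#' Tidy a docking result
#'
#' One row per independent GA run with its objective and cluster assignment.
#'
#' @param x A `gridock_docking`.
#' @param ... Unused.
#' @export
tidy.gridock_docking <- function(x, ...) {
  select(x$run_best, "run", "objective", "cluster")
}

#' @rdname tidy.gridock_docking
#' @export
glance.gridock_docking <- function(x, ...) {
  tibble(ligand = x$ligand, score = x$score,
         objective = x$objective,
         strain = unname(x$breakdown["strain"]),
         n_runs = nrow(x$run_best), n_clusters = length(x$clusters),
         first_cluster_population = x$first_cluster_population,
         success = x$success)
}

#' Plot run objectives by cluster for a docking result
#'
#' @param object A `gridock_docking`.
#' @param ... Unused.
#' @export
autoplot.gridock_docking <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$cluster), .data$objective)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "cluster (energy-ordered)",
                  y = "run-best objective (kcal/mol)",
                  title = sprintf("%s: %d runs, first cluster %d poses",
                                  object$ligand, nrow(df),
                                  object$first_cluster_population))
}
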