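# Objective, internal strain, the GA, clustering and success semantics.

test_that("rigid-ligand objective equals the grid interaction energy", {
  cx <- planted_rigid()
  pose <- cx$planted_pose
  obj <- objective(cx$grid, cx$topology, pose)
  sc <- score_pose(cx$grid, cx$topology, pose)
  X <- pose_to_coordinates(cx$topology, pose, centre = cx$grid$config$center)
  ge <- grid_energy(cx$grid, X, cx$topology$atoms$charge,
                    cx$topology$atoms$element)
  expect_equal(obj, ge, tolerance = 1e-9)
  expect_equal(sc, ge, tolerance = 1e-9)
})

test_that("internal strain is zero at reference and positive for clashes", {
  cx2 <- cached("planted_t2", make_planted_complex(2, seed = 21))
  lig <- cx2$topology
  expect_equal(internal_strain(lig, pose_identity(2)), 0)

  # objective and score differ by exactly the internal strain
  pose <- new_pose(torsions = c(0.7, -0.4))
  obj <- objective(cx2$grid, lig, pose)
  sc <- score_pose(cx2$grid, lig, pose)
  expect_equal(obj - sc, internal_strain(lig, pose, grid = cx2$grid),
               tolerance = 1e-8)
})

test_that("torsion strain scan has period 2*pi with its minimum at reference", {
  sdf <- withr::local_tempfile(fileext = ".sdf")
  butane_sdf(sdf)
  lig <- read_ligands(sdf)[[1]]
  phis <- seq(-pi, pi, length.out = 73)
  scan <- vapply(phis, function(p) internal_strain(lig, new_pose(torsions = p)),
                 numeric(1))
  expect_equal(internal_strain(lig, new_pose(torsions = 0)),
               internal_strain(lig, new_pose(torsions = 2 * pi)),
               tolerance = 1e-9)
  expect_equal(phis[which.min(scan)], 0, tolerance = 0.05)
  expect_true(all(scan >= -1e-9))
})

test_that("a torsion that collapses two atoms onto each other is heavily penalized", {
  # folded 5-atom chain: rotating the 2-3 torsion sweeps atom 5 (the only
  # >3-bond partner of atom 1) through a close approach far below the
  # pair's Lennard-Jones contact distance
  chain <- new_ligand(
    tibble::tibble(element = rep("C", 5), charge = 0),
    tibble::tibble(i = 1:4, j = 2:5, order = 1L),
    rbind(c(-1.1, 1.05, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.0, 1.3, 0),
          c(-0.5, -1.6, -0.5)),
    "clash-chain")
  expect_equal(nrow(chain$torsions), 2L)
  strains <- vapply(seq(-pi, pi, length.out = 361), function(p) {
    internal_strain(chain, new_pose(torsions = c(p, 0)))
  }, numeric(1))
  expect_gt(max(strains), 10)
})

test_that("the GA is seed-reproducible and monotone in best-so-far", {
  cx <- planted_rigid()
  r1 <- run_ga(cx$grid, cx$topology, ga_config(population_size = 60,
                                               generations = 25), run_seed = 7)
  r2 <- run_ga(cx$grid, cx$topology, ga_config(population_size = 60,
                                               generations = 25), run_seed = 7)
  expect_identical(r1$pose, r2$pose)
  expect_identical(r1$objective, r2$objective)
  expect_true(all(diff(r1$history) <= 0))
})

test_that("dock() with a fixed master seed is fully reproducible", {
  cx <- planted_rigid()
  cfg <- small_ga(seed = 5, runs = 4)
  cfg$population_size <- 80; cfg$generations <- 30
  d1 <- dock(cx$grid, cx$topology, cfg)
  d2 <- dock(cx$grid, cx$topology, cfg)
  expect_identical(d1$run_best$objective, d2$run_best$objective)
  expect_identical(d1$best_coords, d2$best_coords)
  expect_identical(tidy(d1), tidy(d2))
})

test_that("greedy energy-ordered clustering reproduces hand partitions", {
  base <- matrix(rnorm(12), ncol = 3)
  shift <- function(d) sweep(base, 2, c(d, 0, 0), `+`)
  # two poses 0.9 A apart join; 1.1 A apart split
  expect_length(cluster_poses(list(base, shift(0.9)), c(-2, -1), 1.0), 1L)
  expect_length(cluster_poses(list(base, shift(1.1)), c(-2, -1), 1.0), 2L)
  # chain A-B 0.9, B-C 0.9, A-C 1.8 with A lowest: {A,B}, {C}
  cl <- cluster_poses(list(A = base, B = shift(0.9), C = shift(1.8)),
                      energies = c(-3, -2, -1), rmsd_threshold = 1.0)
  expect_equal(cl, list(c(1L, 2L), 3L))
  # 50 poses at mutual RMSD 5: all singletons
  far <- lapply(0:9, function(k) shift(5 * k))
  cl2 <- cluster_poses(far, energies = seq(-10, -1), rmsd_threshold = 1.0)
  expect_length(cl2, 10L)
  # clusters partition the input and members sit within threshold of seeds
  all_members <- sort(unlist(cl))
  expect_equal(all_members, 1:3)
})

test_that("docking success flips exactly at the minimum first-cluster population", {
  cx <- planted_rigid()
  cfg <- ga_config(population_size = 120, generations = 60,
                   independent_runs = 10, seed = 3)
  d <- dock(cx$grid, cx$topology, cfg)
  fc <- d$first_cluster_population
  expect_identical(d$success, fc >= cfg$success_min_population)

  # rerunning the same seeds with the threshold at and just above the
  # realized population flips the flag exactly at the boundary
  cfg_at <- cfg; cfg_at$success_min_population <- fc
  expect_true(dock(cx$grid, cx$topology, cfg_at)$success)
  cfg_above <- cfg; cfg_above$success_min_population <- fc + 1
  expect_false(dock(cx$grid, cx$topology, cfg_above)$success)

  expect_s3_class(glance(d), "tbl_df")
  expect_equal(glance(d)$first_cluster_population, fc)
})

test_that("cube-overflow ligands are rejected before the search", {
  cx <- planted_rigid()
  big <- new_ligand(tibble::tibble(element = rep("C", 2), charge = 0),
                    tibble::tibble(i = 1L, j = 2L, order = 1L),
                    rbind(c(0, 0, 0), c(40, 0, 0)), "rod")
  expect_error(run_ga(cx$grid, big, small_ga()), "exceeds")
})
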