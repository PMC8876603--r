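# Synthetic fixtures and the brute-force oracle.

test_that("toy pockets are seed-deterministic with one charged anchor", {
  r1 <- make_toy_pocket(20, seed = 5)
  r2 <- make_toy_pocket(20, seed = 5)
  expect_identical(r1$atoms, r2$atoms)
  expect_equal(nrow(r1$atoms), 20L)
  expect_equal(sum(r1$atoms$charge != 0), 1L)
  expect_equal(sum(r1$atoms$charge), -1)
  r3 <- make_toy_pocket(20, seed = 6)
  expect_false(isTRUE(all.equal(r1$atoms$x, r3$atoms$x)))
})

test_that("the electrostatic minimum sits near the anchor axis", {
  rec <- make_toy_pocket(20, seed = 5, radius = 6)
  cfg <- grid_config(c(0, 0, 0), edge = 11, spacing = 0.22)
  g <- suppressWarnings(build_grids(rec, cfg))
  # scan the elec field along z for a +1 charge: minimum toward the anchor
  zs <- seq(-3.5, 3.5, by = 0.25)
  es <- vapply(zs, function(z) {
    direct_energy(rec, matrix(c(0, 0, z), 1), charges = 1, elements = "Du",
                  config = cfg)
  }, numeric(1))
  expect_lt(zs[which.min(es)], -2) # attracted toward z = -6 anchor
})

test_that("planted complexes verify against the brute-force oracle", {
  cx <- planted_rigid()
  bf <- brute_force_search(cx$grid, cx$topology, resolution = 0.5,
                           angular_resolution = 30)
  # the plant is the continuum polish of the best lattice basins, so no
  # lattice pose may beat it, and the lattice optimum sits within its own
  # resolution error above it
  expect_lte(cx$planted_energy, bf$energy + 1e-9)
  expect_lt(bf$energy - cx$planted_energy, 5)
  # the plant is a genuine local minimum: random small perturbations of
  # the pose never lower the objective
  set.seed(99)
  for (k in 1:20) {
    p <- cx$planted_pose
    p$translation <- p$translation + rnorm(3, sd = 0.1)
    q <- p$quaternion + rnorm(4, sd = 0.02)
    p$quaternion <- q / sqrt(sum(q^2))
    e <- objective(cx$grid, cx$topology, p)
    expect_gte(e, cx$planted_energy - 1e-6)
  }

  # pose vector: 7 rigid parameters + torsions
  cx2 <- cached("planted_t2", make_planted_complex(2, seed = 21))
  expect_length(pose_genome(cx2$planted_pose), 9L)
  expect_length(cx2$planted_pose$torsions, 2L)
})

test_that("halving the brute-force resolution never worsens the optimum", {
  cx <- planted_rigid()
  coarse <- brute_force_search(cx$grid, cx$topology, resolution = 1.0,
                               angular_resolution = 40)
  finer <- brute_force_search(cx$grid, cx$topology, resolution = 0.5,
                              angular_resolution = 40)
  expect_lte(finer$energy, coarse$energy + 1e-9)
})

test_that("the combinatorial cap rejects high-torsion brute force", {
  cx3 <- cached("planted_t3", make_planted_complex(3, seed = 31,
                                                   verify = FALSE))
  expect_error(brute_force_search(cx3$grid, cx3$topology), "GA")
  expect_error(brute_force_search(planted_rigid()$grid,
                                  planted_rigid()$topology,
                                  resolution = 0.05, max_poses = 1e5),
               "cap")
})

test_that("redocking a planted complex recovers the pose within 1 A", {
  cx <- planted_rigid()
  res <- dock(cx$grid, cx$topology, small_ga(seed = 77, runs = 5))
  pc <- pose_to_coordinates(cx$topology, cx$planted_pose,
                            centre = cx$grid$config$center)
  expect_lt(rmsd_all_atoms(pc, res$best_coords), 1.0)
  expect_lt(res$score, 0) # favourable planted complex
})

test_that("orientation lattices are unit quaternions with low discrepancy", {
  q <- orientation_lattice(150)
  expect_equal(rowSums(q^2), rep(1, 150), tolerance = 1e-12)
  # antipodal coverage: no hemisphere bias in the first component
  expect_gt(mean(q[, 1] > 0), 0.35)
  expect_lt(mean(q[, 1] > 0), 0.65)
})

test_that("fixtures serialize to standard formats and re-read", {
  cx <- planted_rigid()
  dir <- withr::local_tempdir()
  write_fixture(cx, dir)
  expect_true(file.exists(file.path(dir, "receptor.pdb")))
  pdb <- bio3d::read.pdb(file.path(dir, "receptor.pdb"), verbose = FALSE)
  expect_equal(nrow(pdb$atom), nrow(cx$receptor$atoms))
  expect_equal(pdb$atom$x, cx$receptor$atoms$x, tolerance = 1e-3)
  lig <- read_ligands(file.path(dir, "ligand.sdf"))[[1]]
  expect_equal(nrow(lig$atoms), nrow(cx$topology$atoms))
  expect_equal(nrow(lig$torsions), nrow(cx$topology$torsions))
  planted <- read_ligands(file.path(dir, "planted_pose.sdf"))[[1]]
  pc <- pose_to_coordinates(cx$topology, cx$planted_pose,
                            centre = cx$grid$config$center)
  expect_equal(planted$coords, pc, tolerance = 1e-4)
})
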