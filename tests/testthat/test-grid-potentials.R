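# Potential grids: construction, closed forms, interpolation, serialization.

test_that("default cube has 101 nodes per axis and validates spacing", {
  cfg <- grid_config(c(0, 0, 0))
  expect_equal(cfg$n_nodes, 101L)
  expect_error(grid_config(c(0, 0, 0), edge = 22, spacing = 0.21),
               "integer node count")
})

test_that("electrostatic field matches the Coulomb closed form", {
  rec <- new_receptor(tibble::tibble(element = "C", x = 0, y = 0, z = 0,
                                     charge = 1))
  # solvent dielectric equal to the interior switches desolvation off, and
  # a probe with no VdW parameters isolates the Coulomb term
  cfg <- grid_config(c(0, 0, 0), edge = 8.8, spacing = 0.22,
                     solvent_dielectric = 1)
  e <- direct_energy(rec, matrix(c(3.32, 0, 0), 1), charges = 1,
                     elements = "Du", config = cfg)
  expect_equal(e, 332.06 / 3.32, tolerance = 1e-9)

  g <- suppressWarnings(build_grids(rec, cfg))
  # value stored at an exact node is returned exactly by interpolation
  node <- c(g$origin[1] + 33 * 0.22, g$origin[2] + 20 * 0.22,
            g$origin[3] + 20 * 0.22)
  ge <- grid_energy(g, matrix(node, 1), charges = 1, elements = "Du")
  de <- direct_energy(rec, matrix(node, 1), charges = 1, elements = "Du",
                      config = cfg)
  expect_equal(ge, de, tolerance = 1e-9)

  # midway between two nodes along one axis: arithmetic mean of node values
  mid <- node + c(0.11, 0, 0)
  n1 <- direct_energy(rec, matrix(node, 1), 1, "Du", cfg)
  n2 <- direct_energy(rec, matrix(node + c(0.22, 0, 0), 1), 1, "Du", cfg)
  expect_equal(grid_energy(g, matrix(mid, 1), 1, "Du"), (n1 + n2) / 2,
               tolerance = 1e-9)
})

test_that("zero receptor charges give an identically zero electrostatic map", {
  rec <- make_toy_pocket(20, seed = 3, anchor_charge = 0)
  cfg <- grid_config(c(0, 0, 0), edge = 8.8, spacing = 0.44)
  g <- suppressWarnings(build_grids(rec, cfg))
  expect_true(all(g$elec == 0))
})

test_that("direct Lennard-Jones hits -eps at rmin and decays monotonically", {
  rec <- new_receptor(tibble::tibble(element = "C", x = 0, y = 0, z = 0,
                                     charge = 0))
  cfg <- grid_config(c(0, 0, 0), edge = 8.8, spacing = 0.22,
                     solvent_dielectric = 1) # no desolvation term
  # combined C-C parameters from the element table
  eps_cc <- 0.086; rmin_cc <- 3.8
  at_min <- direct_energy(rec, matrix(c(rmin_cc, 0, 0), 1), charges = 0,
                          elements = "C", config = cfg)
  expect_equal(at_min, -eps_cc, tolerance = 1e-9)
  rs <- seq(rmin_cc, 8.5, by = 0.25)
  es <- vapply(rs, function(r) {
    direct_energy(rec, matrix(c(r, 0, 0), 1), 0, "C", cfg)
  }, numeric(1))
  expect_true(all(diff(es) > 0))   # rises toward zero
  expect_true(all(es < 0))
})

test_that("grid agrees with the direct oracle away from atoms", {
  rec <- make_toy_pocket(25, seed = 9)
  cfg <- grid_config(c(0, 0, 0), edge = 11, spacing = 0.22)
  g <- suppressWarnings(build_grids(rec, cfg))
  R <- receptor_coords(rec)
  set.seed(42)
  pts <- matrix(nrow = 0, ncol = 3)
  while (nrow(pts) < 60) {
    p <- runif(3, -5.2, 5.2)
    if (sqrt(min(colSums((t(R) - p)^2))) >= cfg$spacing) pts <- rbind(pts, p)
  }
  ge <- vapply(seq_len(nrow(pts)), function(i) {
    grid_energy(g, pts[i, , drop = FALSE], charges = 0.3, elements = "C")
  }, numeric(1))
  de <- vapply(seq_len(nrow(pts)), function(i) {
    direct_energy(rec, pts[i, , drop = FALSE], charges = 0.3, elements = "C",
                  config = cfg)
  }, numeric(1))
  rel <- abs(ge - de) / pmax(abs(de), 1e-12)
  expect_lt(unname(quantile(rel, 0.95)), 0.01)
})

test_that("maps are translation covariant and bounded by the cap", {
  rec <- make_toy_pocket(15, seed = 4)
  cfg <- grid_config(c(0, 0, 0), edge = 6.6, spacing = 0.33)
  g1 <- suppressWarnings(build_grids(rec, cfg))
  shift <- c(3.7, -2.1, 1.4)
  a2 <- rec$atoms
  a2$x <- a2$x + shift[1]; a2$y <- a2$y + shift[2]; a2$z <- a2$z + shift[3]
  rec2 <- new_receptor(a2, center_hint = shift)
  g2 <- suppressWarnings(build_grids(rec2, grid_config(shift, edge = 6.6,
                                                       spacing = 0.33)))
  expect_equal(g1$elec, g2$elec, tolerance = 1e-9)
  expect_equal(g1$vdw_rep, g2$vdw_rep, tolerance = 1e-9)
  expect_equal(g1$desolv, g2$desolv, tolerance = 1e-9)

  expect_true(all(abs(g1$elec) <= cfg$cap))
  expect_true(all(is.finite(g1$vdw_rep)), all(is.finite(g1$vdw_att)))
  # reconstructed VdW values anywhere in the cube stay within the cap
  set.seed(1)
  pts <- matrix(runif(90, -3, 3), ncol = 3)
  vals <- vapply(seq_len(30), function(i) {
    grid_energy(g1, pts[i, , drop = FALSE], charges = 0, elements = "C")
  }, numeric(1))
  expect_true(all(vals <= cfg$cap + 1e-9))
})

test_that("the desolvation map is nonnegative everywhere", {
  rec <- make_toy_pocket(20, seed = 6)
  g <- suppressWarnings(build_grids(rec, grid_config(c(0, 0, 0), edge = 8.8,
                                                     spacing = 0.44)))
  expect_true(all(g$desolv >= 0))
  # isolate the charge-squared (desolvation) component by parity:
  # E(+q) + E(-q) - 2 E(0) = 2 q^2 * desolvation >= 0
  p <- matrix(c(0, 0, -4), 1)
  des2 <- grid_energy(g, p, 1, "Du") + grid_energy(g, p, -1, "Du") -
    2 * grid_energy(g, p, 0, "Du")
  expect_gt(des2, 0)
})

test_that("grid serialization round-trips exactly", {
  rec <- make_toy_pocket(10, seed = 2)
  g <- suppressWarnings(build_grids(rec, grid_config(c(0, 0, 0), edge = 4.4,
                                                     spacing = 0.44)))
  path <- withr::local_tempfile(fileext = ".rds")
  write_grid(g, path)
  g2 <- read_grid(path)
  expect_identical(g$elec, g2$elec)
  expect_identical(g$vdw_rep, g2$vdw_rep)
  expect_identical(g$desolv, g2$desolv)
  expect_identical(g$config, g2$config)

  saveRDS(list(), path)
  expect_error(read_grid(path), "potential grid")
})

test_that("empty coordinate sets are rejected", {
  rec <- make_toy_pocket(10, seed = 2)
  g <- suppressWarnings(build_grids(rec, grid_config(c(0, 0, 0), edge = 4.4,
                                                     spacing = 0.44)))
  expect_error(grid_energy(g, matrix(numeric(0), 0, 3), numeric(0),
                           character(0)), "Empty")
  expect_error(direct_energy(rec, matrix(numeric(0), 0, 3), numeric(0),
                             character(0)), "Empty")
})
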