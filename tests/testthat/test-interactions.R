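# Hydrogen-bond / pi-stack / reactive-proximity detection and the empirical
# H-bond energy.

make_nh_receptor <- function(stretch = 0) {
  new_receptor(tibble::tibble(
    element = c("N", "H", "C"),
    x = c(0, 0, 1.2), y = c(0 - stretch, 1.0 - stretch, 0 - stretch),
    z = c(0, 0, -0.6),
    charge = 0, residue = "GLY", resno = 193L,
    atom_name = c("N", "H", "C")))
}

carbonyl_ligand <- function(y_o = 2.9) {
  new_ligand(tibble::tibble(element = c("O", "C"), charge = c(-0.4, 0.2)),
             tibble::tibble(i = 1L, j = 2L, order = 2L),
             rbind(c(0, y_o, 0.35), c(1.2, y_o + 0.7, 0.4)), "acceptor")
}

test_that("an ideal backbone H-bond is detected; a stretched one is not", {
  rec <- make_nh_receptor()
  lig <- carbonyl_ligand(2.9)
  ir <- detect_interactions(rec, lig$coords, lig)
  expect_equal(nrow(ir$hbonds), 1L)
  expect_lt(ir$hbonds$d_donor_acceptor, 3.5)
  expect_gt(ir$hbonds$angle, 120)
  expect_lt(ir$hbonds$energy, 0)

  far <- carbonyl_ligand(4.5)
  ir2 <- detect_interactions(rec, far$coords, far)
  expect_equal(nrow(ir2$hbonds), 0L)
})

test_that("hbond_energy has its optimum, bounds and boundary behaviour", {
  expect_equal(hbond_energy(2.8, 180), -5.0, tolerance = 1e-12)
  # degraded geometry: strictly between -E0 and 0
  e <- hbond_energy(3.4, 140)
  expect_gt(e, -5); expect_lt(e, 0)
  # never positive over the detection region
  d <- seq(2.0, 3.5, by = 0.05); a <- seq(120, 180, by = 2)
  grid <- expand.grid(d = d, a = a)
  vals <- hbond_energy(grid$d, grid$a)
  expect_true(all(vals <= 1e-12))
  # approximately zero at both detection boundaries
  expect_lt(abs(hbond_energy(3.5, 180)), 0.2)
  expect_lt(abs(hbond_energy(2.8, 120)), 0.2)
  # monotone weakening with distance beyond the optimum and angle decay
  ds <- seq(2.8, 3.5, by = 0.05)
  expect_true(all(diff(hbond_energy(ds, 180)) >= -1e-12))
  as <- seq(180, 120, by = -5)
  expect_true(all(diff(hbond_energy(2.8, as)) >= -1e-12))
  # continuity: small steps never jump
  fine <- hbond_energy(seq(2.7, 3.55, by = 0.001), 170)
  expect_lt(max(abs(diff(fine))), 0.05)
})

test_that("a weak-geometry bond is classified below the existence threshold", {
  # hydrogen--acceptor distance ~2.85 A with poor alignment: detected
  # geometrically but energetically negligible (the -1 kcal/mol rule)
  rec <- make_nh_receptor()
  lig <- new_ligand(tibble::tibble(element = c("O", "C"),
                                   charge = c(-0.4, 0.2)),
                    tibble::tibble(i = 1L, j = 2L, order = 2L),
                    rbind(c(1.55, 3.25, 0.35), c(2.7, 3.9, 0.4)), "weak")
  ir <- detect_interactions(rec, lig$coords, lig)
  if (nrow(ir$hbonds) > 0) {
    expect_gt(ir$hbonds$energy[1], -1.0)
    expect_false(ir$hbonds$exists[1])
  }
  expect_lt(abs(hbond_energy(3.5, 125)), 1.0)
})

test_that("parallel rings stack; detection survives rigid motions", {
  ang <- seq(0, 300, 60) * pi / 180
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  rec <- new_receptor(tibble::tibble(
    element = rep("C", 6), x = ring[, 1], y = ring[, 2], z = ring[, 3],
    charge = 0, residue = "PHE", resno = 10L,
    atom_name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")))
  lig <- new_ligand(tibble::tibble(element = rep("C", 6), charge = 0),
                    tibble::tibble(i = 1:6, j = c(2:6, 1L), order = rep(4L, 6)),
                    cbind(1.39 * cos(ang), 1.39 * sin(ang), 3.8), "benzene")
  ir <- detect_interactions(rec, lig$coords, lig)
  expect_equal(nrow(ir$pi_stacks), 1L)
  expect_equal(ir$pi_stacks$centroid_distance, 3.8, tolerance = 1e-6)
  expect_equal(ir$pi_stacks$interplane_angle, 0, tolerance = 1e-6)

  # apply one rigid rotation + translation to the whole complex
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  t0 <- c(5, -3, 2)
  ra <- rec$atoms
  RX <- as.matrix(ra[, c("x", "y", "z")]) %*% t(R)
  ra$x <- RX[, 1] + t0[1]; ra$y <- RX[, 2] + t0[2]; ra$z <- RX[, 3] + t0[3]
  rec2 <- new_receptor(ra)
  lig2_coords <- lig$coords %*% t(R) + matrix(t0, 6, 3, byrow = TRUE)
  ir2 <- detect_interactions(rec2, lig2_coords, lig)
  expect_equal(nrow(ir2$pi_stacks), 1L)
  expect_equal(ir2$pi_stacks$centroid_distance,
               ir$pi_stacks$centroid_distance, tolerance = 1e-9)
  expect_equal(ir2$pi_stacks$interplane_angle,
               ir$pi_stacks$interplane_angle, tolerance = 1e-6)

  # separated rings do not stack
  ir3 <- detect_interactions(rec, lig$coords + 10, lig)
  expect_equal(nrow(ir3$pi_stacks), 0L)
})

test_that("Michael acceptors are flagged and serine proximity is reported", {
  # methyl vinyl ketone: C4(beta)=C3(alpha)-C2(=O1)-C5
  mvk <- new_ligand(
    tibble::tibble(element = c("O", "C", "C", "C", "C"), charge = 0),
    tibble::tibble(i = c(1L, 2L, 3L, 2L), j = c(2L, 3L, 4L, 5L),
                   order = c(2L, 1L, 2L, 1L)),
    rbind(c(0, 1.2, 0), c(0, 0, 0), c(1.3, -0.7, 0), c(1.35, -2.05, 0),
          c(-1.3, -0.75, 0)),
    "mvk")
  expect_equal(michael_acceptor_carbons(mvk), 4L)

  # butanone (saturated analogue) has no Michael acceptor
  but <- new_ligand(
    tibble::tibble(element = c("O", "C", "C", "C", "C"), charge = 0),
    tibble::tibble(i = c(1L, 2L, 3L, 2L), j = c(2L, 3L, 4L, 5L),
                   order = c(2L, 1L, 1L, 1L)),
    rbind(c(0, 1.2, 0), c(0, 0, 0), c(1.3, -0.7, 0), c(1.35, -2.2, 0),
          c(-1.3, -0.75, 0)),
    "butanone")
  expect_length(michael_acceptor_carbons(but), 0L)

  ser <- new_receptor(tibble::tibble(
    element = c("C", "O"), x = c(2.0, 3.0), y = c(-3.0, -2.6),
    z = c(1.0, 0.6), charge = 0, residue = "SER", resno = 195L,
    atom_name = c("CB", "OG")))
  ir <- detect_interactions(ser, mvk$coords, mvk)
  expect_equal(nrow(ir$reactive), 1L)
  expect_lte(ir$reactive$distance, 4.0)
  expect_match(ir$reactive$nucleophile, "SER195")
})
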