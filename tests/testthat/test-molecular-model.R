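# Receptor preparation, ligand topologies, poses and RMSD.

test_that("receptor preparation applies the pH 7.4 rule table", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(pdb)
  rec <- read_receptor(pdb, pH = 7.4, native = "BEN")

  # Lys side-chain nitrogen carries the cationic charge class
  lys_n <- rec$atoms$charge[rec$atoms$atom_name == "NZ"]
  lys_h <- sum(rec$atoms$charge[grepl("^HZ", rec$atoms$atom_name)])
  expect_gt(lys_n + lys_h, 0.9)
  expect_lt(lys_n + lys_h, 1.1)

  # polar hydrogens were added (backbone amides + NZ protons)
  expect_gt(sum(rec$atoms$element == "H"), 3)

  # native ligand extracted with its heavy-atom geometric centre
  expect_false(is.null(rec$native))
  expect_equal(rec$center_hint,
               unname(colMeans(as.matrix(rec$native[, c("x", "y", "z")]))),
               tolerance = 1e-10)
  expect_false(any(rec$atoms$residue == "BEN"))
})

test_that("incomplete residues and unknown residues are handled per contract", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(pdb, ca_only_resno = 2)
  expect_error(read_receptor(pdb, native = "BEN"), "missing atoms")

  pdb2 <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(pdb2, unknown_residue = TRUE)
  expect_warning(rec <- read_receptor(pdb2, native = "BEN"),
                 "Unknown residue")
  expect_false(any(rec$atoms$residue == "XYZ"))

  expect_error(read_receptor(pdb2, pH = 20), "pH")
})

test_that("rotatable-torsion perception matches manual bond classification", {
  sdf <- withr::local_tempfile(fileext = ".sdf")
  butane_sdf(sdf)
  lig <- read_ligands(sdf)[[1]]
  expect_equal(nrow(lig$torsions), 1L)
  expect_equal(unname(sort(unlist(lig$torsions[1, c("b", "c")]))), c(2L, 3L))

  benzene_sdf(sdf)
  benz <- read_ligands(sdf)[[1]]
  expect_equal(nrow(benz$torsions), 0L)
  expect_equal(length(benz$rings), 1L)
})

test_that("multi-conformer records expand to topologies sharing the bond graph", {
  sdf <- withr::local_tempfile(fileext = ".sdf")
  two_conformer_sdf(sdf)
  ligs <- read_ligands(sdf)
  expect_length(ligs, 2L)
  expect_identical(ligs[[1]]$bonds, ligs[[2]]$bonds)
  expect_identical(ligs[[1]]$atoms$element, ligs[[2]]$atoms$element)
  expect_false(isTRUE(all.equal(ligs[[1]]$coords, ligs[[2]]$coords)))
})

test_that("unparsable records are skipped with a log; valence errors abort", {
  sdf <- withr::local_tempfile(fileext = ".sdf")
  good <- readLines({ p <- tempfile(); butane_sdf(p); p })
  writeLines(c("broken", "  test", "", "garbage counts line", "$$$$", good),
             sdf)
  expect_message(ligs <- read_ligands(sdf), "skipped")
  expect_length(ligs, 1L)
  expect_length(attr(ligs, "log"), 1L)

  # pentavalent carbon
  writeLines(c(
    "badvalence", "  test", "",
    "  6  5  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000   -1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    1.5000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
    "  1  6  2  0",
    "M  END", "$$$$"), sdf)
  expect_error(read_ligands(sdf), "Valence")
})

test_that("pose application is exact for identity, translation and torsion", {
  cx <- planted_rigid()
  lig <- cx$topology
  id <- pose_identity(0)
  expect_equal(pose_to_coordinates(lig, id), lig$coords, tolerance = 1e-12)

  shifted <- pose_to_coordinates(lig, new_pose(c(1, 0, 0)))
  expect_equal(shifted[, 1], lig$coords[, 1] + 1, tolerance = 1e-12)
  expect_equal(shifted[, 2:3], lig$coords[, 2:3], tolerance = 1e-12)

  # planted 4-atom chain: torsion delta of pi lands at reference + pi
  chain <- new_ligand(
    tibble::tibble(element = c("C", "C", "C", "C"), charge = 0),
    tibble::tibble(i = 1:3, j = 2:4, order = 1L),
    rbind(c(-1.2, 0.9, 0), c(0, 0, 0), c(1.5, 0, 0), c(2.3, 1.2, 0.4)),
    "chain")
  expect_equal(nrow(chain$torsions), 1L)
  d0 <- dihedral_angle(chain$coords[1, ], chain$coords[2, ],
                       chain$coords[3, ], chain$coords[4, ])
  out <- pose_to_coordinates(chain, new_pose(torsions = pi))
  d1 <- dihedral_angle(out[1, ], out[2, ], out[3, ], out[4, ])
  delta <- (d1 - d0) %% (2 * pi)
  expect_equal(min(delta, 2 * pi - delta), pi, tolerance = 1e-9)

  expect_error(pose_to_coordinates(chain, pose_identity(0)), "torsions")
})

test_that("rigid poses preserve all bonded distances", {
  cx <- planted_rigid()
  lig <- cx$topology
  for (k in 1:5) {
    pose <- new_pose(rnorm(3), rnorm(4), numeric(0))
    X <- pose_to_coordinates(lig, pose)
    d0 <- sqrt(rowSums((lig$coords[lig$bonds$i, ] - lig$coords[lig$bonds$j, ])^2))
    d1 <- sqrt(rowSums((X[lig$bonds$i, ] - X[lig$bonds$j, ])^2))
    expect_equal(d1, d0, tolerance = 1e-6)
  }
})

test_that("rmsd_all_atoms matches closed forms and is symmetric", {
  a <- matrix(rnorm(30), ncol = 3)
  expect_equal(rmsd_all_atoms(a, a), 0)
  shift <- a; shift[, 1] <- shift[, 1] + 1
  expect_equal(rmsd_all_atoms(a, shift), 1.0, tolerance = 1e-12)

  # two-atom case by hand: displacements 1 and 2 -> sqrt((1+4)/2)
  p <- rbind(c(0, 0, 0), c(5, 0, 0))
  q <- rbind(c(1, 0, 0), c(5, 2, 0))
  expect_equal(rmsd_all_atoms(p, q), sqrt(5 / 2), tolerance = 1e-12)
  expect_equal(rmsd_all_atoms(q, p), rmsd_all_atoms(p, q))
  expect_error(rmsd_all_atoms(a, a[1:5, ]), "identical")
})

test_that("written ligand files re-read with identical topology counts", {
  cx <- planted_rigid()
  lig <- cx$topology
  sdf <- withr::local_tempfile(fileext = ".sdf")
  write_ligands(lig, sdf)
  back <- read_ligands(sdf)[[1]]
  expect_equal(nrow(back$atoms), nrow(lig$atoms))
  expect_equal(nrow(back$bonds), nrow(lig$bonds))
  expect_equal(nrow(back$torsions), nrow(lig$torsions))
  expect_equal(back$coords, lig$coords, tolerance = 1e-4)
  expect_equal(back$atoms$formal_charge, lig$atoms$formal_charge)
})

test_that("MOL2 records read with their stored charges", {
  mol2 <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c(
    "@<TRIPOS>MOLECULE", "ethanol-frag", " 3 2 1", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "      1 C1          0.0000    0.0000    0.0000 C.3     1  LIG1        0.0300",
    "      2 C2          1.5200    0.0000    0.0000 C.3     1  LIG1        0.0500",
    "      3 O1          2.0400    1.3500    0.0000 O.3     1  LIG1       -0.3800",
    "@<TRIPOS>BOND",
    "     1    1    2 1",
    "     2    2    3 1"), mol2)
  lig <- read_ligands(mol2)[[1]]
  expect_equal(lig$atoms$element, c("C", "C", "O"))
  expect_equal(lig$atoms$charge, c(0.03, 0.05, -0.38))
  expect_equal(nrow(lig$bonds), 2L)
})

test_that("Gasteiger charges respond to electronegativity and formal charge", {
  # methanol-like C-O: oxygen pulls negative charge
  q <- gasteiger_charges(c("C", "O"), tibble::tibble(i = 1L, j = 2L, order = 1L))
  expect_lt(q[2], 0)
  expect_gt(q[1], 0)
  expect_equal(sum(q), 0, tolerance = 1e-12)
  # a formal +1 is conserved
  q2 <- gasteiger_charges(c("N", "C"), tibble::tibble(i = 1L, j = 2L, order = 1L),
                          formal_charges = c(1L, 0L))
  expect_equal(sum(q2), 1, tolerance = 1e-12)
})
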