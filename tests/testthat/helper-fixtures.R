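# Shared fixtures, built in code. Heavier objects (grids, planted complexes)
# are cached per session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# A three-residue peptide (GLY-LYS-GLY) plus a benzamidine-like HETATM ring,
# written as PDB text.
write_test_pdb <- function(path, include_ligand = TRUE, ca_only_resno = NULL,
                           unknown_residue = FALSE) {
  fmt <- function(serial, name, res, chain, resno, x, y, z, el,
                  rec = "ATOM  ") {
    sprintf("%s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            rec, serial, name, res, chain, resno, x, y, z, el)
  }
  lines <- character(0)
  serial <- 1
  add <- function(name, res, resno, x, y, z, el, rec = "ATOM  ") {
    lines <<- c(lines, fmt(serial, name, res, "A", resno, x, y, z, el, rec))
    serial <<- serial + 1
  }
  backbone <- function(res, resno, zoff) {
    add("N", res, resno, 0.0, 0.0, zoff, "N")
    add("CA", res, resno, 1.46, 0.0, zoff, "C")
    add("C", res, resno, 2.0, 1.4, zoff, "C")
    add("O", res, resno, 1.3, 2.4, zoff, "O")
  }
  backbone("GLY", 1, 0)
  if (!is.null(ca_only_resno) && ca_only_resno == 2) {
    add("CA", "LYS", 2, 1.46, 0.0, 4.0, "C")
  } else {
    backbone("LYS", 2, 4.0)
    add("CB", "LYS", 2, 2.0, -1.2, 4.8, "C")
    add("CG", "LYS", 2, 3.5, -1.3, 4.9, "C")
    add("CD", "LYS", 2, 4.1, -2.5, 5.6, "C")
    add("CE", "LYS", 2, 5.6, -2.6, 5.7, "C")
    add("NZ", "LYS", 2, 6.2, -3.8, 6.4, "N")
  }
  backbone("GLY", 3, 8.0)
  if (unknown_residue) {
    add("C1", "XYZ", 4, 9.0, 9.0, 9.0, "C")
  }
  if (include_ligand) {
    ang <- seq(0, 300, 60) * pi / 180
    for (k in seq_along(ang)) {
      add(paste0("C", k), "BEN", 9, 10 + 1.39 * cos(ang[k]),
          10 + 1.39 * sin(ang[k]), 2.0, "C", rec = "HETATM")
    }
    add("C7", "BEN", 9, 12.2, 10.0, 2.0, "C", rec = "HETATM")
    add("N1", "BEN", 9, 12.9, 11.1, 2.0, "N", rec = "HETATM")
    add("N2", "BEN", 9, 12.8, 8.9, 2.0, "N", rec = "HETATM")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

# minimal V2000 records (heavy atoms, rough 3D)
butane_sdf <- function(path) {
  writeLines(c(
    "butane", "  test", "",
    "  4  3  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5300    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0400    1.4400    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.5700    1.4400    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0", "  3  4  1  0",
    "M  END", "$$$$"), path)
  invisible(path)
}

benzene_sdf <- function(path) {
  ang <- seq(0, 300, 60) * pi / 180
  atoms <- sprintf(
    "%10.4f%10.4f%10.4f C   0  0  0  0  0  0  0  0  0  0  0  0",
    1.39 * cos(ang), 1.39 * sin(ang), 0)
  bonds <- sprintf("%3d%3d%3d  0", 1:6, c(2:6, 1), rep(c(2, 1), 3))
  writeLines(c("benzene", "  test", "",
               "  6  6  0  0  0  0  0  0  0  0999 V2000", atoms, bonds,
               "M  END", "$$$$"), path)
  invisible(path)
}

# one molecule, two conformers (second record rotated about the 2-3 bond)
two_conformer_sdf <- function(path) {
  rec <- function(name, z4) {
    c(name, "  test", "",
      "  4  3  0  0  0  0  0  0  0  0999 V2000",
      "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "    1.5300    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      "    2.0400    1.4400    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
      sprintf("    2.2000    2.1000%10.4f O   0  0  0  0  0  0  0  0  0  0  0  0", z4),
      "  1  2  1  0", "  2  3  1  0", "  3  4  1  0",
      "M  END", "$$$$")
  }
  writeLines(c(rec("conf1", 1.1), rec("conf2", -1.1)), path)
  invisible(path)
}

planted_rigid <- function(seed = 11) {
  cached(paste0("planted_", seed), make_planted_complex(0, seed = seed))
}

small_ga <- function(seed = 1, runs = 10) {
  ga_config(population_size = 200, generations = 100,
            independent_runs = runs, seed = seed)
}
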