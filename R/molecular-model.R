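# Molecular model: ligand topologies, receptor preparation, file IO.

# ---- ligand topology ---------------------------------------------------------

#' Build a ligand topology from atoms, bonds and a reference conformer
#'
#' The constructor derives everything the docking engine needs from the raw
#' connection table: ring perception, rotatable-torsion detection (single
#' non-ring bonds between non-terminal heavy atoms; amide C-N excluded),
#' Gasteiger partial charges (unless charges are supplied), per-element
#' Lennard-Jones parameters, and the intramolecular nonbonded pair list
#' (atoms separated by more than three bonds).
#'
#' @param atoms Data frame with at least `element`; optional `charge`
#'   (elementary units; computed by the Gasteiger scheme when absent),
#'   `formal_charge`, and `name`.
#' @param bonds Data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3; 4 is accepted as aromatic).
#' @param coords `n x 3` numeric matrix, the reference conformer (A).
#' @param name Identifier carried through results.
#' @return A `gridock_ligand` object.
#' @export
new_ligand <- function(atoms, bonds, coords, name = "ligand") {
  atoms <- as_tibble(atoms)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(atoms)
  if (n < 1) abort("Ligand must contain at least one atom.")
  if (nrow(coords) != n || ncol(coords) != 3 || !all(is.finite(coords))) {
    abort("`coords` must be a finite n x 3 matrix matching the atom count.")
  }
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- tibble(i = integer(0), j = integer(0), order = integer(0))
  }
  bonds <- as_tibble(bonds)
  if (nrow(bonds) > 0) {
    stopifnot(all(bonds$i >= 1), all(bonds$j <= n), all(bonds$i != bonds$j))
  }
  if (n > 1 && !.graph_connected(n, bonds)) {
    abort("Ligand bond graph must be connected (got a disconnected structure).")
  }
  .check_valence(atoms$element, bonds)

  if (!"formal_charge" %in% names(atoms)) atoms$formal_charge <- 0L
  if (!"name" %in% names(atoms)) atoms$name <- paste0(atoms$element, seq_len(n))
  if (!"charge" %in% names(atoms)) {
    atoms$charge <- gasteiger_charges(atoms$element, bonds, atoms$formal_charge)
  }
  lj <- .lj_lookup(atoms$element)
  atoms$eps <- lj$eps
  atoms$rmin <- lj$rmin

  rings <- .perceive_rings(n, bonds)
  ring_bonds <- .ring_bond_flags(bonds, rings)
  tors <- .rotatable_torsions(atoms$element, bonds, ring_bonds)
  moving <- lapply(seq_len(nrow(tors)), function(k) {
    .moving_set(n, bonds, tors$b[k], tors$c[k])
  })
  pairs <- .nb_pairs(n, bonds)
  qq <- atoms$charge[pairs[, 1]] * atoms$charge[pairs[, 2]]
  peps <- sqrt(atoms$eps[pairs[, 1]] * atoms$eps[pairs[, 2]])
  prmin <- 0.5 * (atoms$rmin[pairs[, 1]] + atoms$rmin[pairs[, 2]])

  structure(list(
    name = name,
    atoms = atoms,
    bonds = bonds,
    coords = coords,
    rings = rings,
    torsions = tors,
    torsion_quads0 = if (nrow(tors) > 0) {
      as.matrix(tors[, c("a", "b", "c", "d")]) - 1L
    } else matrix(integer(0), 0, 4),
    torsion_moving0 = lapply(moving, function(v) as.integer(v - 1L)),
    nb_pairs0 = pairs - 1L,
    nb_qq = qq, nb_eps = peps, nb_rmin = prmin,
    formula = .count_formula(atoms$element)
  ), class = "gridock_ligand")
}

#' @export
print.gridock_ligand <- function(x, ...) {
  cat(sprintf(
    "<gridock_ligand> %s: %d atoms (%d heavy), %d bonds, %d rotatable torsions, %d rings\n",
    x$name, nrow(x$atoms), sum(x$atoms$element != "H"), nrow(x$bonds),
    nrow(x$torsions), length(x$rings)))
  cat(sprintf("  formula %s, net charge %+.2f\n", format_formula(x$formula),
              sum(x$atoms$charge)))
  invisible(x)
}

.graph_connected <- function(n, bonds) {
  adj <- .adjacency(n, bonds)
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

.adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

.max_valence <- c(H = 1, C = 4, N = 4, O = 3, F = 1, P = 6, S = 6,
                  Cl = 1, Br = 1, I = 1, B = 4)

.check_valence <- function(elements, bonds) {
  if (nrow(bonds) == 0) return(invisible(TRUE))
  ord <- ifelse(bonds$order == 4, 1.5, bonds$order)
  val <- numeric(length(elements))
  for (k in seq_len(nrow(bonds))) {
    val[bonds$i[k]] <- val[bonds$i[k]] + ord[k]
    val[bonds$j[k]] <- val[bonds$j[k]] + ord[k]
  }
  mx <- .max_valence[elements]
  bad <- which(!is.na(mx) & val > mx + 1.01) # +1 tolerance for charged atoms
  if (length(bad) > 0) {
    abort(sprintf("Valence error: atom %d (%s) has total bond order %.1f.",
                  bad[1], elements[bad[1]], val[bad[1]]),
          class = "gridock_valence_error")
  }
  invisible(TRUE)
}

# Ring perception: ring bonds are non-bridge edges; explicit rings are
# recovered as the shortest cycle through each ring bond (adequate for the
# fused 5/6-membered systems relevant to stacking detection).
.perceive_rings <- function(n, bonds) {
  if (nrow(bonds) == 0 || n < 3) return(list())
  g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  bridges <- igraph::bridges(g)
  ring_edges <- setdiff(seq_len(nrow(bonds)), as.integer(bridges))
  rings <- list()
  for (k in ring_edges) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
      g, c(bonds$i[k], bonds$j[k])))
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = bonds$i[k], to = bonds$j[k]))$vpath[[1]]
    if (length(sp) >= 3 && length(sp) <= 8) {
      ring <- sort(as.integer(sp))
      if (!any(vapply(rings, identical, logical(1), y = ring))) {
        rings[[length(rings) + 1]] <- ring
      }
    }
  }
  rings
}

.ring_bond_flags <- function(bonds, rings) {
  if (nrow(bonds) == 0) return(logical(0))
  vapply(seq_len(nrow(bonds)), function(k) {
    any(vapply(rings, function(r) bonds$i[k] %in% r && bonds$j[k] %in% r,
               logical(1)))
  }, logical(1))
}

# Rotatable bonds: single, acyclic, both ends bound to >= 1 further heavy
# atom, amide C-N excluded. Returns a tibble of torsion quadruples (a,b,c,d).
.rotatable_torsions <- function(elements, bonds, ring_bonds) {
  out <- tibble(a = integer(0), b = integer(0), c = integer(0), d = integer(0))
  if (nrow(bonds) == 0) return(out)
  adj <- .adjacency(length(elements), bonds)
  heavy <- elements != "H"
  is_amide <- function(ci, ni) {
    if (elements[ci] != "C" || elements[ni] != "N") return(FALSE)
    any(vapply(seq_len(nrow(bonds)), function(k) {
      (bonds$i[k] == ci || bonds$j[k] == ci) && bonds$order[k] == 2 &&
        elements[if (bonds$i[k] == ci) bonds$j[k] else bonds$i[k]] == "O"
    }, logical(1)))
  }
  for (k in seq_len(nrow(bonds))) {
    if (bonds$order[k] != 1 || ring_bonds[k]) next
    b <- bonds$i[k]; c <- bonds$j[k]
    nb_b <- setdiff(adj[[b]], c); nb_c <- setdiff(adj[[c]], b)
    if (!any(heavy[nb_b]) || !any(heavy[nb_c])) next
    if (is_amide(b, c) || is_amide(c, b)) next
    a <- nb_b[heavy[nb_b]][1]
    d <- nb_c[heavy[nb_c]][1]
    out <- bind_rows(out, tibble(a = a, b = b, c = c, d = d))
  }
  out
}

# Atoms on the c-side of bond b-c (the set rotated by the torsion).
.moving_set <- function(n, bonds, b, c) {
  adj <- .adjacency(n, bonds)
  seen <- logical(n); seen[b] <- TRUE; seen[c] <- TRUE
  queue <- c; out <- c
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    out <- c(out, nb)
    queue <- c(queue, nb)
  }
  sort(setdiff(out, c(b)))
}

# Pairs separated by more than three bonds (1-5 and beyond).
.nb_pairs <- function(n, bonds) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (k in seq_len(nrow(bonds))) {
    d[bonds$i[k], bonds$j[k]] <- 1; d[bonds$j[k], bonds$i[k]] <- 1
  }
  for (v in seq_len(n)) { # Floyd-Warshall; ligands are small
    d <- pmin(d, outer(d[, v], d[v, ], `+`))
  }
  idx <- which(upper.tri(d) & d > 3, arr.ind = TRUE)
  unname(as.matrix(idx))
}

.count_formula <- function(elements) {
  tab <- table(elements)
  setNames(as.integer(tab), names(tab))
}

#' @rdname monoisotopic_mz
#' @param formula_counts Named integer vector, element -> count.
#' @export
format_formula <- function(formula_counts) {
  ord <- c("C", "H", setdiff(sort(names(formula_counts)), c("C", "H")))
  ord <- ord[ord %in% names(formula_counts)]
  paste0(vapply(ord, function(e) {
    n <- formula_counts[[e]]
    paste0(e, if (n > 1) n else "")
  }, character(1)), collapse = "")
}

# ---- Gasteiger charges -------------------------------------------------------

#' Gasteiger-Marsili partial charges
#'
#' Iterative partial-equalization of orbital electronegativity (8 damped
#' iterations, damping factor 0.5^k). Hybridization is inferred from bond
#' orders. Formal charges seed the iteration.
#'
#' @param elements Character vector of element symbols.
#' @param bonds Bond data frame (`i`, `j`, `order`).
#' @param formal_charges Integer starting charges (default all zero).
#' @return Numeric vector of partial charges (elementary units).
#' @export
gasteiger_charges <- function(elements, bonds, formal_charges = NULL) {
  n <- length(elements)
  if (is.null(formal_charges)) formal_charges <- rep(0L, n)
  if (n == 1 || nrow(bonds) == 0) return(as.numeric(formal_charges))
  hyb <- rep("sp3", n)
  for (k in seq_len(nrow(bonds))) {
    for (v in c(bonds$i[k], bonds$j[k])) {
      if (bonds$order[k] == 3) hyb[v] <- "sp"
      else if (bonds$order[k] %in% c(2, 4) && hyb[v] != "sp") {
        hyb[v] <- if (hyb[v] == "sp2" && bonds$order[k] == 2) "sp" else "sp2"
      }
    }
  }
  par <- .gasteiger_params()
  key <- ifelse(elements %in% c("H", "F", "Cl", "Br", "I"), elements,
                paste(elements, hyb, sep = "."))
  idx <- match(key, par$key)
  # fall back to the sp3 row, then to carbon sp3
  idx[is.na(idx)] <- match(paste(elements[is.na(idx)], "sp3", sep = "."), par$key)
  idx[is.na(idx)] <- match("C.sp3", par$key)
  a <- par$a[idx]; b <- par$b[idx]; cc <- par$c[idx]
  chi_plus <- a + b + cc
  chi_plus[elements == "H"] <- 20.02
  q <- as.numeric(formal_charges)
  damp <- 1
  for (it in seq_len(8)) {
    damp <- damp * 0.5
    chi <- a + b * q + cc * q^2
    dq <- numeric(n)
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$i[k]; j <- bonds$j[k]
      if (chi[j] > chi[i]) {
        t <- (chi[j] - chi[i]) / chi_plus[i] * damp
        dq[i] <- dq[i] + t; dq[j] <- dq[j] - t
      } else {
        t <- (chi[i] - chi[j]) / chi_plus[j] * damp
        dq[j] <- dq[j] + t; dq[i] <- dq[i] - t
      }
    }
    q <- q + dq
  }
  q
}

# ---- ligand file IO ----------------------------------------------------------

#' Read ligands into topologies
#'
#' Supported formats: SDF (V2000, possibly multi-record; each record,
#' including each conformer of the same molecule, becomes a separate
#' topology), MOL2, and plain-text SMILES (one per line, optional
#' tab-separated name; 3D reference conformers are generated through
#' OpenBabel, requiring the ChemmineOB package).
#'
#' Unparsable records are skipped with a log entry; valence errors raise an
#' error.
#'
#' @param path Input file.
#' @param format One of `"sdf"`, `"mol2"`, `"smiles"`; guessed from the file
#'   extension by default.
#' @return List of `gridock_ligand` objects, with a `log` attribute listing
#'   skipped records.
#' @export
read_ligands <- function(path, format = c("auto", "sdf", "mol2", "smiles")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", mol = "sdf", mol2 = "mol2",
                     smi = "smiles", smiles = "smiles", txt = "smiles",
                     abort(sprintf("Cannot guess ligand format from '%s'.", ext)))
  }
  switch(format,
         sdf = .read_sdf_ligands(path),
         mol2 = .read_mol2_ligands(path),
         smiles = .read_smiles_ligands(path))
}

.read_sdf_ligands <- function(path) {
  str <- ChemmineR::read.SDFstr(path)
  out <- list(); log <- character(0)
  for (k in seq_along(str@a)) {
    rec <- tryCatch(.sdf_record_to_ligand(str@a[[k]], k), error = function(e) e)
    if (inherits(rec, "gridock_valence_error")) rlang::cnd_signal(rec)
    if (inherits(rec, "error")) {
      log <- c(log, sprintf("record %d skipped: %s", k, conditionMessage(rec)))
    } else {
      out[[length(out) + 1]] <- rec
    }
  }
  if (length(log) > 0) inform(paste(log, collapse = "\n"))
  attr(out, "log") <- log
  out
}

.sdf_record_to_ligand <- function(lines, index) {
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || na < 1 || is.na(nb) || length(lines) < 4 + na + max(nb, 0)) {
    stop("invalid counts line")
  }
  atoms_raw <- lines[4 + seq_len(na)]
  coords <- suppressWarnings(t(vapply(atoms_raw, function(l) {
    c(as.numeric(substr(l, 1, 10)), as.numeric(substr(l, 11, 20)),
      as.numeric(substr(l, 21, 30)))
  }, numeric(3))))
  dimnames(coords) <- NULL
  elements <- trimws(substr(atoms_raw, 32, 34))
  if (any(is.na(coords)) || any(elements == "")) stop("malformed atom block")
  bonds <- if (nb > 0) {
    braw <- lines[4 + na + seq_len(nb)]
    tibble(
      i = as.integer(substr(braw, 1, 3)),
      j = as.integer(substr(braw, 4, 6)),
      order = as.integer(substr(braw, 7, 9))
    )
  } else tibble(i = integer(0), j = integer(0), order = integer(0))
  fc <- rep(0L, na)
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(l, 7, nchar(l))), "\\s+")[[1]])
    nset <- f[1]
    for (s in seq_len(nset)) fc[f[2 * s]] <- f[2 * s + 1]
  }
  name <- trimws(lines[1])
  if (name == "") name <- sprintf("mol%03d", index)
  new_ligand(tibble(element = elements, formal_charge = fc), bonds, coords,
             name = name)
}

.read_mol2_ligands <- function(path) {
  m <- bio3d::read.mol2(path)
  recs <- if (inherits(m, "mol2")) list(m) else m
  out <- list()
  for (rec in recs) {
    el <- sub("\\..*$", "", rec$atom$elena)
    el <- sub("^([A-Za-z])([a-z]?).*$", "\\1\\2", el)
    coords <- as.matrix(rec$atom[, c("x", "y", "z")])
    bonds <- tibble(
      i = as.integer(rec$bond$origin),
      j = as.integer(rec$bond$target),
      order = suppressWarnings(as.integer(rec$bond$type))
    )
    bonds$order[is.na(bonds$order)] <- 4L # "ar"/"am" types
    out[[length(out) + 1]] <- new_ligand(
      tibble(element = el, charge = suppressWarnings(as.numeric(rec$atom$charge))),
      bonds, coords, name = rec$name %||% "mol2")
  }
  attr(out, "log") <- character(0)
  out
}

.read_smiles_ligands <- function(path) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort("Reading SMILES requires the ChemmineOB package (OpenBabel bridge).")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list(); log <- character(0)
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[k], "[\t ]+")[[1]]
    smi <- fields[1]
    nm <- if (length(fields) > 1) fields[2] else sprintf("smi%03d", k)
    lig <- tryCatch({
      sdf <- ChemmineOB::convertFormat(
        "SMI", "SDF", paste0(smi, " ", nm),
        options = data.frame(names = "gen3d", args = ""))
      rec <- strsplit(sdf, "\n")[[1]]
      .sdf_record_to_ligand(rec, k)
    }, error = function(e) e)
    if (inherits(lig, "error")) {
      log <- c(log, sprintf("line %d (%s) skipped: %s", k, nm,
                            conditionMessage(lig)))
    } else {
      lig$name <- nm
      out[[length(out) + 1]] <- lig
    }
  }
  if (length(log) > 0) inform(paste(log, collapse = "\n"))
  attr(out, "log") <- log
  out
}

#' Write ligand topologies to an SDF file
#'
#' Writes one V2000 record per topology; partial charges and Lennard-Jones
#' parameters are stored in SDF data fields so a round trip preserves the
#' parameterization.
#'
#' @param ligands List of `gridock_ligand` objects (or a single one).
#' @param path Output file.
#' @param coords Optional list of coordinate matrices overriding each
#'   topology's reference conformer (used to export docked poses).
#' @export
write_ligands <- function(ligands, path, coords = NULL) {
  if (inherits(ligands, "gridock_ligand")) ligands <- list(ligands)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(ligands)) {
    lig <- ligands[[k]]
    xyz <- if (is.null(coords)) lig$coords else coords[[k]]
    lines <- c(
      lig$name, "  gridock", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
              nrow(lig$atoms), nrow(lig$bonds)),
      vapply(seq_len(nrow(lig$atoms)), function(i) {
        sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                xyz[i, 1], xyz[i, 2], xyz[i, 3], lig$atoms$element[i])
      }, character(1)),
      vapply(seq_len(nrow(lig$bonds)), function(i) {
        sprintf("%3d%3d%3d  0", lig$bonds$i[i], lig$bonds$j[i],
                lig$bonds$order[i])
      }, character(1))
    )
    fc <- which(lig$atoms$formal_charge != 0)
    if (length(fc) > 0) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(fc)),
                               paste0(sprintf("%4d%4d", fc,
                                              lig$atoms$formal_charge[fc]),
                                      collapse = "")))
    }
    lines <- c(lines, "M  END",
               "> <partial_charges>",
               paste(sprintf("%.6f", lig$atoms$charge), collapse = " "), "",
               "> <lj_parameters>",
               paste(sprintf("%s:%.4f:%.3f", lig$atoms$element,
                             lig$atoms$eps, lig$atoms$rmin), collapse = " "),
               "", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

# ---- receptor ----------------------------------------------------------------

#' Construct a receptor from an atom table
#'
#' Lower-level constructor used by both the PDB reader and the synthetic
#' fixture generator.
#'
#' @param atoms Data frame with `element`, `x`, `y`, `z` and optionally
#'   `charge`, `residue`, `resno`, `chain`, `atom_name`.
#' @param center_hint Length-3 docking-cube centre suggestion (A); defaults
#'   to the geometric centre of the atoms.
#' @param native Optional tibble of native-ligand atoms.
#' @param log Character vector of preparation log entries.
#' @return A `gridock_receptor`.
#' @export
new_receptor <- function(atoms, center_hint = NULL, native = NULL,
                         log = character(0)) {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) < 1) abort("Receptor must contain at least one atom.")
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  if (!all(is.finite(atoms$charge))) abort("Receptor charges must be finite.")
  if (!"residue" %in% names(atoms)) atoms$residue <- "UNK"
  if (!"resno" %in% names(atoms)) atoms$resno <- 1L
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  if (!"atom_name" %in% names(atoms)) {
    atoms$atom_name <- paste0(atoms$element, seq_len(nrow(atoms)))
  }
  lj <- .lj_lookup(atoms$element)
  atoms$eps <- lj$eps
  atoms$rmin <- lj$rmin
  if (is.null(center_hint)) {
    center_hint <- c(mean(atoms$x), mean(atoms$y), mean(atoms$z))
  }
  structure(list(atoms = atoms, center_hint = as.numeric(center_hint),
                 native = native, log = log),
            class = "gridock_receptor")
}

#' @export
print.gridock_receptor <- function(x, ...) {
  cat(sprintf("<gridock_receptor> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ",")))
  cat(sprintf("  net charge %+.2f; docking-cube centre hint [%.2f, %.2f, %.2f]\n",
              sum(x$atoms$charge), x$center_hint[1], x$center_hint[2],
              x$center_hint[3]))
  if (!is.null(x$native)) {
    cat(sprintf("  native ligand: %s (%d atoms)\n",
                x$native$residue[1], nrow(x$native)))
  }
  invisible(x)
}

receptor_coords <- function(receptor) {
  as.matrix(receptor$atoms[, c("x", "y", "z")])
}

#' Read and prepare a receptor from a PDB file
#'
#' Preparation follows a fixed rule table: water and (undeclared) hetero
#' residues are removed, alternate locations other than "A" are dropped,
#' polar hydrogens are added by geometric rules, and ionizable side chains
#' get their dominant protonation state at the requested pH (at pH 7.4:
#' Asp/Glu anionic, Lys/Arg cationic, His neutral). The native ligand, when
#' declared, is extracted separately and its heavy-atom geometric centre is
#' recorded as the docking-cube centre hint.
#'
#' @param pdb_path Path to a PDB file.
#' @param pH Solution pH in `[0, 14]` (default 7.4).
#' @param native Three-letter residue name of the co-crystallized ligand to
#'   extract (e.g. `"BEN"` for benzamidine), or `NULL`.
#' @return A `gridock_receptor`.
#' @export
read_receptor <- function(pdb_path, pH = 7.4, native = NULL) {
  if (!is.numeric(pH) || pH < 0 || pH > 14) abort("`pH` must be in [0, 14].")
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  at <- pdb$atom
  log <- character(0)

  keep_alt <- is.na(at$alt) | at$alt %in% c("", " ", "A")
  if (any(!keep_alt)) {
    log <- c(log, sprintf("dropped %d alternate-location atoms", sum(!keep_alt)))
  }
  at <- at[keep_alt, , drop = FALSE]

  native_tbl <- NULL
  center_hint <- NULL
  if (!is.null(native)) {
    nat <- at[at$resid == native, , drop = FALSE]
    if (nrow(nat) > 0) {
      el <- .element_from_pdb(nat)
      heavy <- el != "H"
      native_tbl <- tibble(element = el, x = nat$x, y = nat$y, z = nat$z,
                           atom_name = trimws(nat$elety),
                           residue = nat$resid, resno = nat$resno,
                           chain = nat$chain)
      center_hint <- c(mean(nat$x[heavy]), mean(nat$y[heavy]),
                       mean(nat$z[heavy]))
      log <- c(log, sprintf("extracted native ligand %s (%d atoms)", native,
                            nrow(nat)))
      at <- at[at$resid != native, , drop = FALSE]
    }
  }

  is_water <- at$resid %in% .water_residues
  if (any(is_water)) log <- c(log, sprintf("removed %d water atoms", sum(is_water)))
  at <- at[!is_water, , drop = FALSE]

  het <- at$type == "HETATM"
  if (any(het)) {
    log <- c(log, sprintf("removed hetero residues: %s",
                          paste(unique(at$resid[het]), collapse = ", ")))
    at <- at[!het, , drop = FALSE]
  }

  unknown <- !(at$resid %in% .standard_residues)
  if (any(unknown)) {
    for (r in unique(paste(at$resid[unknown], at$resno[unknown]))) {
      warn(sprintf("Unknown residue %s skipped.", r))
      log <- c(log, sprintf("skipped unknown residue %s", r))
    }
    at <- at[!unknown, , drop = FALSE]
  }
  if (nrow(at) == 0) abort("No standard protein atoms left after filtering.")

  # completeness: every standard residue needs its full backbone
  res_key <- paste(at$chain, at$resno)
  for (rk in unique(res_key)) {
    sel <- res_key == rk
    names_here <- trimws(at$elety[sel])
    missing <- setdiff(c("N", "CA", "C", "O"), names_here)
    if (length(missing) > 0) {
      abort(sprintf("missing atoms in residue %s %s (chain %s): %s",
                    at$resid[sel][1], at$resno[sel][1], at$chain[sel][1],
                    paste(missing, collapse = ", ")))
    }
  }

  atoms <- tibble(
    element = .element_from_pdb(at),
    x = at$x, y = at$y, z = at$z,
    atom_name = trimws(at$elety),
    residue = at$resid, resno = at$resno, chain = at$chain
  )
  atoms <- .add_polar_hydrogens(atoms)
  atoms$charge <- .assign_receptor_charges(atoms, pH)
  log <- c(log, sprintf("protonated at pH %.1f; %d polar hydrogens present",
                        pH, sum(atoms$element == "H")))

  new_receptor(atoms, center_hint = center_hint, native = native_tbl,
               log = log)
}

.element_from_pdb <- function(at) {
  el <- trimws(at$elesy)
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    guess <- sub("^[0-9]*", "", trimws(at$elety[miss]))
    el[miss] <- substr(guess, 1, 1)
  }
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 10)))
  el
}

# Add polar hydrogens by rule: one H per backbone amide nitrogen (except
# proline), plus side-chain donors per residue. Hydrogens are placed 1.0 A
# from the donor, directed away from the mean of its bonded heavy neighbours.
.add_polar_hydrogens <- function(atoms) {
  if (any(atoms$element == "H")) return(atoms) # already protonated
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rules <- .polar_h_rules()
  newH <- list()
  add_h <- function(i, count) {
    p <- xyz[i, ]
    d2 <- rowSums((xyz - matrix(p, nrow(xyz), 3, byrow = TRUE))^2)
    nb <- which(d2 > 1e-6 & d2 < 1.8^2 & atoms$element != "H")
    dir <- if (length(nb) == 0) c(0, 0, 1) else {
      v <- -colSums(xyz[nb, , drop = FALSE] -
                      matrix(p, length(nb), 3, byrow = TRUE))
      if (sqrt(sum(v^2)) < 1e-6) c(0, 0, 1) else v / sqrt(sum(v^2))
    }
    perp <- c(-dir[2], dir[1], 0)
    if (sqrt(sum(perp^2)) < 1e-6) perp <- c(1, 0, 0)
    perp <- perp / sqrt(sum(perp^2))
    perp2 <- c(dir[2] * perp[3] - dir[3] * perp[2],
               dir[3] * perp[1] - dir[1] * perp[3],
               dir[1] * perp[2] - dir[2] * perp[1])
    for (k in seq_len(count)) {
      ang <- 2 * pi * (k - 1) / max(count, 1)
      v <- dir + if (count > 1) 0.7 * (cos(ang) * perp + sin(ang) * perp2) else 0
      v <- v / sqrt(sum(v^2))
      hname <- if (count == 1) {
        if (atoms$atom_name[i] == "N") "H" else paste0("H", substring(atoms$atom_name[i], 2))
      } else paste0("H", substring(atoms$atom_name[i], 2), k)
      newH[[length(newH) + 1]] <<- tibble(
        element = "H", x = p[1] + v[1], y = p[2] + v[2], z = p[3] + v[3],
        atom_name = hname, residue = atoms$residue[i],
        resno = atoms$resno[i], chain = atoms$chain[i])
    }
  }
  for (i in seq_len(nrow(atoms))) {
    res <- atoms$residue[i]; an <- atoms$atom_name[i]
    if (an == "N" && res != "PRO") add_h(i, 1L)
    r <- rules[[res]]
    if (!is.null(r) && an %in% names(r)) add_h(i, as.integer(r[[an]]))
  }
  if (length(newH) > 0) atoms <- bind_rows(atoms, bind_rows(newH))
  atoms
}

# Rule-table protonation charges. pH enters through simple pKa switches so
# that non-physiological pH values flip the expected groups.
.assign_receptor_charges <- function(atoms, pH) {
  tmpl <- .residue_charges()
  q <- rep(0, nrow(atoms))
  bb <- tmpl$backbone
  hit <- match(atoms$atom_name, names(bb))
  q[!is.na(hit)] <- bb[hit[!is.na(hit)]]
  asp_on <- pH > 3.9; glu_on <- pH > 4.1
  lys_on <- pH < 10.5; arg_on <- pH < 12.5; his_on <- pH < 6.0
  for (i in seq_len(nrow(atoms))) {
    res <- atoms$residue[i]
    t <- tmpl[[res]]
    if (is.null(t)) next
    an <- atoms$atom_name[i]
    if (!an %in% names(t)) next
    use <- switch(res,
                  ASP = asp_on, GLU = glu_on, LYS = lys_on, ARG = arg_on,
                  TRUE)
    if (res == "HIS" && his_on) {
      # cationic imidazolium below pKa: both ring nitrogens protonated
      q[i] <- switch(an, ND1 = 0.2, NE2 = 0.2, HE2 = 0.3, 0)
      next
    }
    if (isTRUE(use)) q[i] <- t[[an]]
  }
  q
}

#' Write a prepared receptor to PDB
#'
#' @param receptor A `gridock_receptor`.
#' @param path Output PDB path.
#' @export
write_receptor <- function(receptor, path) {
  a <- receptor$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$residue, elety = a$atom_name,
    chain = a$chain, elesy = a$element, o = rep(1, nrow(a)),
    b = rep(0, nrow(a))
  )
  invisible(path)
}
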