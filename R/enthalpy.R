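# Thermodynamic-cycle binding enthalpy with pluggable enthalpy backends.
#
# dH_bind = dH(complex) - (dH(protein) + dH(ligand))
#
# dH(protein) uses the same (fixed) conformation as docking; dH(ligand) is
# the minimum backend enthalpy over the supplied unbound conformers;
# dH(complex) is evaluated after local optimization of all ligand atom
# positions in the rigid receptor.

#' Enthalpy backends
#'
#' A backend maps a molecular system (a list of molecules, each with
#' coordinates and parameters) to an enthalpy of formation in kcal/mol. The
#' builtin force-field backend uses the same Coulomb/Lennard-Jones terms as
#' the grid module, computed pairwise with a switched 10--12 A cutoff, plus
#' harmonic bond and 1-3 restraints for the ligand; the rigid receptor's
#' internal enthalpy is defined as the zero of the cycle (it is identical in
#' the complex and protein terms, so it cancels exactly). The backend is
#' size-consistent: infinitely separated fragments contribute additively.
#'
#' `external_backend()` adapts any external program that reads an XYZ file
#' and prints a single enthalpy (kcal/mol) on stdout, for use with
#' semiempirical quantum-chemistry engines when one is installed.
#'
#' @param cutoff,switch_start Nonbonded cutoff and switching start (A).
#' @param interior_dielectric Dielectric for the Coulomb term.
#' @param k_bond,k_13 Harmonic restraint constants (kcal/mol/A^2).
#' @return A `gridock_backend`.
#' @export
forcefield_backend <- function(cutoff = 12, switch_start = 10,
                               interior_dielectric = 1,
                               k_bond = 300, k_13 = 60) {
  force(cutoff); force(switch_start); force(interior_dielectric)
  be <- list(
    name = "builtin-forcefield",
    supports_gradient = TRUE,
    cutoff = cutoff, switch_start = switch_start,
    interior_dielectric = interior_dielectric,
    k_bond = k_bond, k_13 = k_13
  )
  be$evaluate <- function(molecules) {
    .ff_system_energy(molecules, be)$energy
  }
  structure(be, class = "gridock_backend")
}

#' @rdname forcefield_backend
#' @param command Path to an executable invoked as `command input.xyz`; must
#'   print the enthalpy of formation (kcal/mol) as the last whitespace
#'   -separated token of its output.
#' @export
external_backend <- function(command) {
  if (Sys.which(command) == "" && !file.exists(command)) {
    abort(sprintf("External enthalpy program '%s' not found.", command))
  }
  be <- list(name = paste0("external:", basename(command)),
             supports_gradient = FALSE, command = command)
  be$evaluate <- function(molecules) {
    xyz <- tempfile(fileext = ".xyz")
    on.exit(unlink(xyz))
    el <- unlist(lapply(molecules, function(m) m$elements))
    X <- do.call(rbind, lapply(molecules, function(m) m$coords))
    writeLines(c(length(el), "gridock",
                 sprintf("%-2s %12.6f %12.6f %12.6f", el, X[, 1], X[, 2],
                         X[, 3])), xyz)
    out <- tryCatch(system2(command, xyz, stdout = TRUE, stderr = TRUE),
                    error = function(e) {
                      abort(sprintf("Backend '%s' failed: %s", be$name,
                                    conditionMessage(e)))
                    })
    toks <- strsplit(paste(out, collapse = " "), "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(toks[length(toks)]))
    if (!is.finite(val)) {
      abort(sprintf("Backend '%s' returned no numeric enthalpy; output: %s",
                    be$name, paste(utils::tail(out, 3), collapse = " | ")))
    }
    val
  }
  structure(be, class = "gridock_backend")
}

# Molecule descriptor used by the builtin backend.
.ff_molecule <- function(coords, charges, eps, rmin, elements,
                         bonds = NULL, nb_pairs0 = NULL, nb_qq = NULL,
                         nb_eps = NULL, nb_rmin = NULL, r0_bond = NULL,
                         r0_13 = NULL, pairs13 = NULL) {
  list(coords = as.matrix(coords), charges = charges, eps = eps, rmin = rmin,
       elements = elements, bonds = bonds, nb_pairs0 = nb_pairs0,
       nb_qq = nb_qq, nb_eps = nb_eps, nb_rmin = nb_rmin,
       r0_bond = r0_bond, r0_13 = r0_13, pairs13 = pairs13)
}

ff_molecule_from_ligand <- function(topology, coords = NULL) {
  X <- if (is.null(coords)) topology$coords else as.matrix(coords)
  b <- topology$bonds
  pairs13 <- .pairs_13(nrow(topology$atoms), b)
  r0b <- if (nrow(b) > 0) {
    sqrt(rowSums((topology$coords[b$i, , drop = FALSE] -
                    topology$coords[b$j, , drop = FALSE])^2))
  } else numeric(0)
  r013 <- if (nrow(pairs13) > 0) {
    sqrt(rowSums((topology$coords[pairs13[, 1], , drop = FALSE] -
                    topology$coords[pairs13[, 2], , drop = FALSE])^2))
  } else numeric(0)
  .ff_molecule(X, topology$atoms$charge, topology$atoms$eps,
               topology$atoms$rmin, topology$atoms$element,
               bonds = cbind(b$i, b$j), nb_pairs0 = topology$nb_pairs0,
               nb_qq = topology$nb_qq, nb_eps = topology$nb_eps,
               nb_rmin = topology$nb_rmin, r0_bond = r0b, r0_13 = r013,
               pairs13 = pairs13)
}

ff_molecule_from_receptor <- function(receptor) {
  a <- receptor$atoms
  .ff_molecule(receptor_coords(receptor), a$charge, a$eps, a$rmin, a$element)
}

.pairs_13 <- function(n, bonds) {
  if (nrow(bonds) == 0) return(matrix(integer(0), 0, 2))
  adj <- .adjacency(n, bonds)
  out <- list()
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      for (k in seq_len(ncol(cmb))) out[[length(out) + 1]] <- cmb[, k]
    }
  }
  if (length(out) == 0) return(matrix(integer(0), 0, 2))
  m <- unique(do.call(rbind, out))
  # drop pairs that are also bonded (3-membered rings)
  bonded <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  m[!(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])) %in% bonded), ,
    drop = FALSE]
}

# CHARMM-style switching function and derivative factor.
.switch_fn <- function(r, r_on, r_off) {
  s <- rep(1, length(r))
  s[r >= r_off] <- 0
  mid <- r > r_on & r < r_off
  if (any(mid)) {
    r2 <- r[mid]^2; ron2 <- r_on^2; roff2 <- r_off^2
    s[mid] <- (roff2 - r2)^2 * (roff2 + 2 * r2 - 3 * ron2) / (roff2 - ron2)^3
  }
  s
}

.switch_dfn <- function(r, r_on, r_off) {
  d <- rep(0, length(r))
  mid <- r > r_on & r < r_off
  if (any(mid)) {
    r2 <- r[mid]^2; ron2 <- r_on^2; roff2 <- r_off^2
    d[mid] <- 12 * r[mid] * (roff2 - r2) * (ron2 - r2) / (roff2 - ron2)^3
  }
  d
}

# Pairwise Coulomb + LJ between two coordinate sets with switching; returns
# energy and (optionally) the gradient on the first set.
.ff_pair_energy <- function(X1, q1, e1, rm1, X2, q2, e2, rm2, be,
                            gradient = FALSE) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  dx <- outer(X1[, 1], X2[, 1], `-`)
  dy <- outer(X1[, 2], X2[, 2], `-`)
  dz <- outer(X1[, 3], X2[, 3], `-`)
  r2 <- dx^2 + dy^2 + dz^2
  r2[r2 < 0.01] <- 0.01
  r <- sqrt(r2)
  qq <- outer(q1, q2)
  ee <- sqrt(outer(e1, e2))
  rm <- 0.5 * outer(rm1, rm2, `+`)
  s6 <- (rm^2 / r2)^3
  u_c <- .kcoulomb * qq / (be$interior_dielectric * r)
  u_lj <- ee * (s6^2 - 2 * s6)
  sw <- .switch_fn(r, be$switch_start, be$cutoff)
  u <- (u_c + u_lj) * sw
  if (!gradient) return(list(energy = sum(u)))
  # d(u)/dr = (du_c/dr + du_lj/dr)*sw + (u_c+u_lj)*dsw/dr
  du <- (-u_c / r - 12 * ee / r * (s6^2 - s6)) * sw +
    (u_c + u_lj) * .switch_dfn(r, be$switch_start, be$cutoff)
  f <- du / r
  g <- cbind(rowSums(f * dx), rowSums(f * dy), rowSums(f * dz))
  list(energy = sum(u), gradient = g)
}

# Intramolecular ligand energy: bond + 1-3 restraints + >3-bond nonbonded.
.ff_intra_energy <- function(mol, be, gradient = FALSE) {
  X <- mol$coords
  n <- nrow(X)
  e <- 0
  g <- if (gradient) matrix(0, n, 3) else NULL
  pair_term <- function(idx, fun_e, fun_du) {
    if (is.null(idx) || nrow(idx) == 0) return(invisible(NULL))
    i <- idx[, 1]; j <- idx[, 2]
    d <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    r <- sqrt(pmax(rowSums(d^2), 1e-4))
    e <<- e + sum(fun_e(r))
    if (gradient) {
      f <- fun_du(r) / r
      gi <- f * d
      for (k in 1:3) {
        add <- tapply(c(gi[, k], -gi[, k]), c(i, j), sum)
        at <- as.integer(names(add))
        g[at, k] <<- g[at, k] + add
      }
    }
  }
  if (!is.null(mol$bonds) && nrow(mol$bonds) > 0) {
    r0 <- mol$r0_bond
    pair_term(mol$bonds,
              function(r) be$k_bond * (r - r0)^2,
              function(r) 2 * be$k_bond * (r - r0))
  }
  if (!is.null(mol$pairs13) && nrow(mol$pairs13) > 0) {
    r013 <- mol$r0_13
    pair_term(mol$pairs13,
              function(r) be$k_13 * (r - r013)^2,
              function(r) 2 * be$k_13 * (r - r013))
  }
  if (!is.null(mol$nb_pairs0) && nrow(mol$nb_pairs0) > 0) {
    idx <- mol$nb_pairs0 + 1L
    qq <- mol$nb_qq; ee <- mol$nb_eps; rm <- mol$nb_rmin
    i <- idx[, 1]; j <- idx[, 2]
    d <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    r2 <- pmax(rowSums(d^2), 0.01)
    r <- sqrt(r2)
    s6 <- (rm^2 / r2)^3
    u <- .kcoulomb * qq / (be$interior_dielectric * r) + ee * (s6^2 - 2 * s6)
    e <- e + sum(u)
    if (gradient) {
      du <- -.kcoulomb * qq / (be$interior_dielectric * r2) -
        12 * ee / r * (s6^2 - s6)
      f <- du / r
      gi <- f * d
      for (k in 1:3) {
        add <- tapply(c(gi[, k], -gi[, k]), c(i, j), sum)
        at <- as.integer(names(add))
        g[at, k] <- g[at, k] + add
      }
    }
  }
  list(energy = e, gradient = g)
}

.ff_system_energy <- function(molecules, be) {
  e <- 0
  for (m in molecules) e <- e + .ff_intra_energy(m, be)$energy
  if (length(molecules) > 1) {
    for (i in seq_along(molecules)) {
      for (j in seq_along(molecules)) {
        if (j <= i) next
        mi <- molecules[[i]]; mj <- molecules[[j]]
        e <- e + .ff_pair_energy(mi$coords, mi$charges, mi$eps, mi$rmin,
                                 mj$coords, mj$charges, mj$eps, mj$rmin,
                                 be)$energy
      }
    }
  }
  list(energy = e)
}

#' Local optimization of the bound ligand
#'
#' Gradient-based (L-BFGS-B) minimization of the complex energy over all
#' ligand Cartesian coordinates with the receptor fixed, mirroring the
#' complex-relaxation step of the enthalpy cycle. Terminates at a projected
#' gradient below `gtol` or after `max_steps` iterations; the returned
#' coordinates never have higher energy than the start.
#'
#' @param forcefield A builtin `gridock_backend` (from
#'   [forcefield_backend()]); gradient support is required.
#' @param receptor A `gridock_receptor`.
#' @param topology A `gridock_ligand`.
#' @param start_pose A `gridock_pose` from docking, or `NULL` when
#'   `start_coords` is given.
#' @param start_coords Optional explicit starting coordinates.
#' @param centre Pose anchoring centre (the docking-cube centre for docked
#'   poses).
#' @param gtol Gradient-norm termination threshold (kcal/mol/A).
#' @param max_steps Iteration cap.
#' @return List with `coords`, `energy`, `start_energy`, `converged`.
#' @export
local_optimize_ligand <- function(forcefield, receptor, topology,
                                  start_pose = NULL, start_coords = NULL,
                                  centre = NULL, gtol = 1e-3,
                                  max_steps = 2000) {
  stopifnot(inherits(forcefield, "gridock_backend"))
  if (!isTRUE(forcefield$supports_gradient)) {
    abort("local_optimize_ligand requires a gradient-capable backend.")
  }
  if (is.null(start_coords)) {
    if (is.null(start_pose)) abort("Provide `start_pose` or `start_coords`.")
    start_coords <- pose_to_coordinates(topology, start_pose, centre = centre)
  }
  start_coords <- as.matrix(start_coords)
  lig0 <- ff_molecule_from_ligand(topology, start_coords)
  # restrict the receptor to atoms near the ligand (constant-energy remainder)
  rxyz <- receptor_coords(receptor)
  near <- which(apply(rxyz, 1, function(p) {
    min(colSums((t(start_coords) - p)^2)) < (forcefield$cutoff + 4)^2
  }))
  a <- receptor$atoms[near, , drop = FALSE]
  Xr <- rxyz[near, , drop = FALSE]

  energy_grad <- function(xvec, want_grad) {
    X <- matrix(xvec, ncol = 3)
    mol <- lig0; mol$coords <- X
    intra <- .ff_intra_energy(mol, forcefield, gradient = want_grad)
    if (nrow(Xr) > 0) {
      inter <- .ff_pair_energy(X, lig0$charges, lig0$eps, lig0$rmin,
                               Xr, a$charge, a$eps, a$rmin, forcefield,
                               gradient = want_grad)
    } else inter <- list(energy = 0, gradient = matrix(0, nrow(X), 3))
    e <- intra$energy + inter$energy
    if (!want_grad) return(e)
    list(energy = e, gradient = as.numeric(intra$gradient + inter$gradient))
  }
  e0 <- energy_grad(as.numeric(start_coords), FALSE)
  if (!is.finite(e0)) abort("clashed start pose: non-finite starting energy")
  fit <- stats::optim(
    as.numeric(start_coords),
    fn = function(x) energy_grad(x, FALSE),
    gr = function(x) energy_grad(x, TRUE)$gradient,
    method = "L-BFGS-B",
    control = list(maxit = max_steps, pgtol = gtol, factr = 10))
  if (fit$value <= e0) {
    X <- matrix(fit$par, ncol = 3)
    ef <- fit$value
  } else {
    X <- start_coords
    ef <- e0
  }
  dimnames(X) <- NULL
  list(coords = X, energy = ef, start_energy = e0,
       converged = fit$convergence == 0)
}

#' Thermodynamic-cycle binding enthalpy
#'
#' Computes `dH_bind = dH_complex - (dH_protein + dH_ligand)` where
#' `dH_ligand` is the minimum backend enthalpy over the supplied unbound
#' conformers, `dH_protein` uses the docking conformation of the receptor,
#' and `dH_complex` is evaluated at the (locally optimized) bound ligand
#' coordinates.
#'
#' @param backend A `gridock_backend`.
#' @param receptor A `gridock_receptor`.
#' @param topology A `gridock_ligand`.
#' @param optimized_coords Bound-ligand coordinates (from
#'   [local_optimize_ligand()]).
#' @param unbound_conformers List of ligand coordinate matrices; at least one.
#' @return A `gridock_enthalpy` report.
#' @export
binding_enthalpy <- function(backend, receptor, topology, optimized_coords,
                             unbound_conformers) {
  stopifnot(inherits(backend, "gridock_backend"))
  if (length(unbound_conformers) < 1) {
    abort("At least one unbound ligand conformer is required.")
  }
  rec <- ff_molecule_from_receptor(receptor)
  ligb <- ff_molecule_from_ligand(topology, optimized_coords)
  ev <- function(mols) {
    tryCatch(backend$evaluate(mols), error = function(e) {
      abort(sprintf("Enthalpy backend '%s' failed: %s", backend$name,
                    conditionMessage(e)))
    })
  }
  dh_complex <- ev(list(rec, ligb))
  dh_protein <- ev(list(rec))
  lig_vals <- map_dbl(unbound_conformers, function(Xc) {
    ev(list(ff_molecule_from_ligand(topology, Xc)))
  })
  dh_ligand <- min(lig_vals)
  structure(list(
    dH_complex = dh_complex, dH_protein = dh_protein, dH_ligand = dh_ligand,
    dH_bind = dh_complex - (dh_protein + dh_ligand),
    conformer_enthalpies = lig_vals,
    optimized_ligand_coords = as.matrix(optimized_coords),
    backend = backend$name, ligand = topology$name
  ), class = "gridock_enthalpy")
}

#' @export
print.gridock_enthalpy <- function(x, ...) {
  cat(sprintf("<gridock_enthalpy> %s [%s]\n", x$ligand, x$backend))
  cat(sprintf("  dH_complex %.3f | dH_protein %.3f | dH_ligand %.3f\n",
              x$dH_complex, x$dH_protein, x$dH_ligand))
  cat(sprintf("  dH_bind = %.3f kcal/mol\n", x$dH_bind))
  invisible(x)
}

#' @export
tidy.gridock_enthalpy <- function(x, ...) {
  tibble(term = c("dH_complex", "dH_protein", "dH_ligand", "dH_bind"),
         value = c(x$dH_complex, x$dH_protein, x$dH_ligand, x$dH_bind))
}

#' @export
glance.gridock_enthalpy <- function(x, ...) {
  tibble(ligand = x$ligand, backend = x$backend, dH_bind = x$dH_bind,
         n_conformers = length(x$conformer_enthalpies))
}
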