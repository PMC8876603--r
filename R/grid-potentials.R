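# Precomputed interaction grids on the docking cube.
#
# Three potential families are tabulated at every node: electrostatic
# (kcal/(mol e), Coulomb with interior dielectric), Van der Waals (kcal/mol,
# Lennard-Jones 12-6 per probe element, Lorentz-Berthelot combination), and a
# generalized-Born desolvation penalty (kcal/mol per unit charge squared,
# Hawkins-Cramer-Truhlar pairwise descreening). Ligand energies interpolate
# the maps trilinearly. Node values are stored through a soft saturation
# g(E): exact below a documented threshold, smoothly compressed above it and
# bounded by the cap, so that grid and direct evaluation agree wherever the
# potential is physically meaningful while the search landscape stays finite.

#' Docking-cube grid configuration
#'
#' @param center Length-3 cube centre (A), typically the receptor's
#'   `center_hint` (geometric centre of the native ligand).
#' @param edge Cube edge length (A). Default 22.
#' @param spacing Node spacing (A). Default 0.22. `edge / spacing` must be an
#'   integer (within 1e-9); the node count per axis is `edge/spacing + 1`.
#' @param interior_dielectric,solvent_dielectric Dielectric constants of the
#'   protein interior and the solvent; defaults 1 and 78.5.
#' @param probe_elements Elements to tabulate Van der Waals maps for.
#' @param cap Saturation bound for stored node values (kcal/mol); default 1000.
#' @param cap_start_elec,cap_start_vdw Thresholds below which node values are
#'   stored exactly (kcal/mol); defaults 200 and 50.
#' @param born_radius Intrinsic Born radius of the unit probe charge (A).
#' @param hct_scale Descreening scale factor applied to receptor radii.
#' @param outside_penalty Energy added per ligand atom outside the cube.
#' @return A `gridock_grid_config`.
#' @export
grid_config <- function(center, edge = 22, spacing = 0.22,
                        interior_dielectric = 1, solvent_dielectric = 78.5,
                        probe_elements = c("H", "C", "N", "O", "S", "F",
                                           "Cl", "Br", "Du"),
                        cap = 1000, cap_start_elec = 200, cap_start_vdw = 50,
                        born_radius = 1.5, hct_scale = 0.8,
                        outside_penalty = 1e6) {
  stopifnot(edge > 0, spacing > 0)
  ratio <- edge / spacing
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort(sprintf("edge/spacing = %.12f is not an integer node count.", ratio))
  }
  structure(list(center = as.numeric(center), edge = edge, spacing = spacing,
                 interior_dielectric = interior_dielectric,
                 solvent_dielectric = solvent_dielectric,
                 probe_elements = probe_elements, cap = cap,
                 cap_start_elec = cap_start_elec, cap_start_vdw = cap_start_vdw,
                 born_radius = born_radius, hct_scale = hct_scale,
                 outside_penalty = outside_penalty,
                 n_nodes = as.integer(round(ratio)) + 1L),
            class = "gridock_grid_config")
}

.grid_origin <- function(config) config$center - config$edge / 2

.grid_tau <- function(config) {
  .kborn * (1 / config$interior_dielectric - 1 / config$solvent_dielectric)
}

#' Precompute interaction grids for a receptor
#'
#' Tabulates the electrostatic, per-element Van der Waals, and desolvation
#' potentials of the rigid receptor at every node of the docking cube.
#'
#' @param receptor A parameterized `gridock_receptor`.
#' @param config A `gridock_grid_config`.
#' @param margin Warn when the cube extends further than this (A) beyond the
#'   receptor bounding box on any side. Default 10.
#' @return A `gridock_grid`.
#' @export
build_grids <- function(receptor, config, margin = 10) {
  stopifnot(inherits(receptor, "gridock_receptor"),
            inherits(config, "gridock_grid_config"))
  a <- receptor$atoms
  rxyz <- receptor_coords(receptor)
  origin <- .grid_origin(config)
  hi <- origin + config$edge
  box_lo <- c(min(a$x), min(a$y), min(a$z))
  box_hi <- c(max(a$x), max(a$y), max(a$z))
  if (any(origin < box_lo - margin) || any(hi > box_hi + margin)) {
    warn("Docking cube extends well beyond the receptor bounding region.")
  }
  probes <- .lj_lookup(config$probe_elements)
  n <- rep(config$n_nodes, 3)
  maps <- cpp_build_maps(rxyz, a$charge, a$eps, a$rmin, origin,
                         config$spacing, as.integer(n),
                         probes$eps, probes$rmin,
                         config$interior_dielectric, .grid_tau(config),
                         config$born_radius, config$hct_scale, config$cap,
                         config$cap_start_elec, config$cap_start_vdw)
  colnames(maps$vdw_rep) <- config$probe_elements
  colnames(maps$vdw_att) <- config$probe_elements
  structure(list(config = config, origin = origin, n = as.integer(n),
                 elec = maps$elec, vdw_rep = maps$vdw_rep,
                 vdw_att = maps$vdw_att, desolv = maps$desolv,
                 version = "gridock-grid-1"),
            class = "gridock_grid")
}

#' @export
print.gridock_grid <- function(x, ...) {
  cat(sprintf(
    "<gridock_grid> %d x %d x %d nodes, edge %.2f A, spacing %.2f A\n",
    x$n[1], x$n[2], x$n[3], x$config$edge, x$config$spacing))
  cat(sprintf("  centre [%.2f, %.2f, %.2f]; VdW probes: %s\n",
              x$config$center[1], x$config$center[2], x$config$center[3],
              paste(x$config$probe_elements, collapse = ", ")))
  invisible(x)
}

# Map each ligand element to its probe column (0-based for C++).
.vdw_columns <- function(grid, elements) {
  col <- match(elements, colnames(grid$vdw_rep))
  if (anyNA(col)) {
    miss <- unique(elements[is.na(col)])
    cfall <- match("C", colnames(grid$vdw_rep))
    warn(paste0("No VdW probe map for element(s) ",
                paste(miss, collapse = ", "), "; using the carbon map."))
    col[is.na(col)] <- cfall
  }
  as.integer(col - 1L)
}

#' Protein--ligand interaction energy from the grids
#'
#' Sums, over ligand atoms, the trilinearly interpolated electrostatic
#' potential times the atom charge, the Van der Waals map of the atom's
#' element, and the desolvation map times charge squared. Atoms outside the
#' cube each add the configured penalty.
#'
#' @param grid A `gridock_grid`.
#' @param coords `n x 3` ligand coordinates (A).
#' @param charges Ligand partial charges.
#' @param elements Ligand element symbols (select the VdW probe maps).
#' @param per_atom Return the per-atom decomposition instead of the sum.
#' @return Interaction energy in kcal/mol.
#' @export
grid_energy <- function(grid, coords, charges, elements, per_atom = FALSE) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) abort("Empty coordinate set.")
  stopifnot(nrow(coords) == length(charges),
            nrow(coords) == length(elements))
  e <- cpp_grid_energy(grid$elec, grid$vdw_rep, grid$vdw_att, grid$desolv,
                       grid$origin, grid$config$spacing, grid$n, coords,
                       as.numeric(charges), .vdw_columns(grid, elements),
                       grid$config$outside_penalty,
                       grid$config$cap_start_vdw, grid$config$cap)
  if (per_atom) e else sum(e)
}

#' Exact (ungridded) interaction energy
#'
#' Direct pairwise evaluation of the identical Coulomb, Lennard-Jones and
#' desolvation terms used to build the grids, without interpolation. Serves
#' as the oracle for grid accuracy.
#'
#' @param receptor A `gridock_receptor`.
#' @inheritParams grid_energy
#' @param config A `gridock_grid_config` supplying dielectric/cap settings.
#' @export
direct_energy <- function(receptor, coords, charges, elements,
                          config = grid_config(receptor$center_hint),
                          per_atom = FALSE) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) abort("Empty coordinate set.")
  a <- receptor$atoms
  lj <- .lj_lookup(elements)
  e <- cpp_direct_energy(receptor_coords(receptor), a$charge, a$eps, a$rmin,
                         coords, as.numeric(charges), lj$eps, lj$rmin,
                         config$interior_dielectric, .grid_tau(config),
                         config$born_radius, config$hct_scale, config$cap,
                         config$cap_start_elec, config$cap_start_vdw)
  if (per_atom) e else sum(e)
}

#' Save or load a potential grid
#'
#' The container stores a version tag, the full configuration (centre, edge,
#' spacing, probe list, dielectric and cap settings) and the raw per-node
#' arrays; a round trip is exact.
#'
#' @param grid A `gridock_grid`.
#' @param path File path.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "gridock_grid"))
  saveRDS(grid, path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  grid <- readRDS(path)
  if (!inherits(grid, "gridock_grid") ||
      !identical(grid$version, "gridock-grid-1")) {
    abort("File does not contain a gridock potential grid (version 1).")
  }
  grid
}

#' Plot a slice through a potential grid
#'
#' @param object A `gridock_grid`.
#' @param map Which map to slice: "elec", "desolv", or a probe element name.
#' @param z Slice height (A); defaults to the cube centre.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gridock_grid <- function(object, map = "elec", z = NULL, ...) {
  nz <- object$n[3]
  if (is.null(z)) z <- object$config$center[3]
  iz <- round((z - object$origin[3]) / object$config$spacing)
  iz <- max(0, min(nz - 1, iz))
  vals <- if (map == "elec") object$elec else if (map == "desolv") {
    object$desolv
  } else object$vdw[, map]
  nx <- object$n[1]; ny <- object$n[2]
  sel <- seq_len(nx * ny) + nx * ny * iz
  df <- tidyr::expand_grid(
    yi = seq_len(ny) - 1, xi = seq_len(nx) - 1) |>
    mutate(x = object$origin[1] + .data$xi * object$config$spacing,
           y = object$origin[2] + .data$yi * object$config$spacing,
           value = vals[sel])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s potential, z = %.2f A", map,
                                  object$origin[3] + iz * object$config$spacing),
                  x = "x (A)", y = "y (A)", fill = "kcal/mol")
}
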