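# Quaternion and torsion geometry helpers, the pose type, and all-atom RMSD.

#' Construct a ligand pose
#'
#' A pose is the full set of search degrees of freedom of a docked ligand:
#' a rigid translation (A), a rigid orientation (unit quaternion, `w,x,y,z`),
#' and one torsion delta (radians) per rotatable bond, applied relative to
#' the ligand's reference conformer.
#'
#' @param translation Numeric length-3 displacement in Angstrom. For poses
#'   built by the docking engine this displaces the ligand reference centroid
#'   relative to the docking-cube centre.
#' @param quaternion Numeric length-4 orientation `(w, x, y, z)`; normalized
#'   on construction and must be within `1e-9` of unit length afterwards.
#' @param torsions Numeric vector of torsion-angle deltas (radians), one per
#'   rotatable torsion of the ligand the pose is applied to.
#' @return An object of class `gridock_pose`.
#' @examples
#' pose_identity(0)
#' new_pose(c(1, 0, 0), c(1, 0, 0, 0), numeric(0))
#' @export
new_pose <- function(translation = c(0, 0, 0),
                     quaternion = c(1, 0, 0, 0),
                     torsions = numeric(0)) {
  translation <- as.numeric(translation)
  quaternion <- as.numeric(quaternion)
  torsions <- as.numeric(torsions)
  if (length(translation) != 3 || !all(is.finite(translation))) {
    abort("`translation` must be a finite length-3 numeric vector.")
  }
  if (length(quaternion) != 4 || !all(is.finite(quaternion))) {
    abort("`quaternion` must be a finite length-4 numeric vector.")
  }
  n <- sqrt(sum(quaternion^2))
  if (n < 1e-12) abort("`quaternion` must be nonzero.")
  quaternion <- quaternion / n
  stopifnot(abs(sqrt(sum(quaternion^2)) - 1) <= 1e-9)
  structure(list(translation = translation, quaternion = quaternion,
                 torsions = torsions),
            class = "gridock_pose")
}

#' @rdname new_pose
#' @param n_torsions Number of rotatable torsions of the target ligand.
#' @export
pose_identity <- function(n_torsions = 0) {
  new_pose(c(0, 0, 0), c(1, 0, 0, 0), rep(0, n_torsions))
}

#' @export
print.gridock_pose <- function(x, ...) {
  cat("<gridock_pose>",
      sprintf("translation: [%.3f, %.3f, %.3f] A", x$translation[1],
              x$translation[2], x$translation[3]),
      sprintf("quaternion:  [%.4f, %.4f, %.4f, %.4f]", x$quaternion[1],
              x$quaternion[2], x$quaternion[3], x$quaternion[4]),
      sprintf("torsions:    %s", if (length(x$torsions) == 0) "(rigid)" else
        paste(sprintf("%.1f deg", x$torsions * 180 / pi), collapse = ", ")),
      sep = "\n")
  invisible(x)
}

pose_genome <- function(pose) {
  c(pose$translation, pose$quaternion, pose$torsions)
}

genome_pose <- function(genome, n_torsions) {
  new_pose(genome[1:3], genome[4:7],
           if (n_torsions > 0) genome[7 + seq_len(n_torsions)] else numeric(0))
}

quat_random <- function(n = 1) {
  m <- matrix(rnorm(4 * n), ncol = 4)
  m / sqrt(rowSums(m^2))
}

#' Measured dihedral angle of four points
#'
#' Returns the signed dihedral (radians, in (-pi, pi]) defined by points
#' p1-p2-p3-p4.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinates.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / b2n, sum(n1 * n2))
}

#' Apply a pose to a ligand topology
#'
#' Transforms the ligand reference conformer into Cartesian coordinates:
#' torsion deltas are applied about each rotatable bond in listed order, then
#' the rigid rotation about the reference centroid, then the translation.
#' With `centre = c(0,0,0)` (default) the identity pose reproduces the
#' reference conformer exactly.
#'
#' @param topology A `gridock_ligand` topology.
#' @param pose A `gridock_pose` whose torsion count matches the topology.
#' @param centre Optional reference point (A) that the pose translation is
#'   measured from; the docking engine passes the docking-cube centre there.
#'   `NULL` (default) anchors at the reference centroid, so the identity pose
#'   is the identity map.
#' @return An `n x 3` coordinate matrix (A).
#' @export
pose_to_coordinates <- function(topology, pose, centre = NULL) {
  stopifnot(inherits(topology, "gridock_ligand"), inherits(pose, "gridock_pose"))
  nt <- nrow(topology$torsions)
  if (length(pose$torsions) != nt) {
    abort(sprintf("Pose has %d torsions but topology has %d rotatable torsions.",
                  length(pose$torsions), nt))
  }
  cen <- if (is.null(centre)) colMeans(topology$coords) else as.numeric(centre)
  cpp_pose_coords(topology$coords, cen,
                  topology$torsion_quads0, topology$torsion_moving0,
                  c(pose$translation, pose$quaternion, pose$torsions))
}

#' All-atom root-mean-square deviation
#'
#' RMSD over all atoms between two equally ordered coordinate sets. No
#' superposition and no symmetry correction is applied: pose RMSD during
#' clustering is meant to distinguish placements, not conformers.
#'
#' @param coords_a,coords_b `n x 3` numeric matrices with identical atom
#'   ordering.
#' @return RMSD in Angstrom (non-negative scalar).
#' @examples
#' a <- matrix(rnorm(15), ncol = 3)
#' rmsd_all_atoms(a, a) # 0
#' @export
rmsd_all_atoms <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b))) {
    abort("Coordinate sets must have identical dimensions and atom order.")
  }
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}
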