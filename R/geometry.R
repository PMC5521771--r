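# Rigid-monomer geometry. The model retains, per pyranose monomer, the six
# ring atoms (C1, C2, C3, C4, C5, O5) plus the glycosidic oxygen O1 attached
# at C1; all bond lengths, bond angles and improper torsions are fixed, so the
# only flexible degrees of freedom of a chain are the two glycosidic dihedrals
# per link, defined IUPAC-style as
#   phi = O5(i) - C1(i) - O1(i) - C4(i+1)
#   psi = C1(i) - O1(i) - C4(i+1) - C5(i+1).
# The monomer is an idealized 4C1 chair: ring atoms on a hexagonal prism of
# alternating height, substituents placed equatorially (beta anomer, 1,4-di-
# equatorial attachment). The steric/electrostatic interaction site is the
# centroid of the six ring atoms; the resulting ring-center virtual bond
# length l (~0.52 nm) emerges from the geometry and is measured, never set.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v * v))

#' Measure a dihedral angle
#'
#' Standard IUPAC sign convention, returned wrapped to `[0, 2*pi)`.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (positions, nm).
#' @return Dihedral in radians on `[0, 2*pi)`.
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  wrap_angle(atan2(sum(m1 * n2), sum(n1 * n2)))
}

# Natural-extension-reference-frame placement: position D bonded to C with
# given bond length, angle B-C-D and dihedral A-B-C-D.
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(angle), sin(angle) * cos(dihedral), -sin(angle) * sin(dihedral))
  c + cbind(bc, m, n) %*% d2
}

# Equatorial substituent direction at ring atom `x` with ring neighbours u, v:
# the unit vector making the tetrahedral angle with both ring bonds whose
# out-of-plane component is smallest (the other solution is axial).
equatorial_dir <- function(x, u, v, theta = acos(-1 / 3)) {
  u1 <- unit3(u - x); u2 <- unit3(v - x)
  c12 <- sum(u1 * u2)
  a <- cos(theta) / (1 + c12)
  w <- cross3(u1, u2)
  b2 <- (1 - a^2 * (2 + 2 * c12)) / sum(w * w)
  if (b2 < 0) stop("no tetrahedral substituent direction exists", call. = FALSE)
  b <- sqrt(b2)
  cand1 <- a * (u1 + u2) + b * w
  cand2 <- a * (u1 + u2) - b * w
  if (abs(cand1[3]) <= abs(cand2[3])) cand1 else cand2
}

#' Rigid-monomer geometry parameters
#'
#' Builds the canonical (local-frame) coordinates of the retained atoms of one
#' idealized beta-D-glucopyranose monomer and the fixed internal coordinates of
#' the glycosidic bridge. This is the single place where the embedded geometry
#' constants live.
#'
#' @param ring_bond Ring bond length in nm.
#' @param chair_height Half-amplitude of the chair pucker in nm.
#' @param bond_c1_o1 Anomeric C1-O1 bond length in nm.
#' @param bond_o1_c4 Glycosidic O1-C4' bond length in nm.
#' @param angle_c1_o1_c4 Glycosidic valence angle C1-O1-C4' in radians.
#' @return An object of class `cg_geometry`: local atom coordinates (rows
#'   C1, C2, C3, C4, C5, O5, O1), the ring-centroid site offset, the incoming
#'   glycosidic-oxygen direction at C4, and derived scalars.
#' @export
cg_geometry <- function(ring_bond = 0.150,
                        chair_height = 0.025,
                        bond_c1_o1 = 0.142,
                        bond_o1_c4 = 0.143,
                        angle_c1_o1_c4 = 116.5 * pi / 180) {
  stopifnot(ring_bond > 0, chair_height >= 0, bond_c1_o1 > 0, bond_o1_c4 > 0)
  r <- sqrt(ring_bond^2 - 4 * chair_height^2)
  k <- 0:5
  # clockwise ring ordering: the chirality for which the Table-2-style main
  # minimum (phi ~ 5.0, psi ~ 2.2 rad) yields the extended two-fold helix
  # characteristic of beta-(1->4) sugars
  ring <- cbind(r * cos(k * pi / 3),
                -r * sin(k * pi / 3),
                chair_height * (-1)^k)
  rownames(ring) <- c("C1", "C2", "C3", "C4", "C5", "O5")
  # Equatorial O1 at C1 (neighbours C2 and O5) and equatorial attachment
  # direction of the incoming glycosidic oxygen at C4 (neighbours C3 and C5).
  o1_dir <- equatorial_dir(ring["C1", ], ring["C2", ], ring["O5", ])
  o1 <- ring["C1", ] + bond_c1_o1 * o1_dir
  w <- equatorial_dir(ring["C4", ], ring["C3", ], ring["C5", ])
  atoms <- rbind(ring, O1 = o1)
  site <- colMeans(ring)
  v45 <- ring["C5", ] - ring["C4", ]
  structure(list(
    atoms = atoms,
    site = site,
    w_c4 = w,
    bond_o1_c4 = bond_o1_c4,
    angle_c1_o1_c4 = angle_c1_o1_c4,
    bond_c4_c5 = sqrt(sum(v45^2)),
    angle_o1_c4_c5 = acos(sum(unit3(v45) * w)),
    # orthonormal pair used to recover a monomer pose from placed C4', C5', O1
    a_loc = w,
    b_loc = unit3(v45 - sum(v45 * w) * w)
  ), class = "cg_geometry")
}

#' @export
print.cg_geometry <- function(x, ...) {
  cat("Rigid CG monomer geometry (idealized 4C1 chair)\n")
  cat(sprintf("  ring bond %.4f nm, C1-O1 %.4f nm, O1-C4' %.4f nm\n",
              sqrt(sum((x$atoms["C2", ] - x$atoms["C1", ])^2)),
              sqrt(sum((x$atoms["O1", ] - x$atoms["C1", ])^2)), x$bond_o1_c4))
  cat(sprintf("  glycosidic angle C1-O1-C4' %.1f deg\n",
              x$angle_c1_o1_c4 * 180 / pi))
  invisible(x)
}

# Project a near-rotation onto an exact rotation (Gram-Schmidt on columns).
# Without this, the scale error of an incremental pivot transform compounds
# multiplicatively over accepted moves.
orthonormalize3 <- function(R) {
  a <- unit3(R[, 1])
  b <- R[, 2] - sum(R[, 2] * a) * a
  b <- unit3(b)
  cbind(a, b, cross3(a, b))
}

# Pose of monomer i+1 given the pose (R, t) of monomer i and the link
# dihedrals. A pose maps local monomer coordinates into the world frame.
pose_from_link <- function(R, t, phi, psi, geom) {
  o5 <- R %*% geom$atoms["O5", ] + t
  c1 <- R %*% geom$atoms["C1", ] + t
  o1 <- R %*% geom$atoms["O1", ] + t
  c4p <- nerf_place(o5, c1, o1, geom$bond_o1_c4, geom$angle_c1_o1_c4, phi)
  c5p <- nerf_place(c1, o1, c4p, geom$bond_c4_c5, geom$angle_o1_c4_c5, psi)
  a_w <- unit3(as.vector(o1 - c4p))
  v <- as.vector(c5p - c4p)
  b_w <- unit3(v - sum(v * a_w) * a_w)
  Mw <- cbind(a_w, b_w, cross3(a_w, b_w))
  Ml <- cbind(geom$a_loc, geom$b_loc, cross3(geom$a_loc, geom$b_loc))
  Rn <- Mw %*% t(Ml)
  tn <- as.vector(c4p) - as.vector(Rn %*% geom$atoms["C4", ])
  list(R = Rn, t = tn)
}
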