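# Polymer sequences (DP, DD, acetylation pattern) and chain conformations:
# forward-kinematic coordinate reconstruction from per-link dihedrals, O(DP-k)
# pivot updates, and virtual-bond extraction.

round_half_up <- function(x) floor(x + 0.5)

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build a monomer sequence
#'
#' Assigns GlcN (deacetylated, titratable) and GlcNAc (acetylated, neutral)
#' kinds along a chain of `dp` monomers so that the fraction of GlcN matches
#' the degree of deacetylation `dd` as closely as one chain can
#' (`round((1 - dd) * dp)` acetylated monomers, half rounded up).
#'
#' @param dp Degree of polymerization (>= 2).
#' @param dd Degree of deacetylation in `[0, 1]`.
#' @param pattern `"random"` (default), `"alternating"`, `"block"` (with
#'   `block_size`), or an explicit string of `A` (GlcN) / `D` (GlcNAc)
#'   characters of length `dp`. Alternating and block tilings start with GlcN
#'   at monomer 1 and represent only `dd = 0.5`.
#' @param seed RNG seed for the random pattern (reproducible; the global RNG
#'   state is left untouched).
#' @param block_size Run length for the block pattern.
#' @return A `polymer_sequence`: monomer kinds, titratable-site indices, and
#'   bookkeeping fields.
#' @export
build_sequence <- function(dp, dd = 1, pattern = "random", seed = 1L, block_size = 2L) {
  stopifnot(dp >= 2, dd >= 0, dd <= 1)
  if (nchar(pattern) == dp && grepl("^[AD]+$", pattern)) {
    kinds <- ifelse(strsplit(pattern, "")[[1]] == "A", "GlcN", "GlcNAc")
    dd <- mean(kinds == "GlcN")
    pattern_label <- "explicit"
  } else if (pattern == "random") {
    n_ac <- round_half_up((1 - dd) * dp)
    kinds <- rep("GlcN", dp)
    if (n_ac > 0) {
      pos <- with_seed(seed, sample.int(dp, n_ac))
      kinds[pos] <- "GlcNAc"
    }
    pattern_label <- "random"
  } else if (pattern %in% c("alternating", "block")) {
    k <- if (pattern == "alternating") 1L else as.integer(block_size)
    stopifnot(k >= 1)
    tile <- rep(c("GlcN", "GlcNAc"), each = k)
    kinds <- rep(tile, length.out = dp)
    dd_real <- mean(kinds == "GlcN")
    if (abs(dd * dp - sum(kinds == "GlcN")) >= 1) {
      stop(sprintf(
        "dd = %.3f is not representable by the %s tiling at dp = %d; nearest representable dd = %.3f",
        dd, pattern, dp, dd_real), call. = FALSE)
    }
    dd <- dd_real
    pattern_label <- if (pattern == "alternating") "alternating" else sprintf("block(%d)", k)
  } else {
    stop("unknown pattern: ", pattern, call. = FALSE)
  }
  titratable <- which(kinds == "GlcN")
  structure(list(
    kinds = kinds,
    dp = as.integer(dp),
    dd = sum(kinds == "GlcN") / dp,
    n_t = length(titratable),
    titratable = titratable,
    pattern = pattern_label,
    seed = as.integer(seed)
  ), class = "polymer_sequence")
}

#' @export
print.polymer_sequence <- function(x, ...) {
  cat(sprintf("Polymer sequence: DP %d, DD %.3f (%d titratable), pattern %s\n",
              x$dp, x$dd, x$n_t, x$pattern))
  invisible(x)
}

#' Monomer state labels for a sequence with charges
#'
#' @param sequence A `polymer_sequence`.
#' @param charges Integer vector of 0/1 per monomer (GlcNAc must be 0).
#' @return Character vector of state labels per monomer.
#' @export
monomer_state_labels <- function(sequence, charges) {
  stopifnot(length(charges) == sequence$dp, all(charges %in% c(0L, 1L)))
  if (any(charges == 1L & sequence$kinds == "GlcNAc")) {
    stop("GlcNAc monomers cannot carry charge", call. = FALSE)
  }
  ifelse(sequence$kinds == "GlcNAc", "GlcNAc",
         ifelse(charges == 1L, "GlcNH3+", "GlcNH2"))
}

## Conformations ---------------------------------------------------------------

#' Reconstruct chain coordinates from link dihedrals
#'
#' Forward-kinematic build: monomer 1 in the canonical frame, each successive
#' monomer placed by the fixed internal coordinates and its link's (phi, psi).
#'
#' @param sequence A `polymer_sequence` (or an integer DP).
#' @param dihedrals `(dp - 1) x 2` matrix of `(phi, psi)` in radians.
#' @param geometry A [cg_geometry()].
#' @return A `conformation`: per-monomer poses, retained-atom coordinates,
#'   ring-center interaction sites, dihedrals, and the measured mean virtual
#'   bond length `l`.
#' @export
rebuild_coordinates <- function(sequence, dihedrals, geometry = cg_geometry()) {
  dp <- if (inherits(sequence, "polymer_sequence")) sequence$dp else as.integer(sequence)
  dihedrals <- matrix(dihedrals, ncol = 2)
  if (nrow(dihedrals) != dp - 1) {
    stop("need exactly dp - 1 dihedral pairs", call. = FALSE)
  }
  Rarr <- array(0, c(3, 3, dp)); tmat <- matrix(0, dp, 3)
  Rarr[, , 1] <- diag(3)
  for (k in seq_len(dp - 1)) {
    p <- pose_from_link(Rarr[, , k], tmat[k, ], dihedrals[k, 1], dihedrals[k, 2], geometry)
    Rarr[, , k + 1] <- p$R
    tmat[k + 1, ] <- p$t
  }
  conf <- structure(list(
    R = Rarr, t = tmat,
    dihedrals = dihedrals,
    dp = dp,
    geometry = geometry,
    sites = NULL
  ), class = "conformation")
  conf$sites <- t(vapply(seq_len(dp), function(i) {
    as.vector(Rarr[, , i] %*% geometry$site) + tmat[i, ]
  }, numeric(3)))
  conf
}

#' @export
print.conformation <- function(x, ...) {
  bv <- bond_vectors(x)
  cat(sprintf("Chain conformation: DP %d, l = %.4f nm, Ree = %.3f nm, Rg = %.3f nm\n",
              x$dp, bv$l, end_to_end_distance(x$sites), radius_of_gyration(x$sites)))
  invisible(x)
}

#' Atom coordinates of one monomer
#'
#' @param conformation A `conformation`.
#' @param i Monomer index.
#' @return A 7 x 3 matrix (rows C1, C2, C3, C4, C5, O5, O1) of world
#'   coordinates in nm.
#' @export
monomer_atoms <- function(conformation, i) {
  g <- conformation$geometry
  t(conformation$R[, , i] %*% t(g$atoms)) +
    matrix(conformation$t[i, ], nrow(g$atoms), 3, byrow = TRUE)
}

#' Measure the glycosidic dihedrals of a conformation from its coordinates
#'
#' Inverse kinematics used in round-trip checks of the forward build.
#'
#' @param conformation A `conformation`.
#' @return `(dp - 1) x 2` matrix of measured `(phi, psi)`.
#' @export
measure_dihedrals <- function(conformation) {
  dp <- conformation$dp
  out <- matrix(NA_real_, dp - 1, 2)
  a_prev <- monomer_atoms(conformation, 1)
  for (k in seq_len(dp - 1)) {
    a_next <- monomer_atoms(conformation, k + 1)
    out[k, 1] <- measure_dihedral(a_prev["O5", ], a_prev["C1", ], a_prev["O1", ], a_next["C4", ])
    out[k, 2] <- measure_dihedral(a_prev["C1", ], a_prev["O1", ], a_next["C4", ], a_next["C5", ])
    a_prev <- a_next
  }
  out
}

#' Pivot update of a conformation
#'
#' Re-draws link `link_index` to `new_phipsi` and rigidly moves everything
#' downstream; O(dp - link_index) work, equivalent to a full rebuild.
#'
#' @param conformation A `conformation`.
#' @param link_index Link index in `1..dp-1`.
#' @param new_phipsi Numeric `c(phi, psi)`.
#' @return The updated `conformation`.
#' @export
pivot_update <- function(conformation, link_index, new_phipsi) {
  dp <- conformation$dp
  stopifnot(link_index >= 1, link_index <= dp - 1)
  k <- link_index
  g <- conformation$geometry
  new_pose <- pose_from_link(conformation$R[, , k], conformation$t[k, ],
                             new_phipsi[1], new_phipsi[2], g)
  Rold <- conformation$R[, , k + 1]; told <- conformation$t[k + 1, ]
  A <- orthonormalize3(new_pose$R %*% t(Rold))
  b <- new_pose$t - as.vector(A %*% told)
  for (j in (k + 1):dp) {
    conformation$R[, , j] <- A %*% conformation$R[, , j]
    conformation$t[j, ] <- as.vector(A %*% conformation$t[j, ]) + b
    conformation$sites[j, ] <- as.vector(A %*% conformation$sites[j, ]) + b
  }
  conformation$dihedrals[k, ] <- wrap_angle(new_phipsi)
  conformation
}

#' Virtual bond vectors between successive ring centers
#'
#' @param conformation A `conformation`.
#' @return A list: `vectors` (`(dp-1) x 3`, unnormalized), `units`
#'   (normalized), `lengths`, and `l` (their mean, the virtual bond length
#'   used in persistence-length analyses).
#' @export
bond_vectors <- function(conformation) {
  s <- conformation$sites
  v <- s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE]
  len <- sqrt(rowSums(v^2))
  list(vectors = v, units = v / len, lengths = len, l = mean(len))
}

end_to_end_distance <- function(sites) {
  sqrt(sum((sites[nrow(sites), ] - sites[1, ])^2))
}
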