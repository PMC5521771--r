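# Synthetic stand-ins for the metadynamics free-energy maps. Each link type
# gets a two-well map whose main-minimum position, second-minimum gap and
# accessible-area fractions reproduce the published per-link feature table;
# the well widths are solved analytically from the areas (for an isotropic
# Gaussian basin of width sigma at gap g, the fraction of the torus below
# level t is (t - g) * sigma^2 / (2*pi)). What the generator cannot emulate
# is the full 2-D topology of the real maps (basin shapes, location of the
# secondary minimum), which is why chain-scale observables computed from these
# maps are reported, not asserted against the published values.

#' Published per-link map features used to parameterize the synthetic library
#'
#' Accessible-area fractions at 12 k_BT and (strictly below) 1 k_BT,
#' main-minimum position (radians) and free-energy gap to the second minimum
#' (k_BT) for the nine glycosidic link types of chitosan; reducing-end monomer
#' first.
#'
#' @return A nine-row tibble.
#' @export
table2_map_parameters <- function() {
  tibble::tribble(
    ~link_key,           ~area_12kt, ~area_1kt, ~phi,   ~psi,   ~delta_g2,
    "GlcNAc-GlcNAc",     0.298,      0.0061,    4.956,  2.180,  2.4,
    "GlcNAc-GlcNH2",     0.274,      0.0050,    4.933,  2.198,  3.0,
    "GlcNAc-GlcNH3+",    0.217,      0.0053,    4.9747, 2.214,  3.7,
    "GlcNH2-GlcNAc",     0.280,      0.0087,    4.953,  2.05,   2.6,
    "GlcNH2-GlcNH2",     0.284,      0.0055,    4.997,  2.188,  4.0,
    "GlcNH2-GlcNH3+",    0.266,      0.0068,    5.037,  2.209,  3.4,
    "GlcNH3+-GlcNAc",    0.256,      0.0054,    5.11,   2.216,  1.35,
    "GlcNH3+-GlcNH2",    0.252,      0.0049,    5.1287, 2.1736, 2.2,
    "GlcNH3+-GlcNH3+",   0.193,      0.0060,    5.12,   2.186,  3.6
  )
}

#' Well parameters for one synthetic link map
#'
#' Solves the two-well generator parameters (widths, depths) from the target
#' feature row: the main-well width from the sub-1-k_BT area, the second-well
#' width from the remaining 12-k_BT accessible area, the depth gap from
#' `delta_g2`.
#'
#' @param row One row of [table2_map_parameters()].
#' @param background Background level in k_BT.
#' @param second_well_offset Position of the secondary well relative to the
#'   main one, `c(dphi, dpsi)` radians.
#' @return A two-row well data frame for [synthesize_map()].
#' @export
wells_from_features <- function(row, background = 25, second_well_offset = c(-1.2, pi)) {
  sigma1 <- sqrt(2 * pi * row$area_1kt)
  s2sq <- 2 * pi * (row$area_12kt - 12 * row$area_1kt) / (12 - row$delta_g2)
  if (s2sq <= 0) stop("feature row not representable by a two-well map", call. = FALSE)
  data.frame(
    phi = wrap_angle(c(row$phi, row$phi + second_well_offset[1])),
    psi = wrap_angle(c(row$psi, row$psi + second_well_offset[2])),
    depth = c(background, background - row$delta_g2),
    width_phi = c(sigma1, sqrt(s2sq)),
    width_psi = c(sigma1, sqrt(s2sq))
  )
}

#' Synthetic nine-map library
#'
#' Builds the full link-keyed library of two-well maps from the published
#' feature table (or any table of the same shape).
#'
#' @param params Feature table, default [table2_map_parameters()].
#' @param cutoff Restriction energy in k_BT.
#' @param grid_spec Grid shape.
#' @param background Background level in k_BT.
#' @param second_well_offset Secondary-well offset, `c(dphi, dpsi)` radians.
#' @return A `map_library` with all nine link types.
#' @export
synthetic_map_library <- function(params = table2_map_parameters(), cutoff = 7,
                                  grid_spec = c(200, 200), background = 25,
                                  second_well_offset = c(-1.2, pi)) {
  maps <- lapply(seq_len(nrow(params)), function(k) {
    row <- params[k, ]
    synthesize_map(wells_from_features(row, background, second_well_offset),
                   background = background, grid_spec = grid_spec,
                   link_key = row$link_key)
  })
  names(maps) <- params$link_key
  map_library(maps, cutoff = cutoff)
}
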