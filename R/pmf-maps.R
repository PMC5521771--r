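# Glycosidic (phi, psi) free-energy maps: loading, synthesis, feature
# analysis, cutoff restriction and sampling, and the nine-map library keyed by
# the ordered (reducing-end, non-reducing-end) monomer states.
#
# A map is a periodic 2-D grid of free energies in k_BT over
# [0, 2*pi) x [0, 2*pi), node-centered: node j of an n-bin axis sits at
# (j-1) * 2*pi / n, and values are interpolated with periodic bilinear
# interpolation. Maps are normalized so the global minimum is exactly 0.

new_dihedral_map <- function(grid, link_key = NA_character_) {
  stopifnot(is.matrix(grid), nrow(grid) >= 4, ncol(grid) >= 4)
  if (!all(is.finite(grid))) stop("map grid contains non-finite energies", call. = FALSE)
  offset <- min(grid)
  structure(list(
    grid = grid - offset,
    link_key = link_key,
    n_phi = nrow(grid),
    n_psi = ncol(grid),
    offset = offset
  ), class = "dihedral_map")
}

#' @export
print.dihedral_map <- function(x, ...) {
  cat(sprintf("Glycosidic free-energy map [%s]: %d x %d grid, range 0 - %.2f kT\n",
              ifelse(is.na(x$link_key), "unkeyed", x$link_key),
              x$n_phi, x$n_psi, max(x$grid)))
  invisible(x)
}

#' Interpolate a free-energy map
#'
#' Periodic bilinear interpolation of the map at continuous angles.
#'
#' @param map A `dihedral_map`.
#' @param phi,psi Angles in radians (vectorized; any real value, wrapped).
#' @return Free energies in k_BT.
#' @export
map_interpolate <- function(map, phi, psi) {
  np <- map$n_phi; nq <- map$n_psi
  u <- wrap_angle(phi) * np / (2 * pi)
  v <- wrap_angle(psi) * nq / (2 * pi)
  i0 <- floor(u); f <- u - i0
  j0 <- floor(v); g <- v - j0
  i0 <- as.integer(i0 %% np); i1 <- as.integer((i0 + 1L) %% np)
  j0 <- as.integer(j0 %% nq); j1 <- as.integer((j0 + 1L) %% nq)
  G <- map$grid
  (1 - f) * (1 - g) * G[cbind(i0 + 1L, j0 + 1L)] +
    f * (1 - g) * G[cbind(i1 + 1L, j0 + 1L)] +
    (1 - f) * g * G[cbind(i0 + 1L, j1 + 1L)] +
    f * g * G[cbind(i1 + 1L, j1 + 1L)]
}

# Resample a grid onto an n_phi x n_psi node-centered periodic grid.
resample_grid <- function(map, n_phi, n_psi) {
  if (map$n_phi == n_phi && map$n_psi == n_psi) return(map$grid)
  phi <- rep((seq_len(n_phi) - 1) * 2 * pi / n_phi, times = n_psi)
  psi <- rep((seq_len(n_psi) - 1) * 2 * pi / n_psi, each = n_phi)
  matrix(map_interpolate(map, phi, psi), n_phi, n_psi)
}

split_fields <- function(line) {
  strsplit(trimws(line), "[,[:blank:]]+")[[1]]
}

#' Load a glycosidic free-energy map from a text file
#'
#' Two dialects are auto-detected: (i) three-column `phi psi G` rows
#' (whitespace- or comma-separated, radians), or (ii) a dense matrix whose rows
#' are phi nodes, preceded by a comment header line giving the axis ranges,
#' e.g. `# phi 0 6.2832 psi 0 6.2832`. Energies are assumed to be in k_BT
#' unless a comment line declares `kJ/mol`, in which case they are divided by
#' k_BT at 298 K (2.479 kJ/mol). Angles on `[-pi, pi)` are shifted onto
#' `[0, 2*pi)`. The map is resampled onto the canonical grid by periodic
#' bilinear interpolation and normalized so its minimum is 0.
#'
#' @param path Path to the map file.
#' @param link_key Optional link key label (e.g. `"GlcNH2-GlcNH2"`).
#' @param grid_spec Target grid shape, default `c(200, 200)`.
#' @return A `dihedral_map`.
#' @export
load_map <- function(path, link_key = NA_character_, grid_spec = c(200, 200)) {
  if (!file.exists(path)) stop("map file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  is_comment <- startsWith(trimws(lines), "#")
  comments <- lines[is_comment]
  data_lines <- lines[!is_comment]
  data_nos <- lineno[!is_comment]
  if (length(data_lines) == 0) stop("map file contains no data rows", call. = FALSE)
  in_kjmol <- any(grepl("kj/mol", comments, ignore.case = TRUE))

  nf <- length(split_fields(data_lines[1]))
  if (nf == 3) {
    vals <- lapply(seq_along(data_lines), function(k) {
      f <- suppressWarnings(as.numeric(split_fields(data_lines[k])))
      if (length(f) != 3 || anyNA(f)) {
        stop("malformed map row at line ", data_nos[k], ": '", data_lines[k], "'",
             call. = FALSE)
      }
      f
    })
    m <- do.call(rbind, vals)
    grid <- grid_from_xyz(m[, 1], m[, 2], m[, 3])
  } else {
    hdr <- grep("phi", comments, ignore.case = TRUE, value = TRUE)
    if (length(hdr) == 0) {
      stop("dense-matrix map file needs a '# phi <min> <max> psi <min> <max>' header",
           call. = FALSE)
    }
    nums <- suppressWarnings(as.numeric(split_fields(gsub("[^0-9eE+:.[:blank:]-]", " ", hdr[1]))))
    nums <- nums[!is.na(nums)]
    if (length(nums) < 4) stop("could not parse axis ranges from map header", call. = FALSE)
    rng_phi <- nums[1:2]; rng_psi <- nums[3:4]
    rows <- lapply(seq_along(data_lines), function(k) {
      f <- suppressWarnings(as.numeric(split_fields(data_lines[k])))
      if (anyNA(f)) stop("malformed map row at line ", data_nos[k], call. = FALSE)
      f
    })
    if (length(unique(lengths(rows))) != 1) {
      stop("non-rectangular grid: matrix rows have unequal lengths", call. = FALSE)
    }
    grid <- do.call(rbind, rows)
    np <- nrow(grid); nq <- ncol(grid)
    # rows are phi nodes on [rng_phi[1], rng_phi[2]); shift to start at 0
    grid <- roll_axis(grid, rng_phi[1], np, 1L)
    grid <- roll_axis(grid, rng_psi[1], nq, 2L)
  }
  if (in_kjmol) grid <- grid / kbt_kjmol(298)
  m <- new_dihedral_map(grid, link_key)
  out <- new_dihedral_map(resample_grid(m, grid_spec[1], grid_spec[2]), link_key)
  out$offset <- out$offset + m$offset   # total shift relative to the file values
  out
}

# Reorder a dense grid whose first node sits at angle `a0` so that node 1 is
# the node at (or wrapping onto) angle 0.
roll_axis <- function(grid, a0, n, axis) {
  shift <- round(wrap_angle(a0) * n / (2 * pi)) %% n
  if (shift == 0) return(grid)
  idx <- ((seq_len(n) - 1 + shift) %% n) + 1
  if (axis == 1L) grid[order(idx), , drop = FALSE] else grid[, order(idx), drop = FALSE]
}

grid_from_xyz <- function(phi, psi, G) {
  shift_axis <- function(a) {
    a <- round(a, 10)
    u <- sort(unique(a))
    # tolerate a duplicated periodic endpoint (0 and 2*pi both present)
    if (length(u) > 2 && isTRUE(all.equal(u[length(u)] - u[1], 2 * pi, tolerance = 1e-6))) {
      u <- u[-length(u)]
    }
    u
  }
  phi_w <- round(wrap_angle(round(phi, 10)), 10)
  psi_w <- round(wrap_angle(round(psi, 10)), 10)
  up <- shift_axis(phi_w); uq <- shift_axis(psi_w)
  phi_w[!phi_w %in% up] <- up[1]  # wrapped endpoint duplicates map onto node 0
  psi_w[!psi_w %in% uq] <- uq[1]
  np <- length(up); nq <- length(uq)
  if (np < 4 || nq < 4) stop("map grid too small", call. = FALSE)
  dp <- diff(up); dq <- diff(uq)
  if (max(dp) - min(dp) > 1e-4 * max(dp) || max(dq) - min(dq) > 1e-4 * max(dq)) {
    stop("non-uniform grid spacing in map file", call. = FALSE)
  }
  i <- match(phi_w, up); j <- match(psi_w, uq)
  grid <- matrix(NA_real_, np, nq)
  grid[cbind(i, j)] <- G
  if (anyNA(grid)) {
    stop("non-rectangular grid: ", sum(is.na(grid)), " of ", np * nq,
         " (phi, psi) combinations missing", call. = FALSE)
  }
  grid
}

#' Write a map to a text file
#'
#' @param map A `dihedral_map`.
#' @param path Output path.
#' @param dialect `"xyz"` (three-column) or `"matrix"` (dense with header).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, dialect = c("xyz", "matrix")) {
  dialect <- match.arg(dialect)
  phi <- (seq_len(map$n_phi) - 1) * 2 * pi / map$n_phi
  psi <- (seq_len(map$n_psi) - 1) * 2 * pi / map$n_psi
  if (dialect == "xyz") {
    df <- expand.grid(phi = phi, psi = psi)
    lines <- sprintf("%.10f %.10f %.10f", df$phi, df$psi, map$grid[cbind(
      match(df$phi, phi), match(df$psi, psi))])
    writeLines(c(sprintf("# glycosidic map %s (kBT)", map$link_key), lines), path)
  } else {
    hdr <- sprintf("# phi %.10f %.10f psi %.10f %.10f (kBT)", 0, 2 * pi, 0, 2 * pi)
    writeLines(c(hdr, apply(map$grid, 1, function(r) paste(sprintf("%.10f", r), collapse = " "))),
               path)
  }
  invisible(path)
}

#' Synthesize a free-energy map from Gaussian wells
#'
#' Composes periodic Gaussian basins on a uniform background:
#' `G(phi, psi) = -ln sum_w exp(-(background - depth_w) - d_w^2 / 2)` with
#' `d_w^2` the periodic squared distance to well `w` scaled by its widths, so
#' that each well bottom sits at `background - depth_w` before normalization.
#'
#' @param wells Data frame with columns `phi`, `psi`, `depth` (k_BT),
#'   `width_phi`, `width_psi` (radians).
#' @param background Background level in k_BT; must be at least the largest
#'   depth.
#' @param grid_spec Grid shape, default `c(200, 200)`.
#' @param link_key Optional link key label.
#' @return A normalized `dihedral_map`.
#' @export
synthesize_map <- function(wells, background = 25, grid_spec = c(200, 200),
                           link_key = NA_character_) {
  wells <- as.data.frame(wells)
  stopifnot(nrow(wells) >= 1,
            all(c("phi", "psi", "depth", "width_phi", "width_psi") %in% names(wells)))
  if (any(wells$depth <= 0)) stop("well depths must be positive", call. = FALSE)
  if (any(wells$width_phi <= 0) || any(wells$width_psi <= 0)) {
    stop("well widths must be positive", call. = FALSE)
  }
  if (background < max(wells$depth)) {
    stop("background must be at least the largest well depth", call. = FALSE)
  }
  np <- grid_spec[1]; nq <- grid_spec[2]
  phi <- (seq_len(np) - 1) * 2 * pi / np
  psi <- (seq_len(nq) - 1) * 2 * pi / nq
  pd <- function(a, a0) {  # periodic (minimal-image) difference
    d <- (a - a0) %% (2 * pi)
    ifelse(d > pi, d - 2 * pi, d)
  }
  S <- matrix(0, np, nq)
  for (w in seq_len(nrow(wells))) {
    dphi <- pd(phi, wells$phi[w]) / wells$width_phi[w]
    dpsi <- pd(psi, wells$psi[w]) / wells$width_psi[w]
    d2 <- outer(dphi^2, dpsi^2, `+`)
    S <- S + exp(-(background - wells$depth[w]) - d2 / 2)
  }
  m <- new_dihedral_map(-log(S), link_key)
  mins <- find_minima(m)
  if (nrow(mins) < nrow(wells)) {
    warning("overlapping wells merged: ", nrow(wells), " wells produced ",
            nrow(mins), " distinct minima", call. = FALSE)
  }
  m
}

## Minima and features ---------------------------------------------------------

# Persistence of every strict local minimum (union-find sweep in C++); used
# to suppress grid-noise duplicates.
minima_persistence <- function(grid, mins_idx) {
  grid_persistence(grid, as.integer(mins_idx))
}

#' Locate the minima of a free-energy map
#'
#' Strict local minima on the periodic grid (below all 8 neighbours), filtered
#' by topographic persistence to suppress grid-noise duplicates, with sub-bin
#' refinement of positions by a local quadratic fit.
#'
#' @param map A `dihedral_map` (normalized).
#' @param min_persistence Minimum barrier height (k_BT) separating a reported
#'   minimum from a deeper basin; shallower dimples are merged.
#' @return A tibble with columns `phi`, `psi`, `G`, `persistence`, sorted by
#'   `G`. A flat map yields zero rows and attribute `flat = TRUE`.
#' @export
find_minima <- function(map, min_persistence = 0.2) {
  G <- map$grid
  if (max(G) - min(G) < 1e-12) {
    out <- tibble::tibble(phi = numeric(), psi = numeric(),
                          G = numeric(), persistence = numeric())
    attr(out, "flat") <- TRUE
    return(out)
  }
  np <- nrow(G); nq <- ncol(G)
  sh <- function(m, di, dj) {
    m[((seq_len(np) - 1 + di) %% np) + 1, ((seq_len(nq) - 1 + dj) %% nq) + 1]
  }
  nbmin <- sh(G, 1, 0)
  for (d in list(c(-1, 0), c(0, 1), c(0, -1), c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    nbmin <- pmin(nbmin, sh(G, d[1], d[2]))
  }
  idx <- which(G < nbmin)
  if (length(idx) == 0) {
    out <- tibble::tibble(phi = numeric(), psi = numeric(),
                          G = numeric(), persistence = numeric())
    attr(out, "flat") <- FALSE
    return(out)
  }
  pers <- if (length(idx) > 1) minima_persistence(G, idx) else Inf
  keep <- pers >= min_persistence
  idx <- idx[keep]; pers <- pers[keep]
  dphi <- 2 * pi / np; dpsi <- 2 * pi / nq
  ref <- t(vapply(idx, function(cell) refine_minimum(G, cell, np, nq), numeric(3)))
  out <- tibble::tibble(
    phi = wrap_angle((((idx - 1L) %% np)) * dphi + ref[, 1] * dphi),
    psi = wrap_angle((((idx - 1L) %/% np)) * dpsi + ref[, 2] * dpsi),
    G = ref[, 3],
    persistence = pers
  )
  out <- out[order(out$G), ]
  attr(out, "flat") <- FALSE
  out
}

# Quadratic (paraboloid) refinement around a minimum bin; returns the sub-bin
# offset (in bin units, clamped to one bin) and the refined energy.
refine_minimum <- function(G, cell, np, nq) {
  i <- ((cell - 1L) %% np) + 1L
  j <- ((cell - 1L) %/% np) + 1L
  at <- function(di, dj) G[((i - 1L + di) %% np) + 1L, ((j - 1L + dj) %% nq) + 1L]
  gx <- (at(1, 0) - at(-1, 0)) / 2
  gy <- (at(0, 1) - at(0, -1)) / 2
  hxx <- at(1, 0) - 2 * at(0, 0) + at(-1, 0)
  hyy <- at(0, 1) - 2 * at(0, 0) + at(0, -1)
  hxy <- (at(1, 1) - at(1, -1) - at(-1, 1) + at(-1, -1)) / 4
  det <- hxx * hyy - hxy^2
  if (det <= 0 || hxx <= 0) return(c(0, 0, at(0, 0)))
  ox <- -(hyy * gx - hxy * gy) / det
  oy <- -(hxx * gy - hxy * gx) / det
  ox <- max(-1, min(1, ox)); oy <- max(-1, min(1, oy))
  val <- at(0, 0) + gx * ox + gy * oy +
    0.5 * (hxx * ox^2 + 2 * hxy * ox * oy + hyy * oy^2)
  c(ox, oy, val)
}

#' Free-energy gap to the second minimum
#'
#' @param map A `dihedral_map`.
#' @param min_persistence Passed to [find_minima()].
#' @return The energy (k_BT) of the second-lowest distinct minimum above the
#'   global one, or `NA_real_` if the map has fewer than two distinct minima.
#' @export
delta_g2 <- function(map, min_persistence = 0.2) {
  m <- find_minima(map, min_persistence)
  if (nrow(m) < 2) return(NA_real_)
  m$G[2] - m$G[1]
}

#' Fraction of the map accessible below an energy threshold
#'
#' @param map A `dihedral_map`.
#' @param threshold Threshold in k_BT (> 0).
#' @param strict Use strict `<` (the convention for the 1 k_BT main-minimum
#'   area) instead of `<=`.
#' @return Fraction of grid bins at or below the threshold.
#' @export
accessible_area_fraction <- function(map, threshold, strict = FALSE) {
  stopifnot(threshold > 0)
  if (strict) mean(map$grid < threshold) else mean(map$grid <= threshold)
}

#' Summarize the features of a map
#'
#' @param map A `dihedral_map`.
#' @param min_persistence Passed to [find_minima()].
#' @return A one-row tibble: link key, accessible-area fractions at 12 and
#'   (strictly below) 1 k_BT, main-minimum position, and the gap to the second
#'   minimum.
#' @export
map_features <- function(map, min_persistence = 0.2) {
  m <- find_minima(map, min_persistence)
  tibble::tibble(
    link_key = map$link_key,
    area_12kt = accessible_area_fraction(map, 12),
    area_1kt = accessible_area_fraction(map, 1, strict = TRUE),
    phi_min = if (nrow(m) > 0) m$phi[1] else NA_real_,
    psi_min = if (nrow(m) > 0) m$psi[1] else NA_real_,
    delta_g2 = if (nrow(m) >= 2) m$G[2] - m$G[1] else NA_real_,
    n_minima = nrow(m)
  )
}

## Cutoff restriction and sampling --------------------------------------------

#' Restrict a map to its low-energy region
#'
#' Pivot moves propose angles only inside the region of the map below the
#' cutoff; because the global minimum is 0, the region is never empty.
#'
#' @param map A `dihedral_map`.
#' @param cutoff Restriction energy in k_BT (default 7).
#' @return A `restricted_region`: allowed node indices plus grid metadata and
#'   a record of the parent link key.
#' @export
restrict_map <- function(map, cutoff = 7) {
  stopifnot(cutoff > 0)
  allowed <- which(map$grid <= cutoff)
  structure(list(
    parent = map$link_key,
    allowed = allowed,
    bin_count = length(allowed),
    n_phi = map$n_phi,
    n_psi = map$n_psi,
    cutoff = cutoff
  ), class = "restricted_region")
}

#' @export
print.restricted_region <- function(x, ...) {
  cat(sprintf("Restricted region [%s]: %d / %d bins below %.1f kT\n",
              ifelse(is.na(x$parent), "unkeyed", x$parent),
              x$bin_count, x$n_phi * x$n_psi, x$cutoff))
  invisible(x)
}

#' Sample uniformly from a restricted region
#'
#' Draws an allowed bin uniformly and jitters uniformly within the bin, so the
#' proposal density is uniform over the allowed area.
#'
#' @param region A `restricted_region`.
#' @param n Number of samples.
#' @return An `n x 2` matrix of `(phi, psi)` in radians.
#' @export
sample_region <- function(region, n = 1) {
  pick <- region$allowed[sample.int(region$bin_count, n, replace = TRUE)]
  dphi <- 2 * pi / region$n_phi
  dpsi <- 2 * pi / region$n_psi
  phi <- (((pick - 1L) %% region$n_phi)) * dphi + (stats::runif(n) - 0.5) * dphi
  psi <- (((pick - 1L) %/% region$n_phi)) * dpsi + (stats::runif(n) - 0.5) * dpsi
  cbind(phi = wrap_angle(phi), psi = wrap_angle(psi))
}

## Map library -----------------------------------------------------------------

#' Bundle maps into a link-keyed library
#'
#' @param maps Named list of `dihedral_map`s; names are link keys like
#'   `"GlcNH3+-GlcNAc"` (reducing end first).
#' @param cutoff Restriction energy in k_BT applied to every map.
#' @return A `map_library`.
#' @export
map_library <- function(maps, cutoff = 7) {
  stopifnot(is.list(maps), !is.null(names(maps)))
  shapes <- vapply(maps, function(m) paste(m$n_phi, m$n_psi), "")
  if (length(unique(shapes)) > 1) {
    stop("all maps in a library must share one grid shape", call. = FALSE)
  }
  structure(list(maps = maps, cutoff = cutoff), class = "map_library")
}

#' @export
print.map_library <- function(x, ...) {
  cat(sprintf("Map library: %d link types, cutoff %.1f kT\n",
              length(x$maps), x$cutoff))
  cat(" ", paste(names(x$maps), collapse = ", "), "\n")
  invisible(x)
}

#' Check that a library covers all nine link types
#'
#' A titrating simulation requires every combination of the three monomer
#' states at both ends of a link.
#'
#' @param library A `map_library`.
#' @return The library, invisibly; errors listing absent link types otherwise.
#' @export
validate_library <- function(library) {
  missing <- setdiff(link_keys(), names(library$maps))
  if (length(missing) > 0) {
    stop("map library is missing link types: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(library)
}

#' Look up the map for a link
#'
#' @param library A `map_library`.
#' @param left_state,right_state Monomer-state labels of the reducing-end and
#'   non-reducing-end monomers (`"GlcNAc"`, `"GlcNH2"`, `"GlcNH3+"`).
#' @return The corresponding `dihedral_map` (no copy).
#' @export
map_for_link <- function(library, left_state, right_state) {
  state_code(c(left_state, right_state))  # validates labels
  key <- link_key(left_state, right_state)
  m <- library$maps[[key]]
  if (is.null(m)) stop("map library is missing link type: ", key, call. = FALSE)
  m
}

#' Feature table for a whole library
#'
#' @param library A `map_library`.
#' @param min_persistence Passed to [find_minima()].
#' @return A tibble with one row per map (link key, accessible areas,
#'   main-minimum position, second-minimum gap).
#' @export
analyze_map_library <- function(library, min_persistence = 0.2) {
  dplyr::bind_rows(lapply(library$maps, map_features, min_persistence = min_persistence))
}
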