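# Shared fixtures: small synthetic maps and chains built in code.

# report every expectation rather than stopping at the default failure cap
options(testthat.progress.max_fails = Inf)

# Two-well map with a known gap between the minima.
make_twowell_map <- function(gap = 2.4, grid = c(120, 120),
                             centers = list(c(4.997, 2.188), c(3.797, 2.188 + pi)),
                             widths = c(0.2, 0.35), background = 20,
                             link_key = NA_character_) {
  wells <- data.frame(
    phi = c(centers[[1]][1], centers[[2]][1]),
    psi = c(centers[[1]][2], centers[[2]][2]),
    depth = c(background, background - gap),
    width_phi = widths, width_psi = widths
  )
  synthesize_map(wells, background = background, grid_spec = grid, link_key = link_key)
}

# Single-well map.
make_onewell_map <- function(grid = c(80, 80), center = c(2, 4), width = 0.3) {
  synthesize_map(
    data.frame(phi = center[1], psi = center[2], depth = 10,
               width_phi = width, width_psi = width),
    background = 10, grid_spec = grid
  )
}

# A small nine-map library on a reduced grid (fast to analyze and simulate).
small_library <- local({
  cache <- NULL
  function(grid = c(48, 48), cutoff = 7, background = 25) {
    if (!is.null(cache)) return(cache)
    params <- table2_map_parameters()
    maps <- lapply(seq_len(nrow(params)), function(k) {
      row <- params[k, ]
      suppressWarnings(synthesize_map(
        wells_from_features(row, background = background),
        background = background, grid_spec = grid, link_key = row$link_key
      ))
    })
    names(maps) <- params$link_key
    cache <<- map_library(maps, cutoff = cutoff)
    cache
  }
})

# Integrate exp(-G) of a map over each node bin (quadrature by sub-sampling),
# aggregated into coarse bins of `fold` x `fold` nodes. Independent oracle for
# the sampling distribution of the MC engine.
boltzmann_coarse_weights <- function(map, fold, allowed = NULL) {
  np <- map$n_phi
  d <- 2 * pi / np
  idx <- if (is.null(allowed)) seq_len(np * map$n_psi) else allowed
  sub <- expand.grid(a = seq(-0.4, 0.4, 0.2), b = seq(-0.4, 0.4, 0.2))
  w <- numeric(np * map$n_psi)
  ii <- (idx - 1) %% np
  jj <- (idx - 1) %/% np
  for (s in seq_len(nrow(sub))) {
    G <- map_interpolate(map, (ii + sub$a[s]) * d, (jj + sub$b[s]) * d)
    w[idx] <- w[idx] + exp(-G) / nrow(sub)
  }
  all_i <- 0:(np * map$n_psi - 1) %% np
  all_j <- 0:(np * map$n_psi - 1) %/% np
  as.vector(tapply(w, list(all_i %/% fold, all_j %/% fold), sum))
}

# Nearest-node coarse bin of continuous angles (matches the node-bin layout
# the engine proposes from).
coarse_bin_of <- function(ang, n_nodes, fold) {
  d <- 2 * pi / n_nodes
  (round(ang / d) %% n_nodes) %/% fold
}

resample_grid_for_test <- function(map, np, nq) {
  chitomc:::resample_grid(map, np, nq)
}
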