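# Metropolis Monte Carlo driver. One MC sweep is a single pivot move followed
# by `titration_moves_per_sweep` protonation attempts (default: one per
# titratable site). The fast path is the compiled engine; `pivot_move()` and
# `titration_move()` are the pure-R reference implementation of single moves,
# used as the independent cross-check of the compiled path.

.chitomc_env <- new.env(parent = emptyenv())

#' Default synthetic map library (cached per session)
#' @param cutoff Restriction energy in k_BT.
#' @return A `map_library`.
#' @export
default_map_library <- function(cutoff = 7) {
  key <- sprintf("lib_%g", cutoff)
  if (is.null(.chitomc_env[[key]])) {
    .chitomc_env[[key]] <- suppressWarnings(synthetic_map_library(cutoff = cutoff))
  }
  .chitomc_env[[key]]
}

map_global_minimum <- function(map) {
  cell <- which.min(map$grid)
  r <- refine_minimum(map$grid, cell, map$n_phi, map$n_psi)
  c(wrap_angle(((cell - 1) %% map$n_phi + r[1]) * 2 * pi / map$n_phi),
    wrap_angle(((cell - 1) %/% map$n_phi + r[2]) * 2 * pi / map$n_psi))
}

#' Simulation configuration
#'
#' @param dp Degree of polymerization.
#' @param dd Degree of deacetylation.
#' @param pattern Acetylation pattern (see [build_sequence()]).
#' @param ph,cs Solution pH and salt concentration (mol/L).
#' @param n_sweeps Number of MC sweeps (1 pivot + `titration_moves_per_sweep`
#'   titration attempts each).
#' @param seed RNG seed; fully determines the run.
#' @param library A `map_library` (default: the synthetic nine-map library).
#' @param params A [forcefield_params()].
#' @param conditions Optional [solution_conditions()]; built from `ph`, `cs`
#'   if omitted.
#' @param sequence Optional pre-built [build_sequence()] object.
#' @param titration_moves_per_sweep Titration attempts per pivot move;
#'   default one per titratable site (N_t).
#' @param log_stride Log observables every this many sweeps.
#' @param electrostatics,titration,map_swapping Feature switches.
#' @param static_map_key If set, every link uses this one map regardless of
#'   monomer states (the no-swapping comparison mode); forces
#'   `map_swapping = FALSE`.
#' @param burn_in Fraction of sweeps discarded before computing equilibrium
#'   averages.
#' @param collect_frames Keep site coordinates of every logged frame.
#' @param collect_dihedrals Keep per-link dihedrals of every logged frame.
#' @param geometry A [cg_geometry()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(dp = 100, dd = 1, pattern = "random",
                              ph = 4.5, cs = 0.1,
                              n_sweeps = 10000, seed = 1L,
                              library = NULL, params = forcefield_params(),
                              conditions = NULL, sequence = NULL,
                              titration_moves_per_sweep = NULL,
                              log_stride = 10L,
                              electrostatics = TRUE, titration = TRUE,
                              map_swapping = TRUE, static_map_key = NULL,
                              burn_in = 0.2,
                              collect_frames = FALSE, collect_dihedrals = FALSE,
                              geometry = cg_geometry()) {
  stopifnot(n_sweeps >= 1, burn_in >= 0, burn_in < 1)
  if (is.null(sequence)) sequence <- build_sequence(dp, dd, pattern, seed = seed)
  if (is.null(conditions)) conditions <- solution_conditions(ph = ph, cs = cs)
  if (is.null(library)) library <- default_map_library(cutoff = params$cutoff)
  if (!is.null(static_map_key)) map_swapping <- FALSE
  if (is.null(titration_moves_per_sweep)) titration_moves_per_sweep <- sequence$n_t
  structure(list(
    sequence = sequence, conditions = conditions, params = params,
    library = library, n_sweeps = as.integer(n_sweeps), seed = as.integer(seed),
    titration_moves_per_sweep = as.integer(titration_moves_per_sweep),
    log_stride = as.integer(log_stride),
    electrostatics = isTRUE(electrostatics), titration = isTRUE(titration),
    map_swapping = isTRUE(map_swapping), static_map_key = static_map_key,
    burn_in = burn_in,
    collect_frames = isTRUE(collect_frames),
    collect_dihedrals = isTRUE(collect_dihedrals),
    geometry = geometry
  ), class = "simulation_config")
}

# Initial charges: all titratable sites protonated below pK_i, neutral above.
initial_charges <- function(sequence, conditions, params) {
  z <- integer(sequence$dp)
  if (conditions$ph < params$pk_i) z[sequence$titratable] <- 1L
  z
}

# Map key per link from monomer state labels (or a single static key).
assign_link_maps <- function(library, labels, static_map_key = NULL) {
  if (!is.null(static_map_key)) {
    if (is.null(library$maps[[static_map_key]])) {
      stop("map library is missing link type: ", static_map_key, call. = FALSE)
    }
    return(rep(static_map_key, length(labels) - 1))
  }
  paste(labels[-length(labels)], labels[-1], sep = "-")
}

geometry_for_engine <- function(g) {
  list(o5 = g$atoms["O5", ], c1 = g$atoms["C1", ], o1 = g$atoms["O1", ],
       c4 = g$atoms["C4", ], site = g$site, a_loc = g$a_loc, b_loc = g$b_loc,
       bond_o1_c4 = g$bond_o1_c4, angle_c1_o1_c4 = g$angle_c1_o1_c4,
       bond_c4_c5 = g$bond_c4_c5, angle_o1_c4_c5 = g$angle_o1_c4_c5)
}

#' Run a Monte Carlo simulation
#'
#' Executes the configured schedule in the compiled engine: per sweep one
#' cutoff-restricted pivot move and (by default) one titration attempt per
#' titratable site, with map swapping on accepted protonation changes. Fully
#' reproducible from the seed.
#'
#' @param config A [simulation_config()].
#' @return An `mc_run`: the observable log (tibble), final state, counters,
#'   the measured virtual bond length `l`, and optional frames.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seq_ <- config$sequence
  cond <- config$conditions
  par_ <- config$params
  lib <- config$library
  if (config$titration && config$map_swapping) validate_library(lib)
  if (config$titration && seq_$n_t == 0) {
    warning("no titratable sites: titration moves skipped", call. = FALSE)
    config$titration <- FALSE
  }

  z0 <- initial_charges(seq_, cond, par_)
  labels <- monomer_state_labels(seq_, z0)
  link_keys_used <- assign_link_maps(lib, labels, config$static_map_key)

  map_names <- names(lib$maps)
  grids <- lapply(lib$maps, function(m) m$grid)
  allowed <- lapply(lib$maps, function(m) restrict_map(m, lib$cutoff)$allowed)
  state_idx <- matrix(0L, 3, 3)
  for (a in 0:2) for (b in 0:2) {
    key <- link_key(monomer_states()[a + 1], monomer_states()[b + 1])
    idx <- match(key, map_names)
    state_idx[a + 1, b + 1] <- ifelse(is.na(idx), 1L, idx)
  }
  link_idx0 <- match(link_keys_used, map_names)
  if (anyNA(link_idx0)) {
    stop("map library is missing link types: ",
         paste(unique(link_keys_used[is.na(link_idx0)]), collapse = ", "),
         call. = FALSE)
  }

  # initial conformation: every link at its map's global minimum
  mins <- lapply(lib$maps, map_global_minimum)
  dih0 <- do.call(rbind, mins[link_idx0])
  conf0 <- rebuild_coordinates(seq_, dih0, config$geometry)
  l <- bond_vectors(conf0)$l

  mu <- protonation_mu(cond$ph, par_$pk_i)
  res <- with_seed(config$seed, cg_run_engine(
    geometry_for_engine(config$geometry),
    as.integer(seq_$kinds == "GlcN"), z0,
    grids, allowed, as.integer(link_idx0), state_idx, dih0,
    cond$lambda_b, cond$kappa, mu,
    par_$sigma_lj, par_$eps_kbt, par_$r_c,
    config$electrostatics, config$titration, config$map_swapping,
    par_$include_bonded_in_titration, par_$double_count_titration_pairs,
    config$n_sweeps, config$titration_moves_per_sweep, config$log_stride,
    config$collect_frames, config$collect_dihedrals
  ))

  log <- tibble::as_tibble(as.data.frame(res$log))
  log$e_total <- log$e_map + log$e_lj + log$e_dh + log$f_mu + log$f_pair
  structure(list(
    log = log,
    config = config,
    l = l,
    contour_length = (seq_$dp - 1) * l,
    final = list(dihedrals = res$dihedrals, charges = res$charges,
                 link_map_idx = res$link_map_idx,
                 link_map_keys = map_names[res$link_map_idx],
                 sites = res$sites),
    energies = res$energies,
    counters = res$counters,
    frames = if (config$collect_frames) res$frames else NULL,
    dihedral_trace = if (config$collect_dihedrals) res$dihedral_trace else NULL
  ), class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  eq <- equilibrium_window(x)
  cat(sprintf("MC run: DP %d, DD %.2f, pH %.2f, cs %.4g M, %d sweeps (seed %d)\n",
              x$config$sequence$dp, x$config$sequence$dd,
              x$config$conditions$ph, x$config$conditions$cs,
              x$config$n_sweeps, x$config$seed))
  cat(sprintf("  <Rg> %.3f nm, <Ree> %.3f nm, <alpha> %.3f (post burn-in)\n",
              mean(x$log$rg[eq]), mean(x$log$ree[eq]), mean(x$log$alpha[eq])))
  ar <- acceptance_report(x)
  cat(sprintf("  acceptance: pivot %.3f, titration %s\n", ar$rate[ar$move == "pivot"],
              ifelse(is.na(ar$rate[ar$move == "titration"]), "-",
                     sprintf("%.3f", ar$rate[ar$move == "titration"]))))
  invisible(x)
}

# Logical index of post-burn-in log rows.
equilibrium_window <- function(run, burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- run$config$burn_in
  run$log$step > burn_in * max(run$log$step)
}

#' Acceptance rates by move type
#'
#' Rates over the post-burn-in window, recomputed from the raw attempt and
#' acceptance counters in the log.
#'
#' @param run An `mc_run`.
#' @param burn_in Burn-in fraction; default from the run's config.
#' @return A tibble with columns `move`, `attempted`, `accepted`, `rate`.
#' @export
acceptance_report <- function(run, burn_in = NULL) {
  log <- run$log
  eq <- equilibrium_window(run, burn_in)
  first <- which(eq)[1]
  base <- if (is.na(first) || first == 1) {
    list(pa = 0, pc = 0, ta = 0, tc = 0)
  } else {
    list(pa = log$pivot_attempted[first - 1], pc = log$pivot_accepted[first - 1],
         ta = log$titration_attempted[first - 1], tc = log$titration_accepted[first - 1])
  }
  n <- nrow(log)
  pa <- log$pivot_attempted[n] - base$pa
  pc <- log$pivot_accepted[n] - base$pc
  ta <- log$titration_attempted[n] - base$ta
  tc <- log$titration_accepted[n] - base$tc
  tibble::tibble(
    move = c("pivot", "titration"),
    attempted = c(pa, ta),
    accepted = c(pc, tc),
    rate = c(ifelse(pa > 0, pc / pa, NA_real_), ifelse(ta > 0, tc / ta, NA_real_))
  )
}

#' Stationarity check of the equilibrium window
#'
#' Splits the post-burn-in R_G samples into first and last thirds and tests
#' whether their means agree within `n_se` combined standard errors (standard
#' errors from non-overlapping block means to absorb autocorrelation).
#'
#' @param run An `mc_run`.
#' @param observable Log column to check (default `"rg"`).
#' @param n_se Agreement criterion in combined standard errors.
#' @param n_blocks Number of blocks per third for the SE estimate.
#' @return A list: `stationary` (logical), `z`, and the two means.
#' @export
check_stationarity <- function(run, observable = "rg", n_se = 2, n_blocks = 10) {
  x <- run$log[[observable]][equilibrium_window(run)]
  n <- length(x)
  stopifnot(n >= 3 * n_blocks)
  third <- floor(n / 3)
  block_se <- function(v) {
    b <- floor(length(v) / n_blocks)
    m <- vapply(seq_len(n_blocks), function(k) mean(v[((k - 1) * b + 1):(k * b)]), 0)
    stats::sd(m) / sqrt(n_blocks)
  }
  a <- x[1:third]; b <- x[(n - third + 1):n]
  z <- (mean(a) - mean(b)) / sqrt(block_se(a)^2 + block_se(b)^2)
  list(stationary = abs(z) <= n_se, z = z, mean_first = mean(a), mean_last = mean(b))
}

## Pure-R reference implementation of single moves -----------------------------

#' Build an explicit MC state (reference implementation)
#'
#' Slow, transparent state container used to cross-check the compiled engine:
#' energies are recomputed from scratch by the R energy functions.
#'
#' @param config A [simulation_config()].
#' @return An `mc_state`.
#' @export
mc_state <- function(config) {
  seq_ <- config$sequence
  z <- initial_charges(seq_, config$conditions, config$params)
  labels <- monomer_state_labels(seq_, z)
  keys <- assign_link_maps(config$library, labels, config$static_map_key)
  mins <- lapply(config$library$maps, map_global_minimum)
  dih0 <- do.call(rbind, mins[keys])
  conf <- rebuild_coordinates(seq_, dih0, config$geometry)
  structure(list(
    config = config, sequence = seq_, charges = z, link_keys = keys,
    conformation = conf,
    counters = c(pivot_attempted = 0, pivot_accepted = 0,
                 titration_attempted = 0, titration_accepted = 0)
  ), class = "mc_state")
}

#' Energy breakdown of an MC state (full recompute)
#'
#' @param state An `mc_state`.
#' @return A list with `e_map`, `e_lj`, `e_dh`, `f_mu`, `f_pair`, `total`,
#'   all in k_BT.
#' @export
state_energy <- function(state) {
  cfg <- state$config
  dih <- state$conformation$dihedrals
  e_map <- sum(vapply(seq_along(state$link_keys), function(k) {
    map_interpolate(cfg$library$maps[[state$link_keys[k]]], dih[k, 1], dih[k, 2])
  }, 0))
  nb <- nonbonded_energy(state$conformation, state$charges, cfg$conditions, cfg$params)
  if (!cfg$electrostatics) nb$e_dh <- 0
  tit <- titration_energy(state$conformation, state$charges, cfg$conditions, cfg$params)
  if (!cfg$electrostatics) tit$f_pair <- 0
  list(e_map = e_map, e_lj = nb$e_lj, e_dh = nb$e_dh,
       f_mu = tit$f_mu, f_pair = tit$f_pair,
       total = e_map + nb$e_lj + nb$e_dh + tit$f_mu + tit$f_pair)
}

#' Single pivot move (reference implementation)
#'
#' Chooses a link uniformly (or takes the given one), proposes `(phi, psi)`
#' uniformly over the link map's allowed region (or takes the given pair),
#' and accepts with the Metropolis probability for the map + steric +
#' screened-electrostatic energy change.
#'
#' @param state An `mc_state`.
#' @param link Optional link index.
#' @param proposal Optional `c(phi, psi)` proposal.
#' @return The updated `mc_state`, with attributes `accepted` and `delta_e`.
#' @export
pivot_move <- function(state, link = NULL, proposal = NULL) {
  cfg <- state$config
  nlink <- state$sequence$dp - 1
  if (is.null(link)) link <- sample.int(nlink, 1)
  map <- cfg$library$maps[[state$link_keys[link]]]
  if (is.null(proposal)) {
    proposal <- sample_region(restrict_map(map, cfg$library$cutoff), 1)[1, ]
  }
  old_e <- state_energy(state)
  cand <- state
  cand$conformation <- pivot_update(state$conformation, link, proposal)
  new_e <- state_energy(cand)
  d_e <- (new_e$e_map + new_e$e_lj + new_e$e_dh) - (old_e$e_map + old_e$e_lj + old_e$e_dh)
  accepted <- d_e <= 0 || stats::runif(1) < exp(-d_e)
  out <- if (accepted) cand else state
  out$counters["pivot_attempted"] <- state$counters["pivot_attempted"] + 1
  out$counters["pivot_accepted"] <- state$counters["pivot_accepted"] + accepted
  attr(out, "accepted") <- accepted
  attr(out, "delta_e") <- d_e
  out
}

#' Single titration move (reference implementation)
#'
#' Flips the protonation state of one titratable site; the acceptance uses
#' the chemical potential plus the change of the pairwise screened
#' electrostatics over all charged pairs including nearest neighbours. On
#' acceptance the maps of the adjacent links are reassigned to the new
#' monomer states.
#'
#' @param state An `mc_state`.
#' @param site Optional monomer index of a titratable site.
#' @return The updated `mc_state`, with attributes `accepted` and `delta_f`.
#' @export
titration_move <- function(state, site = NULL) {
  cfg <- state$config
  seq_ <- state$sequence
  if (seq_$n_t == 0) {
    warning("no titratable sites: titration move skipped", call. = FALSE)
    return(state)
  }
  if (is.null(site)) site <- seq_$titratable[sample.int(seq_$n_t, 1)]
  stopifnot(site %in% seq_$titratable)
  old_e <- state_energy(state)
  cand <- state
  cand$charges[site] <- 1L - state$charges[site]
  labels <- monomer_state_labels(seq_, cand$charges)
  cand$link_keys <- assign_link_maps(cfg$library, labels, cfg$static_map_key)
  new_e <- state_energy(cand)
  d_f <- (new_e$f_mu + new_e$f_pair) - (old_e$f_mu + old_e$f_pair)
  if (cfg$params$include_bonded_in_titration) {
    d_f <- d_f + new_e$e_map - old_e$e_map
  }
  accepted <- d_f <= 0 || stats::runif(1) < exp(-d_f)
  out <- if (accepted) cand else state
  if (accepted && !cfg$map_swapping && is.null(cfg$static_map_key)) {
    out$link_keys <- state$link_keys  # keep old maps when swapping is off
  }
  out$counters["titration_attempted"] <- state$counters["titration_attempted"] + 1
  out$counters["titration_accepted"] <- state$counters["titration_accepted"] + accepted
  attr(out, "accepted") <- accepted
  attr(out, "delta_f") <- d_f
  out
}
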