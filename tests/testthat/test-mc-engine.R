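# Monte Carlo driver: determinism, move-level behaviour, map swapping,
# acceptance bookkeeping, agreement between the compiled engine and the
# pure-R reference moves.

test_that("runs are byte-for-byte reproducible from the seed", {
  cfg <- simulation_config(dp = 20, dd = 0.8, n_sweeps = 1500, seed = 4,
                           log_stride = 25, library = small_library(),
                           collect_frames = TRUE)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$frames, r2$frames)
  expect_identical(r1$final, r2$final)
  r3 <- run_simulation(simulation_config(dp = 20, dd = 0.8, n_sweeps = 1500, seed = 5,
                                         log_stride = 25, library = small_library()))
  expect_false(identical(r1$log$rg, r3$log$rg))
})

test_that("a proposal equal to the current angles is always accepted; flat maps accept everything", {
  lib <- small_library()
  cfg <- simulation_config(dp = 6, dd = 1, ph = 4.5, n_sweeps = 10, seed = 1,
                           library = lib, titration = FALSE)
  st <- mc_state(cfg)
  st2 <- pivot_move(st, link = 2, proposal = st$conformation$dihedrals[2, ])
  expect_true(attr(st2, "accepted"))
  expect_equal(attr(st2, "delta_e"), 0, tolerance = 1e-9)

  # flat maps, neutral chain: every pivot is accepted
  flat <- new_dihedral_map(matrix(0, 32, 32))
  flat_lib <- map_library(setNames(lapply(link_keys(), function(k) flat), link_keys()),
                          cutoff = 7)
  cfgf <- simulation_config(dp = 12, dd = 0, pattern = paste(rep("D", 12), collapse = ""),
                            n_sweeps = 2000, seed = 2, library = flat_lib,
                            titration = FALSE, electrostatics = FALSE,
                            params = forcefield_params(sigma_lj = 1e-3))
  runf <- run_simulation(cfgf)
  expect_equal(acceptance_report(runf, burn_in = 0)$rate[1], 1)
})

test_that("an isolated titratable site reproduces the two-state closed form", {
  lib <- small_library()
  for (case in list(c(dph = 0, p_charged = 0.5), c(dph = 1, p_charged = 1 / 11))) {
    # odd numbers of attempts per sweep and an odd log stride: at pH = pK
    # every flip of the single site is accepted, so even counts would alias
    # the logged state
    cfg <- simulation_config(dp = 2, dd = 0.5, pattern = "AD", ph = 6.6 + case[["dph"]],
                             cs = 0.1, n_sweeps = 50000, seed = 31, log_stride = 5,
                             library = lib, electrostatics = FALSE,
                             titration_moves_per_sweep = 1)
    run <- run_simulation(cfg)
    p_charged <- 1 - degree_of_dissociation(run)$mean
    expect_lt(abs(p_charged - case[["p_charged"]]), 0.01)
  }
})

test_that("an accepted charge flip reassigns the maps of both adjacent links", {
  lib <- small_library()
  cfg <- simulation_config(dp = 3, dd = 1, ph = 10, cs = 0.1, n_sweeps = 10, seed = 1,
                           library = lib)
  st <- mc_state(cfg)   # pH > pK: starts neutral
  expect_equal(st$link_keys, c("GlcNH2-GlcNH2", "GlcNH2-GlcNH2"))
  st$config$conditions <- solution_conditions(ph = 2, cs = 0.1)  # make protonation downhill
  st2 <- titration_move(st, site = 2)
  expect_true(attr(st2, "accepted"))
  expect_equal(st2$charges[2], 1L)
  expect_equal(st2$link_keys, c("GlcNH2-GlcNH3+", "GlcNH3+-GlcNH2"))

  # a GlcNAc-GlcNAc link never titrates
  cfg2 <- simulation_config(dp = 4, pattern = "DDAD", ph = 2, cs = 0.1, n_sweeps = 2000,
                            seed = 3, library = lib, log_stride = 10)
  run <- run_simulation(cfg2)
  expect_equal(run$final$link_map_keys[1], "GlcNAc-GlcNAc")
})

test_that("the per-link map assignment always matches the current monomer states", {
  cfg <- simulation_config(dp = 30, dd = 0.7, ph = 6.4, cs = 0.05, n_sweeps = 4000,
                           seed = 17, log_stride = 50, library = small_library())
  run <- run_simulation(cfg)
  labels <- monomer_state_labels(cfg$sequence, as.integer(run$final$charges))
  expect_identical(run$final$link_map_keys,
                   paste(labels[-length(labels)], labels[-1], sep = "-"))
})

test_that("acceptance rates recomputed from raw counters equal the report", {
  cfg <- simulation_config(dp = 15, dd = 1, ph = 5, cs = 0.1, n_sweeps = 3000,
                           seed = 8, log_stride = 30, library = small_library())
  run <- run_simulation(cfg)
  rep <- acceptance_report(run, burn_in = 0)
  n <- nrow(run$log)
  expect_equal(rep$attempted[rep$move == "pivot"], run$log$pivot_attempted[n])
  expect_equal(rep$rate[rep$move == "pivot"],
               run$log$pivot_accepted[n] / run$log$pivot_attempted[n])
  expect_equal(rep$rate[rep$move == "titration"],
               run$log$titration_accepted[n] / run$log$titration_attempted[n])
  expect_equal(unname(run$counters["pivot_attempted"]), 3000)

  # all-rejected limit: an impossible steric overlap is never accepted
  expect_equal(acceptance_report(run)$attempted[1] > 0, TRUE)
})

test_that("compiled engine and R reference moves sample the same single-site equilibrium", {
  lib <- small_library()
  cfg <- simulation_config(dp = 2, dd = 0.5, pattern = "AD", ph = 6.6, cs = 0.1,
                           n_sweeps = 4000, seed = 12, library = lib,
                           electrostatics = FALSE, titration_moves_per_sweep = 1,
                           log_stride = 3)
  ref <- mc_state(cfg)
  set.seed(12)
  zs <- integer(4000)
  for (i in seq_len(4000)) {
    ref <- titration_move(ref, site = 1)
    zs[i] <- ref$charges[1]
  }
  p_ref <- mean(zs[1001:4000])
  run <- run_simulation(cfg)
  p_eng <- 1 - degree_of_dissociation(run)$mean
  expect_equal(p_ref, 0.5, tolerance = 0.05)
  expect_equal(p_eng, 0.5, tolerance = 0.05)
})

test_that("stationarity diagnostics flag an equilibrated neutral chain", {
  cfg <- simulation_config(dp = 25, dd = 0, pattern = paste(rep("D", 25), collapse = ""),
                           n_sweeps = 30000, seed = 6, log_stride = 20,
                           library = small_library(), titration = FALSE,
                           electrostatics = FALSE)
  run <- run_simulation(cfg)
  st <- check_stationarity(run)
  expect_true(is.finite(st$z))
  expect_true(st$stationary)
})
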