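# Energy terms: closed-form values, shape properties, bookkeeping.

test_that("Bjerrum length matches water at 298 K and scales inversely with permittivity", {
  expect_equal(bjerrum_length(298, 78.5), 0.714, tolerance = 1e-3)
  expect_equal(bjerrum_length(298, 78.5), 0.7139, tolerance = 1e-3)
  expect_equal(bjerrum_length(298, 2 * 78.5), bjerrum_length(298, 78.5) / 2)
  expect_error(bjerrum_length(-1), "temperature")
})

test_that("Debye length reproduces the printed screening lengths and the square-root law", {
  k01 <- kappa_from_ionic_strength(0.1)
  k1 <- kappa_from_ionic_strength(1.0)
  expect_lt(abs(1 / k01 - 0.96), 0.01)
  expect_lt(abs(1 / k1 - 0.30), 0.01)
  expect_equal(1 / kappa_from_ionic_strength(4 * 0.1), (1 / k01) / 2, tolerance = 1e-12)

  cond <- solution_conditions(ph = 7, cs = 0.1)
  expect_equal(debye_length(cond), 1 / cond$kappa)
  cond0 <- solution_conditions(ph = 14, cs = 0, include_ph_in_ionic_strength = FALSE)
  expect_message(dl <- debye_length(cond0), "infinite")
  expect_identical(dl, Inf)

  # the proton contribution matters at low pH: c_eff = c_s + 10^-pH
  c3 <- solution_conditions(ph = 2, cs = 0.1)
  expect_equal(c3$c_eff, 0.11)
  expect_gt(c3$kappa, solution_conditions(ph = 7, cs = 0.1)$kappa)
})

test_that("WCA potential has the closed-form values and repulsive shape", {
  p <- forcefield_params(sigma_lj = 0.65)
  expect_equal(wca_energy(p$r_c, p), 0)
  expect_equal(wca_energy(p$r_c - 1e-9, p), 0, tolerance = 1e-6)  # continuity
  expect_equal(wca_energy(p$r_c + 1e-9, p), 0)
  expect_equal(wca_energy(p$sigma_lj, p), p$eps_kbt)
  # independent arithmetic at r = 0.9 sigma
  r <- 0.9 * p$sigma_lj
  s6 <- (1 / 0.9)^6
  expect_equal(wca_energy(r, p), 4 * (0.6276 / kbt_kjmol(298)) * (s6^2 - s6 + 0.25))
  rs <- seq(0.4 * p$sigma_lj, p$r_c, length.out = 50)
  u <- wca_energy(rs, p)
  expect_true(all(u >= 0))
  expect_true(all(diff(u) <= 1e-12))
  expect_error(wca_energy(0, p), "positive")
  expect_equal(sigma_from_msa(4 * pi * 0.325^2), 0.65)
})

test_that("Debye-Hueckel pair energy matches closed forms and decays monotonically", {
  cond <- solution_conditions(ph = 7, cs = 0.1)
  expect_equal(dh_pair_energy(0, 1, 1.0, cond), 0)
  expect_equal(dh_pair_energy(1, 0, 0.5, cond), 0)

  cond0 <- solution_conditions(ph = 14, cs = 0, include_ph_in_ionic_strength = FALSE)
  expect_equal(dh_pair_energy(1, 1, cond0$lambda_b, cond0), 1, tolerance = 1e-12)

  # z=1,1 at r = kappa^-1 = 0.96 nm with lambda_B = 0.714: (0.714/0.96) e^-1
  cond96 <- solution_conditions(ph = 7, cs = 0.1)
  r <- 1 / cond96$kappa
  expect_equal(dh_pair_energy(1, 1, r, cond96), (cond96$lambda_b / r) * exp(-1))
  expect_equal((0.714 / 0.96) * exp(-1), 0.2736, tolerance = 1e-3)

  rs <- seq(0.3, 5, length.out = 40)
  u <- dh_pair_energy(1, 1, rs, cond96)
  expect_true(all(diff(u) < 0))
  u_lowsalt <- dh_pair_energy(1, 1, rs, solution_conditions(ph = 7, cs = 0.01))
  expect_true(all(u_lowsalt > u))
  expect_error(dh_pair_energy(1, 1, -1, cond96), "positive")
})

test_that("protonation chemical potential is ln(10) (pH - pK)", {
  expect_equal(protonation_mu(6.6, 6.6), 0)
  expect_equal(protonation_mu(5.6, 6.6), -log(10))
  expect_equal(protonation_mu(4.5, 6.6), -4.835, tolerance = 1e-3)
})

test_that("non-bonded sums exclude adjacent pairs; titration sum includes them", {
  g <- cg_geometry()
  cond <- solution_conditions(ph = 4.5, cs = 0.1)
  par <- forcefield_params(sigma_lj = 0.3)
  conf <- rebuild_coordinates(3, matrix(rep(c(4.997, 2.188), 2), ncol = 2, byrow = TRUE), g)

  # fully neutral: no electrostatics anywhere
  nb0 <- nonbonded_energy(conf, c(0L, 0L, 0L), cond, par)
  expect_equal(nb0$e_dh, 0)

  # monomers 1 and 3 charged: conformational DH equals the single pair energy
  z <- c(1L, 0L, 1L)
  nb <- nonbonded_energy(conf, z, cond, par)
  r13 <- sqrt(sum((conf$sites[3, ] - conf$sites[1, ])^2))
  expect_equal(nb$e_dh, dh_pair_energy(1, 1, r13, cond))

  # adjacent charges contribute nothing conformationally but do titrate
  zadj <- c(1L, 1L, 0L)
  expect_equal(nonbonded_energy(conf, zadj, cond, par)$e_dh, 0)
  r12 <- sqrt(sum((conf$sites[2, ] - conf$sites[1, ])^2))
  tit <- titration_energy(conf, zadj, cond, par)
  mu <- protonation_mu(4.5, 6.6)
  expect_equal(tit$f_prot, 2 * mu + dh_pair_energy(1, 1, r12, cond))

  # single charged site: F_prot = mu exactly; all neutral: 0
  expect_equal(titration_energy(conf, c(0L, 1L, 0L), cond, par)$f_prot, mu)
  expect_equal(titration_energy(conf, c(0L, 0L, 0L), cond, par)$f_prot, 0)

  # literal double-sum reading doubles the pair term only
  par2 <- forcefield_params(sigma_lj = 0.3, double_count_titration_pairs = TRUE)
  tit2 <- titration_energy(conf, zadj, cond, par2)
  expect_equal(tit2$f_pair, 2 * tit$f_pair)
  expect_equal(tit2$f_mu, tit$f_mu)
})

test_that("incremental engine bookkeeping stays on the full recompute over long runs", {
  cfg <- simulation_config(dp = 25, dd = 0.8, ph = 5.5, cs = 0.05, n_sweeps = 5000,
                           seed = 21, log_stride = 100, library = small_library())
  run <- run_simulation(cfg)
  st <- mc_state(cfg)
  st$charges <- as.integer(run$final$charges)
  st$link_keys <- run$final$link_map_keys
  st$conformation <- rebuild_coordinates(cfg$sequence, run$final$dihedrals, cfg$geometry)
  e <- state_energy(st)
  expect_lt(abs(e$e_map - run$energies[["e_map"]]), 1e-6)
  expect_lt(abs(e$e_lj - run$energies[["e_lj"]]), 1e-6)
  expect_lt(abs(e$e_dh - run$energies[["e_dh"]]), 1e-6)
  expect_lt(abs(e$f_mu - run$energies[["f_mu"]]), 1e-6)
  expect_lt(abs(e$f_pair - run$energies[["f_pair"]]), 1e-6)
  expect_lt(max(abs(st$conformation$sites - run$final$sites)), 1e-8)
})
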