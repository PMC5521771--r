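# Chain-statistics estimators against analytic and generated oracles.

test_that("radius of gyration matches closed forms and the ideal-chain law", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(3, 0, 0))), 1.5)

  # long uniform rod: L / sqrt(12)
  n <- 4000
  rod <- cbind(seq(0, 10, length.out = n), 0, 0)
  expect_equal(radius_of_gyration(rod), 10 / sqrt(12), tolerance = 1e-3)

  # freely jointed chain: <R_G^2> = N b^2 / 6
  fr <- generate_ideal_chain_frames(dp = 1000, n_frames = 120, l = 1, correlation = 0, seed = 5)
  rg2 <- vapply(seq_len(120), function(i) radius_of_gyration(fr[i, , ])^2, 0)
  se <- stats::sd(rg2) / sqrt(120)
  expect_lt(abs(mean(rg2) - 1000 / 6), 3 * se)
})

test_that("bond correlation is 1 for rods, 0 for freely jointed chains, cos^n for freely rotating chains", {
  rod <- cbind(0:50, 0, 0)
  ck <- bond_correlation(rod)
  expect_true(all(abs(ck$c_k - 1) < 1e-12))

  fjc <- generate_ideal_chain_frames(dp = 200, n_frames = 150, correlation = 0, seed = 2)
  ckf <- bond_correlation(fjc, max_lag = 10)
  expect_lt(max(abs(ckf$c_k)), 0.02)

  frc <- generate_ideal_chain_frames(dp = 400, n_frames = 400, l = 0.5, correlation = 0.9, seed = 3)
  ckr <- bond_correlation(frc, max_lag = 12)
  expect_equal(ckr$c_k, 0.9^(1:12), tolerance = 0.03)
})

test_that("persistence-length fit is exact on an exponential and finds the slow scale of a mixture", {
  lp <- 10; l <- 0.5
  ck <- tibble::tibble(n = 1:100, c_k = exp(-(1:100) * l / lp))
  fit <- persistence_length_fit(ck, l)
  expect_equal(fit$lp, 10, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)

  # two-scale decay: the default large-n window returns the slow scale
  ck2 <- tibble::tibble(n = 1:200,
                        c_k = 0.6 * exp(-(1:200) * l / 1) + 0.4 * exp(-(1:200) * l / 20))
  fit2 <- persistence_length_fit(ck2, l)
  expect_equal(fit2$lp, 20, tolerance = 0.05 * 20)

  expect_error(persistence_length_fit(ck[1, ], l, fit_window = c(1, 1)),
               "fewer than two")
  expect_error(persistence_length_fit(tibble::tibble(n = 1:5, c_k = rep(0.9, 5)), l,
                                      fit_window = c(1, 5)))
})

test_that("Benoit-Doty inversion recovers forward-evaluated persistence lengths", {
  for (lp in c(0.8, 5, 42)) {
    L <- 500
    rg <- sqrt(chitomc:::benoit_doty_rhs(lp, L) * L / 3)
    expect_equal(benoit_doty_lp(rg, L)$lp, lp, tolerance = 1e-6 * lp)
  }
  # long-chain limit: the approximation converges on the full inversion
  L <- 5000
  rg <- sqrt(chitomc:::benoit_doty_rhs(5, L) * L / 3)
  bd <- benoit_doty_lp(rg, L)
  expect_equal(bd$lp_long_chain, bd$lp, tolerance = 0.01 * bd$lp)
  # rod bound
  expect_error(benoit_doty_lp(sqrt(100^2 / 12), 100), "rod")
})

test_that("expansion factors have the exact printed coefficients", {
  expect_identical(alpha_el_expansion(0), 1)   # 0.541 + 0.459 = 1 exactly
  expect_identical(alpha_r_expansion(0), 1)
  expect_equal(alpha_r_expansion(0.1)^2, 1 + 0.133 - 0.02075 + 0.006459)
  z <- seq(0, 1, 0.05)
  expect_true(all(diff(alpha_r_expansion(z)) > 0))
  expect_true(all(diff(alpha_el_expansion(z)) > 0))
})

test_that("the Odijk iteration recovers a self-consistently expanded chain", {
  L <- 470; kappa <- 1 / 0.96; lp_true <- 8
  rg0 <- sqrt(chitomc:::benoit_doty_rhs(lp_true, L) * L / 3)
  z <- z_el_parameter(L, kappa, lp_true)
  rg <- alpha_el_expansion(z) * rg0
  est <- odijk_iteration(rg, L, kappa, charge_spacing = 0.5)
  expect_equal(est$lp, lp_true, tolerance = 0.02 * lp_true)
  expect_equal(est$rg0, rg0, tolerance = 0.02 * rg0)
  expect_equal(est$z_el, z, tolerance = 0.02 * z)

  # strong screening: z_el -> 0, L_P,0 -> L_P
  est2 <- odijk_iteration(rg0, L, kappa = 1e4, charge_spacing = 0.5)
  expect_lt(est2$z_el, 1e-3)
  expect_equal(est2$lp0_osf, est2$lp, tolerance = 1e-3 * est2$lp)
  expect_equal(est2$alpha_el, 1, tolerance = 1e-3)
})

test_that("characteristic ratio is 1 for ideal chains, n for rods, and plateaus at the FRC limit", {
  fjc <- generate_ideal_chain_frames(dp = 300, n_frames = 200, l = 1, correlation = 0, seed = 9)
  cn <- characteristic_ratio(fjc, l = 1, n_values = c(5, 20, 80))
  expect_equal(cn$c_n, rep(1, 3), tolerance = 0.05)

  rod <- cbind(0:60, 0, 0)
  cnr <- characteristic_ratio(rod, l = 1, n_values = c(2, 10, 40))
  expect_equal(cnr$c_n, c(2, 10, 40))

  # freely rotating chain: C_inf = (1 + c) / (1 - c)
  cc <- 0.8
  frc <- generate_ideal_chain_frames(dp = 500, n_frames = 250, l = 1, correlation = cc, seed = 10)
  cninf <- characteristic_ratio(frc, l = 1, n_values = 300)$c_n
  expect_equal(cninf, (1 + cc) / (1 - cc), tolerance = 0.08 * cninf)
})

test_that("three persistence-length routes agree on a discrete worm-like chain", {
  cc <- 0.9; l <- 0.5
  lp_true <- frc_persistence_length(l, cc)
  fr <- generate_ideal_chain_frames(dp = 600, n_frames = 250, l = l, correlation = cc, seed = 14)
  # route 1: bond-correlation fit
  lp_ck <- persistence_length_fit(bond_correlation(fr, max_lag = 80), l)$lp
  # route 2: Benoit-Doty from the ensemble R_G
  rg2 <- mean(vapply(seq_len(250), function(i) radius_of_gyration(fr[i, , ])^2, 0))
  lp_bd <- benoit_doty_lp(sqrt(rg2), 599 * l)$lp
  # route 3: characteristic-ratio plateau, L_P = (C_inf + 1) l / 2
  cinf <- characteristic_ratio(fr, l = l, n_values = 400)$c_n
  lp_cn <- (cinf + 1) * l / 2
  for (lp in c(lp_ck, lp_bd, lp_cn)) {
    expect_equal(lp, lp_true, tolerance = 0.10 * lp_true)
  }
})

test_that("Henderson-Hasselbalch fitting is exact on its own functional form", {
  ph <- seq(4.5, 8.5, 0.25)
  ideal <- tibble::tibble(ph = ph, alpha = 1 / (1 + 10^(6.6 - ph)))
  fit <- henderson_hasselbalch_fit(ideal)
  expect_equal(fit$n, 1, tolerance = 1e-10)
  expect_equal(fit$pk_app, 6.6, tolerance = 1e-10)
  expect_equal(fit$pk_half, 6.6, tolerance = 0.02)

  # generated with n = 1.5, pK = 6.0: recovered to 0.01
  gen <- tibble::tibble(ph = ph, alpha = 1 / (1 + 10^(-(ph - 6.0) / 1.5)))
  fit2 <- henderson_hasselbalch_fit(gen)
  expect_equal(fit2$n, 1.5, tolerance = 0.01)
  expect_equal(fit2$pk_app, 6.0, tolerance = 0.01)

  # no points inside the logit window
  flat <- tibble::tibble(ph = c(3, 3.5, 4), alpha = c(0.999, 0.9995, 0.9999))
  expect_error(henderson_hasselbalch_fit(flat), "logit window")
})

test_that("degree of dissociation tracks the charge state exactly at the extremes", {
  lib <- small_library()
  # pH far below pK, titration off: chain stays fully charged, alpha = 0
  cfg <- simulation_config(dp = 10, dd = 1, ph = 1, cs = 0.1, n_sweeps = 500, seed = 2,
                           library = lib, titration = FALSE, log_stride = 10)
  expect_equal(degree_of_dissociation(run_simulation(cfg))$mean, 0)
  # pH far above pK: fully neutral, alpha = 1
  cfg2 <- simulation_config(dp = 10, dd = 1, ph = 12, cs = 0.1, n_sweeps = 500, seed = 2,
                            library = lib, titration = FALSE, log_stride = 10)
  expect_equal(degree_of_dissociation(run_simulation(cfg2))$mean, 1)
  # no titratable sites: explicit error
  cfg3 <- simulation_config(dp = 10, dd = 0, pattern = paste(rep("D", 10), collapse = ""),
                            n_sweeps = 100, seed = 2, library = lib, titration = FALSE)
  expect_error(degree_of_dissociation(run_simulation(cfg3)), "titratable")
})

test_that("matched-run persistence decomposition refuses mismatched runs and is zero for identical ones", {
  lib <- small_library()
  base <- function(elec, seed = 19, dp = 60) {
    simulation_config(dp = dp, dd = 1, ph = 4.5, cs = 0.1, n_sweeps = 40000, seed = seed,
                      library = lib, electrostatics = elec, titration = FALSE,
                      collect_frames = TRUE, log_stride = 40)
  }
  rw <- run_simulation(base(TRUE))
  ro <- run_simulation(base(FALSE))
  dec <- decompose_lp(rw, ro)
  expect_gt(dec$lp, 0)
  expect_gt(dec$lp0, 0)
  # identical runs: exactly zero electrostatic contribution
  dec0 <- decompose_lp(rw, rw)
  expect_identical(dec0$lp_e, 0)
  # mismatched configurations are refused
  r_other <- run_simulation(base(FALSE, dp = 40))
  expect_error(decompose_lp(rw, r_other), "not matched")
})

test_that("tidiers and autoplot methods return well-formed objects", {
  ph <- seq(5, 8, 0.25)
  fit <- henderson_hasselbalch_fit(tibble::tibble(ph = ph, alpha = 1 / (1 + 10^(6.6 - ph))))
  expect_named(glance(fit), c("pk_app", "n", "pk_half", "r_squared", "n_points"))
  expect_equal(tidy(fit)$estimate[1], 6.6, tolerance = 1e-8)

  ck <- tibble::tibble(n = 1:50, c_k = exp(-(1:50) * 0.05))
  lfit <- persistence_length_fit(ck, 0.5)
  expect_s3_class(autoplot(lfit), "ggplot")
  expect_s3_class(autoplot(make_onewell_map()), "ggplot")

  cfg <- simulation_config(dp = 10, dd = 1, n_sweeps = 200, seed = 1,
                           library = small_library(), log_stride = 10)
  run <- run_simulation(cfg)
  expect_s3_class(autoplot(run), "ggplot")
  g <- glance(run)
  expect_true(all(c("rg", "pivot_rate", "l") %in% names(g)))
  expect_equal(tidy(run), run$log)
})
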