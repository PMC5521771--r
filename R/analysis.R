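# Chain-statistics and titration-curve estimators: R_G, bond-vector
# correlation, persistence-length fits and their intrinsic/electrostatic
# decomposition, Benoit-Doty and Odijk-Houwaart worm-like-chain estimators,
# characteristic ratio, and modified Henderson-Hasselbalch fits.

#' Radius of gyration of a set of sites
#'
#' @param sites An `n x 3` coordinate matrix (nm), unweighted.
#' @return `sqrt(mean |r_i - r_cm|^2)` in nm.
#' @export
radius_of_gyration <- function(sites) {
  sites <- as.matrix(sites)
  stopifnot(nrow(sites) >= 2)
  d <- sweep(sites, 2, colMeans(sites))
  sqrt(mean(rowSums(d^2)))
}

#' Logged site frames of a run
#'
#' @param run An `mc_run` made with `collect_frames = TRUE`.
#' @param burn_in Burn-in fraction to discard (default from the config).
#' @return A `n_frames x dp x 3` array.
#' @export
run_frames <- function(run, burn_in = NULL) {
  if (is.null(run$frames)) {
    stop("run was not made with collect_frames = TRUE", call. = FALSE)
  }
  keep <- equilibrium_window(run, burn_in)
  run$frames[keep, , , drop = FALSE]
}

as_frame_list <- function(frames) {
  if (is.list(frames)) return(frames)
  if (is.matrix(frames)) return(list(frames))
  stopifnot(length(dim(frames)) == 3)
  lapply(seq_len(dim(frames)[1]), function(i) frames[i, , ])
}

#' Bond-vector correlation function
#'
#' `C_k(n) = <b_i . b_(i+n)> / <|b|^2>` averaged over all origins and frames,
#' for virtual bonds between successive ring centers.
#'
#' @param frames A frame list / matrix / `n_frames x dp x 3` array of site
#'   coordinates, or an `mc_run` with collected frames.
#' @param max_lag Largest lag (default `dp - 2`).
#' @return A tibble with columns `n`, `c_k`.
#' @export
bond_correlation <- function(frames, max_lag = NULL) {
  if (inherits(frames, "mc_run")) frames <- run_frames(frames)
  fl <- as_frame_list(frames)
  nb <- nrow(fl[[1]]) - 1
  if (is.null(max_lag)) max_lag <- nb - 1
  max_lag <- min(max_lag, nb - 1)
  num <- numeric(max_lag)
  cnt <- numeric(max_lag)
  denom <- 0; dcnt <- 0
  for (s in fl) {
    b <- diff(s)
    G <- tcrossprod(b)
    denom <- denom + sum(diag(G)); dcnt <- dcnt + nb
    for (n in seq_len(max_lag)) {
      idx <- seq_len(nb - n)
      num[n] <- num[n] + sum(G[cbind(idx, idx + n)])
      cnt[n] <- cnt[n] + (nb - n)
    }
  }
  tibble::tibble(n = seq_len(max_lag), c_k = (num / cnt) / (denom / dcnt))
}

#' Fit the persistence length from the bond-correlation decay
#'
#' Least-squares fit of `ln C_k = -n l / L_P` over a window of lags. By
#' default the window is the largest contiguous range with
#' `C_k` in `[0.05, 0.75]`, i.e. past the short-range transient (where
#' multiple decay scales mix) but before the noise floor.
#'
#' @param ck Tibble from [bond_correlation()] (columns `n`, `c_k`).
#' @param l Virtual bond length in nm.
#' @param fit_window Optional `c(n_min, n_max)` overriding the default.
#' @param band Correlation band used to pick the default window.
#' @return An `lp_fit`: `lp` (nm), the window, `r_squared`, and the fit data.
#' @export
persistence_length_fit <- function(ck, l, fit_window = NULL, band = c(0.05, 0.75)) {
  stopifnot(all(c("n", "c_k") %in% names(ck)))
  if (is.null(fit_window)) {
    ok <- ck$c_k >= band[1] & ck$c_k <= band[2]
    if (!any(ok)) stop("no C_k values inside the fit band; supply fit_window", call. = FALSE)
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    best <- which.max(ifelse(runs$values, runs$lengths, 0))
    fit_window <- c(ck$n[starts[best]], ck$n[ends[best]])
  }
  sel <- ck$n >= fit_window[1] & ck$n <= fit_window[2] & ck$c_k > 0
  if (sum(sel) < 2) stop("fit window contains fewer than two positive C_k points", call. = FALSE)
  x <- ck$n[sel] * l
  y <- log(ck$c_k[sel])
  fit <- stats::lm(y ~ x)
  slope <- coef(fit)[["x"]]
  if (slope >= 0) stop("C_k does not decay over the fit window", call. = FALSE)
  structure(list(
    lp = -1 / slope,
    intercept = coef(fit)[["(Intercept)"]],
    window = fit_window,
    n_points = sum(sel),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    l = l,
    data = ck[sel, ]
  ), class = "lp_fit")
}

#' @export
print.lp_fit <- function(x, ...) {
  cat(sprintf("Persistence length fit: L_P = %.3f nm (lags %d-%d, R^2 = %.4f)\n",
              x$lp, x$window[1], x$window[2], x$r_squared))
  invisible(x)
}

#' Decompose the persistence length into intrinsic and electrostatic parts
#'
#' `L_P` comes from the run with electrostatics, `L_P,0` from a matched run
#' without them (the intrinsic stiffness at infinite screening); the
#' electrostatic contribution is the difference. The two runs must be
#' identical apart from the electrostatics switch.
#'
#' @param run_with,run_without Matched `mc_run`s with collected frames.
#' @param ... Passed to [persistence_length_fit()].
#' @return A list: `lp`, `lp0`, `lp_e`, and the two fits.
#' @export
decompose_lp <- function(run_with, run_without, ...) {
  a <- run_with$config; b <- run_without$config
  same <- identical(a$sequence$kinds, b$sequence$kinds) &&
    isTRUE(all.equal(a$conditions[c("ph", "cs", "temperature")],
                     b$conditions[c("ph", "cs", "temperature")])) &&
    a$n_sweeps == b$n_sweeps
  if (!same) stop("runs are not matched: only the electrostatics switch may differ",
                  call. = FALSE)
  fit_w <- persistence_length_fit(bond_correlation(run_with), run_with$l, ...)
  fit_o <- persistence_length_fit(bond_correlation(run_without), run_without$l, ...)
  list(lp = fit_w$lp, lp0 = fit_o$lp, lp_e = fit_w$lp - fit_o$lp,
       fit_with = fit_w, fit_without = fit_o)
}

benoit_doty_rhs <- function(lp, L) {
  x <- lp / L
  if (x > 50) {
    # asymptotic series; the closed form cancels catastrophically here
    return(L / 4 - L / (20 * x) + L / (120 * x^2))
  }
  lp * (1 - 3 * x + 6 * x^2 - 6 * x^3 * (-expm1(-1 / x)))
}

#' Benoit-Doty worm-like-chain persistence length from R_G
#'
#' Numerically inverts `3 R_G^2 / L = L_P (1 - 3x + 6x^2 - 6x^3 (1 - e^(-1/x)))`
#' (with `x = L_P / L`) for `L_P`; also reports the long-chain approximation
#' `L_P ~ 3 R_G^2 / L`.
#'
#' @param rg Radius of gyration in nm (root-mean-square).
#' @param L Contour length in nm.
#' @return A list: `lp`, `lp_long_chain`.
#' @export
benoit_doty_lp <- function(rg, L) {
  stopifnot(rg > 0, L > 0)
  target <- 3 * rg^2 / L
  if (rg^2 >= L^2 / 12 * (1 - 1e-12)) {
    stop("R_G at or above the rigid-rod bound (R_G^2 = L^2/12): L_P diverges",
         call. = FALSE)
  }
  root <- stats::uniroot(function(lp) benoit_doty_rhs(lp, L) - target,
                         lower = 1e-9, upper = 1e9 * L, tol = 1e-12)
  list(lp = root$root, lp_long_chain = target)
}

#' Electrostatic expansion factor of the Odijk-Houwaart model
#'
#' `alpha_el^2 = 0.541 + 0.459 (1 + 6.04 z_el)^0.46`; equals 1 at `z_el = 0`.
#'
#' @param z_el Electrostatic excluded-volume parameter (>= 0).
#' @return `alpha_el`.
#' @export
alpha_el_expansion <- function(z_el) {
  stopifnot(all(z_el >= 0))
  sqrt(0.541 + 0.459 * (1 + 6.04 * z_el)^0.46)
}

#' Electrostatic excluded-volume parameter
#'
#' `z_el = sqrt(27 L / (2 pi)) kappa^-1 L_P^(-3/2)`.
#'
#' @param L Contour length (nm).
#' @param kappa Inverse Debye length (1/nm).
#' @param lp Persistence length (nm).
#' @return `z_el` (dimensionless).
#' @export
z_el_parameter <- function(L, kappa, lp) {
  stopifnot(L > 0, kappa > 0, lp > 0)
  sqrt(27 * L / (2 * pi)) * (1 / kappa) * lp^(-3 / 2)
}

#' Perturbation-theory expansion factor
#'
#' `alpha_R^2 = 1 + 1.33 z - 2.075 z^2 + 6.459 z^3`.
#'
#' @param z_el Electrostatic excluded-volume parameter (>= 0).
#' @return `alpha_R`.
#' @export
alpha_r_expansion <- function(z_el) {
  stopifnot(all(z_el >= 0))
  a2 <- 1 + 1.33 * z_el - 2.075 * z_el^2 + 6.459 * z_el^3
  if (any(a2 <= 0)) stop("expansion-factor polynomial is non-positive", call. = FALSE)
  sqrt(a2)
}

#' Iterative Odijk-Houwaart worm-like-chain estimate
#'
#' Experiment-style estimate of the persistence length from a perturbed
#' (in-solution) `R_G`: invert Benoit-Doty for `L_P`, evaluate the
#' electrostatic excluded-volume parameter `z_el` and expansion factor
#' `alpha_el`, deflate `R_G,0 = R_G / alpha_el`, and iterate to convergence.
#' Also reports the OSF-form electrostatic persistence length
#' `L_P,e = lambda_B / (4 kappa^2 A^2)` for mean contour spacing `A` between
#' charges, and `L_P,0 = L_P - L_P,e`.
#'
#' @param rg Measured (perturbed) radius of gyration, nm.
#' @param L Contour length, nm.
#' @param kappa Inverse Debye length, 1/nm (> 0).
#' @param charge_spacing Mean contour distance between charged monomers, nm.
#' @param lambda_b Bjerrum length, nm.
#' @param tol Relative convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A `wlc_estimate`: `lp`, `z_el`, `alpha_el`, `alpha_r`, `rg0`,
#'   `lp_e_osf`, `lp0_osf`, `iterations`.
#' @export
odijk_iteration <- function(rg, L, kappa, charge_spacing,
                            lambda_b = bjerrum_length(), tol = 1e-6,
                            max_iter = 1000) {
  stopifnot(rg > 0, L > 0, kappa > 0, charge_spacing > 0)
  rg0 <- rg
  lp <- NA_real_; z <- 0; a <- 1
  for (it in seq_len(max_iter)) {
    lp <- benoit_doty_lp(rg0, L)$lp
    z <- z_el_parameter(L, kappa, lp)
    a <- alpha_el_expansion(z)
    rg0_new <- rg / a
    if (abs(rg0_new - rg0) <= tol * rg0) {
      rg0 <- rg0_new
      lp_e <- lambda_b / (4 * kappa^2 * charge_spacing^2)
      return(structure(list(
        lp = lp, z_el = z, alpha_el = a, alpha_r = alpha_r_expansion(z),
        rg0 = rg0, lp_e_osf = lp_e, lp0_osf = lp - lp_e,
        iterations = it
      ), class = "wlc_estimate"))
    }
    rg0 <- rg0_new
  }
  stop("Odijk iteration did not converge after ", max_iter,
       " iterations (last L_P = ", signif(lp, 6), ")", call. = FALSE)
}

#' @export
print.wlc_estimate <- function(x, ...) {
  cat(sprintf("WLC estimate: L_P = %.3f nm (z_el = %.4f, alpha_el = %.4f, %d iterations)\n",
              x$lp, x$z_el, x$alpha_el, x$iterations))
  cat(sprintf("  OSF decomposition: L_P,e = %.3f nm, L_P,0 = %.3f nm\n",
              x$lp_e_osf, x$lp0_osf))
  invisible(x)
}

#' Characteristic ratio curve
#'
#' `C_n = <R_ee^2(n)> / (n l^2)` over internal sub-chains of `n` bonds,
#' averaged over all windows and frames.
#'
#' @param frames Frames as for [bond_correlation()], or an `mc_run`.
#' @param l Virtual bond length (nm); taken from the run if one is given.
#' @param n_values Sub-chain lengths to evaluate (default all).
#' @return A tibble with columns `n`, `c_n`.
#' @export
characteristic_ratio <- function(frames, l = NULL, n_values = NULL) {
  if (inherits(frames, "mc_run")) {
    if (is.null(l)) l <- frames$l
    frames <- run_frames(frames)
  }
  stopifnot(!is.null(l))
  fl <- as_frame_list(frames)
  nb <- nrow(fl[[1]]) - 1
  if (is.null(n_values)) n_values <- seq_len(nb)
  n_values <- n_values[n_values >= 1 & n_values <= nb]
  acc <- numeric(length(n_values)); cnt <- numeric(length(n_values))
  for (s in fl) {
    for (j in seq_along(n_values)) {
      n <- n_values[j]
      d <- s[(1 + n):(nb + 1), , drop = FALSE] - s[1:(nb + 1 - n), , drop = FALSE]
      acc[j] <- acc[j] + sum(rowSums(d^2))
      cnt[j] <- cnt[j] + (nb + 1 - n)
    }
  }
  tibble::tibble(n = n_values, c_n = (acc / cnt) / (n_values * l^2))
}

#' Modified Henderson-Hasselbalch fit of a titration curve
#'
#' Linear fit of `pH = pK_app + n * log10(alpha / (1 - alpha))` over the
#' window `|log10(alpha / (1 - alpha))| < 0.5`, i.e. the transition region.
#' `alpha` is the fraction of neutral titratable sites (0 = fully charged).
#' `pK_app` is also reported as the interpolated pH at `alpha = 0.5`.
#'
#' @param curve Data frame with columns `ph` and `alpha`.
#' @param window Half-width of the logit window (default 0.5).
#' @return An `hh_fit`: `pk_app`, `n`, `pk_half`, fit metadata.
#' @export
henderson_hasselbalch_fit <- function(curve, window = 0.5) {
  stopifnot(all(c("ph", "alpha") %in% names(curve)))
  ok <- curve$alpha > 0 & curve$alpha < 1
  x <- log10(curve$alpha[ok] / (1 - curve$alpha[ok]))
  ph <- curve$ph[ok]
  sel <- abs(x) < window
  if (sum(sel) < 3) {
    stop("fewer than 3 points inside the logit window |log10(a/(1-a))| < ",
         window, call. = FALSE)
  }
  fit <- stats::lm(ph ~ x, data = data.frame(ph = ph[sel], x = x[sel]))
  # interpolated pH at alpha = 0.5 (x = 0), from the curve itself
  ord <- order(curve$ph)
  a <- curve$alpha[ord]; p <- curve$ph[ord]
  pk_half <- if (any(a <= 0.5) && any(a >= 0.5)) {
    stats::approx(a, p, xout = 0.5, ties = mean)$y
  } else NA_real_
  structure(list(
    pk_app = coef(fit)[["(Intercept)"]],
    n = coef(fit)[["x"]],
    pk_half = pk_half,
    n_points = sum(sel),
    window = window,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    data = tibble::tibble(ph = ph[sel], logit = x[sel])
  ), class = "hh_fit")
}

#' @export
print.hh_fit <- function(x, ...) {
  cat(sprintf("Henderson-Hasselbalch fit: pK_app = %.3f, n = %.3f (%d points, R^2 = %.4f)\n",
              x$pk_app, x$n, x$n_points, x$r_squared))
  invisible(x)
}

#' Degree-of-dissociation series of a run
#'
#' Per-frame fraction of neutral titratable sites (`alpha = 0` fully charged,
#' `alpha = 1` fully neutral) and its post-burn-in mean with a block standard
#' error.
#'
#' @param run An `mc_run`.
#' @param burn_in Burn-in fraction (default from the config).
#' @param n_blocks Blocks for the standard error.
#' @return A list: `series` (tibble `step`, `alpha`), `mean`, `se`.
#' @export
degree_of_dissociation <- function(run, burn_in = NULL, n_blocks = 10) {
  if (run$config$sequence$n_t == 0) {
    stop("no titratable sites in this run", call. = FALSE)
  }
  keep <- equilibrium_window(run, burn_in)
  x <- run$log$alpha[keep]
  b <- max(1, floor(length(x) / n_blocks))
  bm <- vapply(seq_len(min(n_blocks, length(x))), function(k) {
    mean(x[((k - 1) * b + 1):min(k * b, length(x))])
  }, 0)
  list(series = tibble::tibble(step = run$log$step, alpha = run$log$alpha),
       mean = mean(x), se = stats::sd(bm) / sqrt(length(bm)))
}

#' Equilibrium mean of a logged observable
#'
#' @param run An `mc_run`.
#' @param observable Log column (default `"rg"`).
#' @param burn_in Burn-in fraction.
#' @param n_blocks Blocks for the standard error.
#' @return A list: `mean`, `se`, `n`.
#' @export
observable_mean <- function(run, observable = "rg", burn_in = NULL, n_blocks = 10) {
  x <- run$log[[observable]][equilibrium_window(run, burn_in)]
  b <- max(1, floor(length(x) / n_blocks))
  bm <- vapply(seq_len(min(n_blocks, length(x))), function(k) {
    mean(x[((k - 1) * b + 1):min(k * b, length(x))])
  }, 0)
  list(mean = mean(x), se = stats::sd(bm) / sqrt(length(bm)), n = length(x))
}

#' Simulated titration curve over a pH ladder
#'
#' Runs one simulation per pH value and collects the equilibrium degree of
#' dissociation.
#'
#' @param ph_values pH ladder.
#' @param ... Passed to [simulation_config()] (everything but `ph`).
#' @return A tibble with columns `ph`, `alpha`, `se`, `cs`.
#' @export
titration_scan <- function(ph_values, ...) {
  rows <- lapply(ph_values, function(p) {
    run <- run_simulation(simulation_config(ph = p, ...))
    a <- degree_of_dissociation(run)
    tibble::tibble(ph = p, alpha = a$mean, se = a$se, cs = run$config$conditions$cs)
  })
  dplyr::bind_rows(rows)
}
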