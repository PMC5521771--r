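# broom-style tidy()/glance() methods for the fitted objects.

#' @export
tidy.hh_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pk_app", "n"),
    estimate = c(x$pk_app, x$n)
  )
}

#' @export
glance.hh_fit <- function(x, ...) {
  tibble::tibble(
    pk_app = x$pk_app, n = x$n, pk_half = x$pk_half,
    r_squared = x$r_squared, n_points = x$n_points
  )
}

#' @export
tidy.lp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lp", "intercept"),
    estimate = c(x$lp, x$intercept)
  )
}

#' @export
glance.lp_fit <- function(x, ...) {
  tibble::tibble(
    lp = x$lp, window_min = x$window[1], window_max = x$window[2],
    n_points = x$n_points, r_squared = x$r_squared
  )
}

#' @export
tidy.wlc_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("lp", "z_el", "alpha_el", "alpha_r", "rg0", "lp_e_osf", "lp0_osf"),
    estimate = c(x$lp, x$z_el, x$alpha_el, x$alpha_r, x$rg0, x$lp_e_osf, x$lp0_osf)
  )
}

#' @export
glance.wlc_estimate <- function(x, ...) {
  tibble::tibble(
    lp = x$lp, z_el = x$z_el, alpha_el = x$alpha_el, rg0 = x$rg0,
    lp_e_osf = x$lp_e_osf, lp0_osf = x$lp0_osf, iterations = x$iterations
  )
}

#' @export
glance.mc_run <- function(x, ...) {
  rgm <- observable_mean(x, "rg")
  reem <- observable_mean(x, "ree")
  ar <- acceptance_report(x)
  tibble::tibble(
    dp = x$config$sequence$dp,
    dd = x$config$sequence$dd,
    ph = x$config$conditions$ph,
    cs = x$config$conditions$cs,
    n_sweeps = x$config$n_sweeps,
    seed = x$config$seed,
    l = x$l,
    contour_length = x$contour_length,
    rg = rgm$mean, rg_se = rgm$se,
    ree = reem$mean, ree_se = reem$se,
    alpha = mean(x$log$alpha[equilibrium_window(x)]),
    pivot_rate = ar$rate[ar$move == "pivot"],
    titration_rate = ar$rate[ar$move == "titration"]
  )
}

#' @export
tidy.mc_run <- function(x, ...) x$log
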