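# ggplot2 autoplot() methods for maps, runs and fitted objects.

#' Plot a free-energy map
#'
#' Filled raster of the (phi, psi) free energy, capped at `max_energy` so the
#' basin structure is visible.
#'
#' @param object A `dihedral_map`.
#' @param max_energy Display cap in k_BT.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dihedral_map <- function(object, max_energy = 12, ...) {
  df <- expand.grid(
    phi = (seq_len(object$n_phi) - 1) * 2 * pi / object$n_phi,
    psi = (seq_len(object$n_psi) - 1) * 2 * pi / object$n_psi
  )
  df$G <- pmin(as.vector(object$grid), max_energy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$psi, fill = .data$G)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(G ~ (k[B] * T)), direction = -1) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(
      title = ifelse(is.na(object$link_key), "Glycosidic free-energy map",
                     paste("Glycosidic map:", object$link_key)),
      x = expression(phi ~ (rad)), y = expression(psi ~ (rad))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the observable traces of a run
#'
#' @param object An `mc_run`.
#' @param observables Log columns to show.
#' @param ... Unused.
#' @return A ggplot (facetted traces vs MC sweep).
#' @export
autoplot.mc_run <- function(object, observables = c("rg", "ree", "alpha"), ...) {
  log <- object$log
  df <- dplyr::bind_rows(lapply(observables, function(ob) {
    tibble::tibble(step = log$step, value = log[[ob]], observable = ob)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~observable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "MC sweep", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a bond-correlation decay with its persistence-length fit
#'
#' @param object An `lp_fit`.
#' @param ... Unused.
#' @return A ggplot of `ln C_k` vs contour distance with the fitted line.
#' @export
autoplot.lp_fit <- function(object, ...) {
  df <- object$data
  df$x <- df$n * object$l
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = log(.data$c_k))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(intercept = object$intercept, slope = -1 / object$lp,
                         color = "red") +
    ggplot2::labs(
      x = "n l (nm)", y = expression(ln ~ C[k]),
      title = sprintf("L_P = %.2f nm", object$lp)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a titration curve with its Henderson-Hasselbalch fit
#'
#' @param object An `hh_fit`.
#' @param curve Optional original `ph`/`alpha` curve to overlay.
#' @param ... Unused.
#' @return A ggplot of pH vs the dissociation logit.
#' @export
autoplot.hh_fit <- function(object, curve = NULL, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$logit, y = .data$ph)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$pk_app, slope = object$n, color = "red") +
    ggplot2::labs(
      x = expression(log[10] * (alpha / (1 - alpha))), y = "pH",
      title = sprintf("pK_app = %.2f, n = %.2f", object$pk_app, object$n)
    ) +
    ggplot2::theme_minimal()
  p
}

#' Titration-curve plot
#'
#' @param curve Tibble from [titration_scan()].
#' @return A ggplot of alpha vs pH per ionic strength.
#' @export
plot_titration_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$ph, y = .data$alpha,
                                      color = factor(.data$cs))) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pH", y = expression(alpha ~ "(fraction neutral)"),
                  color = expression(c[s] ~ (M))) +
    ggplot2::theme_minimal()
}
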