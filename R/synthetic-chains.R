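# Ideal-chain ensemble generators with known statistics, used to validate the
# chain estimators: a freely jointed chain (bond correlation identically 0)
# and a freely rotating chain with fixed bond angle, whose bond correlation is
# exactly cos(theta)^n, i.e. a discrete worm-like chain with
# L_P = -l / ln(cos(theta)).

#' Generate ideal-chain site frames
#'
#' Bond directions follow a Markov chain: each bond makes a fixed angle
#' `acos(correlation)` with its predecessor, with uniform azimuth (freely
#' rotating chain). `correlation = 0` gives the freely jointed chain;
#' `correlation = 1` a rigid rod.
#'
#' @param dp Number of sites per chain.
#' @param n_frames Number of independent chains.
#' @param l Bond length (nm).
#' @param correlation `cos(theta)` of successive bonds, in `[0, 1]`.
#' @param seed RNG seed (global RNG state is left untouched).
#' @return A `n_frames x dp x 3` array of site coordinates.
#' @export
generate_ideal_chain_frames <- function(dp, n_frames, l = 0.5, correlation = 0,
                                        seed = 1L) {
  stopifnot(dp >= 2, n_frames >= 1, l > 0, correlation >= 0, correlation <= 1)
  with_seed(seed, {
    out <- array(0, c(n_frames, dp, 3))
    ct <- correlation
    st <- sqrt(1 - ct^2)
    for (f in seq_len(n_frames)) {
      b <- matrix(0, dp - 1, 3)
      u <- c(0, 0, 1)
      for (k in seq_len(dp - 1)) {
        if (k == 1 || correlation == 0) {
          # uniform direction on the sphere (also used for the first bond)
          z <- 2 * stats::runif(1) - 1
          a <- 2 * pi * stats::runif(1)
          u <- c(sqrt(1 - z^2) * cos(a), sqrt(1 - z^2) * sin(a), z)
        } else {
          # new direction at fixed angle to u, uniform azimuth
          ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
          e1 <- unit3(cross3(u, ref))
          e2 <- cross3(u, e1)
          a <- 2 * pi * stats::runif(1)
          u <- ct * u + st * (cos(a) * e1 + sin(a) * e2)
          u <- unit3(u)
        }
        b[k, ] <- l * u
      }
      out[f, , ] <- rbind(c(0, 0, 0), apply(b, 2, cumsum))
    }
    out
  })
}

#' Persistence length of the freely rotating chain
#'
#' Closed form `L_P = -l / ln(correlation)` for the generator's bond
#' correlation `cos(theta)^n`.
#'
#' @param l Bond length (nm).
#' @param correlation `cos(theta)` in `(0, 1)`.
#' @return `L_P` in nm.
#' @export
frc_persistence_length <- function(l, correlation) {
  stopifnot(correlation > 0, correlation < 1)
  -l / log(correlation)
}
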