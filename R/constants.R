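# Physical constants (CODATA 2018) and unit helpers. Internal energy unit is
# k_BT throughout; lengths are nm, angles radians on [0, 2pi).

.const <- list(
  e_charge  = 1.602176634e-19,   # C
  eps0      = 8.8541878128e-12,  # F/m
  k_B       = 1.380649e-23,      # J/K
  N_A       = 6.02214076e23,     # 1/mol
  R_gas     = 8.31446261815324   # J/(mol K)
)

#' Thermal energy in kJ/mol
#'
#' @param temperature Temperature in K.
#' @return k_B T expressed in kJ/mol (2.479 at 298 K).
#' @export
kbt_kjmol <- function(temperature = 298) {
  .const$R_gas * temperature / 1000
}

#' Wrap angles onto the canonical domain
#'
#' @param x Angle(s) in radians.
#' @return Values wrapped to `[0, 2*pi)`.
#' @export
wrap_angle <- function(x) {
  x - 2 * pi * floor(x / (2 * pi))
}

## Monomer state labels --------------------------------------------------------
## 0 = GlcNAc (acetylated, never charged), 1 = GlcNH2 (deacetylated, neutral),
## 2 = GlcNH3+ (deacetylated, protonated). Link keys are ordered pairs
## (reducing-end state, non-reducing-end state).

#' Monomer state labels
#' @export
monomer_states <- function() c("GlcNAc", "GlcNH2", "GlcNH3+")

state_code <- function(label) {
  m <- match(label, monomer_states())
  if (anyNA(m)) {
    stop("unknown monomer state label(s): ",
         paste(unique(label[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  m - 1L
}

#' All nine ordered link keys
#'
#' @return Character vector like `"GlcNH2-GlcNH2"`, reducing end first.
#' @export
link_keys <- function() {
  s <- monomer_states()
  as.vector(t(outer(s, s, paste, sep = "-")))
}

link_key <- function(left, right) paste(left, right, sep = "-")
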