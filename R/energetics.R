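# Energy terms, all in k_BT: repulsive (WCA) Lennard-Jones sterics between
# ring-center sites, Debye-Hueckel screened electrostatics between charged
# sites, the protonation chemical potential, and the titration free energy.

#' Bjerrum length
#'
#' Distance at which two unit charges interact with k_BT:
#' `e^2 / (4 pi eps0 eps_r k_B T)`. 0.714 nm in water at 298 K.
#'
#' @param temperature Temperature in K.
#' @param relative_permittivity Relative permittivity of the solvent.
#' @return Length in nm.
#' @export
bjerrum_length <- function(temperature = 298, relative_permittivity = 78.5) {
  stopifnot(temperature > 0, relative_permittivity > 0)
  lb_m <- .const$e_charge^2 /
    (4 * pi * .const$eps0 * relative_permittivity * .const$k_B * temperature)
  lb_m * 1e9
}

#' Solution conditions
#'
#' Bundles pH, salt concentration and temperature and derives the Bjerrum
#' length, the effective ionic strength and the inverse Debye length. The
#' effective ionic strength includes the strong-acid proton contribution,
#' `c_eff = c_s + 10^(-pH)` mol/L, which matters below pH ~ 3; it can be
#' switched off.
#'
#' @param ph Solution pH.
#' @param cs Added salt concentration in mol/L (>= 0).
#' @param temperature Temperature in K.
#' @param relative_permittivity Solvent relative permittivity.
#' @param include_ph_in_ionic_strength Add `10^(-pH)` mol/L to the ionic
#'   strength (default TRUE).
#' @return A `solution_conditions` with fields `lambda_b` (nm), `c_eff`
#'   (mol/L) and `kappa` (1/nm).
#' @export
solution_conditions <- function(ph = 4.5, cs = 0.1, temperature = 298,
                                relative_permittivity = 78.5,
                                include_ph_in_ionic_strength = TRUE) {
  stopifnot(cs >= 0, temperature > 0)
  lambda_b <- bjerrum_length(temperature, relative_permittivity)
  c_eff <- cs + if (include_ph_in_ionic_strength) 10^(-ph) else 0
  structure(list(
    ph = ph, cs = cs, temperature = temperature,
    relative_permittivity = relative_permittivity,
    include_ph_in_ionic_strength = include_ph_in_ionic_strength,
    lambda_b = lambda_b,
    c_eff = c_eff,
    kappa = kappa_from_ionic_strength(c_eff, lambda_b)
  ), class = "solution_conditions")
}

#' @export
print.solution_conditions <- function(x, ...) {
  cat(sprintf("Solution: pH %.2f, cs %.4g M, T %.0f K | lambda_B %.4f nm, kappa^-1 %s nm\n",
              x$ph, x$cs, x$temperature, x$lambda_b,
              if (x$kappa > 0) sprintf("%.3f", 1 / x$kappa) else "Inf"))
  invisible(x)
}

#' Inverse Debye length from the ionic strength
#'
#' `kappa = sqrt(8 pi lambda_B N_A c)` with `c` in mol/L converted to nm^-3.
#'
#' @param c_molar Ionic strength in mol/L.
#' @param lambda_b Bjerrum length in nm.
#' @return kappa in 1/nm (0 for `c_molar = 0`, i.e. no screening).
#' @export
kappa_from_ionic_strength <- function(c_molar, lambda_b = bjerrum_length()) {
  stopifnot(c_molar >= 0)
  c_nm3 <- c_molar * .const$N_A * 1e-24
  sqrt(8 * pi * lambda_b * c_nm3)
}

#' Debye screening length
#'
#' @param conditions A [solution_conditions()].
#' @return kappa^-1 in nm; `Inf` (with a message) for zero effective ionic
#'   strength.
#' @export
debye_length <- function(conditions) {
  if (conditions$kappa == 0) {
    message("zero effective ionic strength: screening length is infinite")
    return(Inf)
  }
  1 / conditions$kappa
}

#' Force-field parameters
#'
#' @param sigma_lj LJ diameter in nm (the monomer steric size).
#' @param eps_lj_kjmol LJ energy parameter in kJ/mol (default 0.6276; results
#'   are insensitive because the potential is purely repulsive).
#' @param pk_i Intrinsic dissociation constant of the glucosamine amino group.
#' @param cutoff Map restriction energy in k_BT.
#' @param temperature Temperature used to convert eps to k_BT.
#' @param include_bonded_in_titration Add the adjacent-link map-energy change
#'   to the titration acceptance (off by default; sensitivity switch).
#' @param double_count_titration_pairs Count each charged pair twice in the
#'   titration free energy, the literal reading of a double sum over i and
#'   j != i (off by default; unordered pairs counted once).
#' @return A `forcefield_params` with derived `r_c = 2^(1/6) sigma` and
#'   `eps_kbt`.
#' @export
forcefield_params <- function(sigma_lj = 0.65, eps_lj_kjmol = 0.6276,
                              pk_i = 6.6, cutoff = 7, temperature = 298,
                              include_bonded_in_titration = FALSE,
                              double_count_titration_pairs = FALSE) {
  stopifnot(sigma_lj > 0, eps_lj_kjmol > 0, cutoff > 0)
  structure(list(
    sigma_lj = sigma_lj,
    eps_lj_kjmol = eps_lj_kjmol,
    eps_kbt = eps_lj_kjmol / kbt_kjmol(temperature),
    r_c = 2^(1 / 6) * sigma_lj,
    pk_i = pk_i,
    cutoff = cutoff,
    include_bonded_in_titration = include_bonded_in_titration,
    double_count_titration_pairs = double_count_titration_pairs
  ), class = "forcefield_params")
}

#' LJ diameter from a molecular surface area
#'
#' Solves `4 pi (sigma/2)^2 = area` — the rule that the steric sphere's
#' surface area equals the monomer's molecular surface area.
#'
#' @param area_nm2 Molecular surface area in nm^2.
#' @return sigma in nm.
#' @export
sigma_from_msa <- function(area_nm2) {
  stopifnot(area_nm2 > 0)
  sqrt(area_nm2 / pi)
}

#' Repulsive (WCA) Lennard-Jones energy
#'
#' `4 eps [ (sigma/r)^12 - (sigma/r)^6 + 1/4 ]` for `r <= r_c = 2^(1/6) sigma`,
#' 0 beyond; continuous at the cutoff.
#'
#' @param r Distance(s) in nm (> 0).
#' @param params A [forcefield_params()].
#' @return Energy in k_BT (vectorized over `r`).
#' @export
wca_energy <- function(r, params = forcefield_params()) {
  if (any(r <= 0)) stop("distances must be positive", call. = FALSE)
  s6 <- (params$sigma_lj / r)^6
  ifelse(r <= params$r_c, 4 * params$eps_kbt * (s6^2 - s6 + 0.25), 0)
}

#' Debye-Hueckel pair energy
#'
#' `z_a z_b lambda_B exp(-kappa r) / r` in k_BT.
#'
#' @param z_a,z_b Valences (0 or 1).
#' @param r Distance(s) in nm (> 0).
#' @param conditions A [solution_conditions()].
#' @return Energy in k_BT (vectorized over `r`).
#' @export
dh_pair_energy <- function(z_a, z_b, r, conditions) {
  if (any(r <= 0)) stop("distances must be positive", call. = FALSE)
  stopifnot(all(c(z_a, z_b) %in% c(0, 1)))
  z_a * z_b * conditions$lambda_b * exp(-conditions$kappa * r) / r
}

#' Chemical potential of protonation
#'
#' `ln(10) (pH - pK_i)` in k_BT: the cost of protonating one isolated site.
#'
#' @param ph Solution pH.
#' @param pk_i Intrinsic dissociation constant.
#' @return Energy in k_BT.
#' @export
protonation_mu <- function(ph, pk_i = 6.6) {
  log(10) * (ph - pk_i)
}

#' Conformational non-bonded energy
#'
#' Steric (WCA) energy over all site pairs `|i - j| >= 2` and screened
#' electrostatics over charged site pairs `|i - j| >= 2`; adjacent-pair
#' physics lives in the dihedral maps.
#'
#' @param conformation A `conformation` (or a sites matrix).
#' @param charges Integer 0/1 per monomer.
#' @param conditions A [solution_conditions()].
#' @param params A [forcefield_params()].
#' @return `list(e_lj, e_dh)` in k_BT.
#' @export
nonbonded_energy <- function(conformation, charges, conditions, params) {
  sites <- if (inherits(conformation, "conformation")) conformation$sites else conformation
  n <- nrow(sites)
  e_lj <- 0; e_dh <- 0
  if (n >= 3) {
    d <- as.matrix(stats::dist(sites))
    iu <- which(upper.tri(d) & abs(row(d) - col(d)) >= 2)
    r <- d[iu]
    e_lj <- sum(wca_energy(r, params))
    zz <- (charges %o% charges)[iu]
    ch <- zz > 0
    if (any(ch)) {
      e_dh <- sum(conditions$lambda_b * exp(-conditions$kappa * r[ch]) / r[ch])
    }
  }
  list(e_lj = e_lj, e_dh = e_dh)
}

#' Titration free energy
#'
#' `F_prot = sum_i mu z_i + sum_(pairs) U_DH(r_ij)` over titratable sites,
#' where the electrostatic sum runs over unordered charged pairs including
#' nearest neighbours (counted twice if the literal double-sum flag is set).
#'
#' @param conformation A `conformation` (or sites matrix).
#' @param charges Integer 0/1 per monomer.
#' @param conditions A [solution_conditions()].
#' @param params A [forcefield_params()].
#' @return `list(f_mu, f_pair, f_prot)` in k_BT.
#' @export
titration_energy <- function(conformation, charges, conditions, params) {
  sites <- if (inherits(conformation, "conformation")) conformation$sites else conformation
  mu <- protonation_mu(conditions$ph, params$pk_i)
  f_mu <- mu * sum(charges)
  ch <- which(charges == 1L)
  f_pair <- 0
  if (length(ch) >= 2) {
    d <- stats::dist(sites[ch, , drop = FALSE])
    f_pair <- sum(conditions$lambda_b * exp(-conditions$kappa * d) / d)
    if (params$double_count_titration_pairs) f_pair <- 2 * f_pair
  }
  list(f_mu = f_mu, f_pair = f_pair, f_prot = f_mu + f_pair)
}
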