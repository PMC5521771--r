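---
title: "A coarse-grained constant-pH Monte Carlo model of chitosan: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained constant-pH Monte Carlo model of chitosan: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chitomc)
```

# The model

`chitomc` represents a chitosan chain as a sequence of rigid pyranose
monomers. Each monomer keeps seven atoms — the six ring atoms and the
glycosidic oxygen — in an idealized ⁴C₁ chair with all bond lengths, valence
angles and impropers fixed, so that the only flexible degrees of freedom of
the whole chain are the two glycosidic dihedrals per link,

* φ = O5(i)–C1(i)–O1(i)–C4(i+1),
* ψ = C1(i)–O1(i)–C4(i+1)–C5(i+1),

in the IUPAC convention, on the domain [0, 2π). Sterics and electrostatics
act on one interaction site per monomer, the centroid of the ring atoms. The
distance between successive centroids defines the virtual bond length *l*;
it is **measured** from the geometry (≈ 0.47 nm at typical link angles), not
set, and every analysis uses the measured value.

The geometry constants live in one place, `cg_geometry()`. The ring is a
hexagonal chair (uniform ring bond 0.150 nm, pucker half-height 0.025 nm)
with equatorial substituents at C1 and C4 (the β, 1,4-diequatorial
attachment). Of the two mirror-image constructions the one for which the
published main-minimum angles (φ ≈ 5.0, ψ ≈ 2.2 rad) produce the extended
two-fold-like helix characteristic of β-(1→4) sugars is used; the mirrored
chirality would fold the same dihedrals into a tight coil.

## Energy terms

All energies are in k_BT, lengths in nm.

* **Bonded**: per-link free-energy maps G(φ, ψ) interpolated bilinearly on a
  periodic 200×200 grid, normalized so min G = 0. Nine maps cover the
  ordered (reducing end, non-reducing end) combinations of GlcNAc, GlcNH2
  and GlcNH3+.
* **Steric**: the purely repulsive (WCA) Lennard-Jones form,
  4ε[(σ/r)¹² − (σ/r)⁶ + ¼] cut at r_c = 2^{1/6}σ. Defaults
  ε = 0.6276 kJ/mol (a carbon-like value; results are insensitive because
  the term is purely repulsive) and σ = 0.65 nm. σ is defined through the
  rule that the sphere's surface area equals the monomer's molecular surface
  area; since that area is not tabulated here, the default is a fixed,
  configurable value and `sigma_from_msa()` exposes the rule.
* **Electrostatic**: Debye–Hückel, z_α z_β λ_B e^{−κr}/r, between
  *non-adjacent* charged monomers; adjacent-monomer physics is carried by
  the maps. λ_B = e²/(4πε₀ε_r k_BT) = 0.714 nm in water at 298 K, and
  κ = (8π λ_B N_A c_eff)^{1/2}.
* **Titration**: F_prot = Σᵢ μ zᵢ + Σ_{pairs} U^{DH}, the pair sum over all
  charged pairs *including* nearest neighbours, each unordered pair counted
  once. μ = ln(10)(pH − pK_i) with pK_i = 6.6, the value that best matches
  experimental titration of highly deacetylated chitosan.

Two deliberate readings of ambiguous formulations are implemented exactly
and exposed as switches:

* the titration double sum is read as unordered pairs counted once
  (`double_count_titration_pairs = FALSE` by default), since pairwise
  energies are conventionally single-counted;
* the change in bonded (map) energy of the adjacent links is **not** part
  of the titration acceptance by default
  (`include_bonded_in_titration = FALSE`), matching the simulation protocol
  the model reproduces; turning it on makes the joint
  (conformation, charge) ensemble exactly consistent and is what the
  enumeration tests use.

The effective ionic strength is c_eff = c_s + 10^{−pH} mol/L: the strong
acid needed to set a low pH contributes ions. This matters only below
pH ≈ 3 and can be disabled (`include_ph_in_ionic_strength = FALSE`).

## Monte Carlo scheme

One sweep is a single pivot move followed by `titration_moves_per_sweep`
(default N_t, the number of titratable sites) protonation attempts.

A pivot move picks a link uniformly, draws (φ′, ψ′) uniformly over the
region of that link's map below the cutoff (default 7 k_BT; a bin is drawn
uniformly from the allowed set and jittered uniformly within the bin), and
rotates the downstream chain rigidly. Because the proposal is uniform over a
fixed region that always contains the current point's bin neighbourhood of
the minimum, the proposal is symmetric and Metropolis acceptance
min(1, e^{−ΔE}) with ΔE = ΔE_map + ΔE_LJ + ΔE_DH targets the Boltzmann
distribution truncated at the cutoff. The regions above 7 k_BT carry less
than 10⁻³ of the Boltzmann mass, so the truncation is a sampling-efficiency
device, not a physical approximation.

A titration move flips one titratable site with
ΔF = Δ(μz) + Δ(pairwise DH including nearest neighbours); on acceptance the
maps of the (up to) two adjacent links are reassigned to the new monomer
states ("map swapping"). κ is not updated on charge changes — monomer
charges are not part of the ionic strength.

The initial conformation puts every link at its map's global minimum, and
all titratable sites start charged when pH < pK_i, neutral otherwise — a
physical state from which equilibration is fast. Equilibration is handled by
discarding a burn-in fraction (default 20%) and `check_stationarity()`
compares first/last thirds of the retained R_G samples within two combined
block standard errors.

The RNG stream order is fixed and documented: per sweep, pivot link, allowed
bin, φ jitter, ψ jitter, pivot acceptance; then per titration attempt, site
and acceptance. Acceptance uniforms are always drawn, so a run is
reproducible byte-for-byte from its seed.

## Numerical choices

* **Incremental updates.** A pivot updates only the downstream poses and the
  O(k·(DP−k)) pair energies that span the pivoted link. Two safeguards keep
  this exact in practice: the incremental rigid transform is projected back
  onto an exact rotation before application (otherwise its scale error
  compounds *multiplicatively* over accepted moves), and every 2000 sweeps
  the engine rebuilds coordinates and energy caches from scratch. Tests
  assert agreement with a full recompute at 10⁻⁶ k_BT after thousands of
  moves.
* **Map minima.** Strict 8-neighbour local minima are filtered by
  topographic persistence (union-find sweep; default threshold 0.2 k_BT) so
  that grid noise does not produce spurious second minima; positions are
  refined below the bin width by a local quadratic fit, since published
  minima are quoted to 3–4 decimals while the grid bin is 0.0314 rad. ΔG₂ is
  the energy of the second-lowest *persistent* minimum.
* **Accessible areas** use ≤ at 12 k_BT and strict < at 1 k_BT, matching the
  "<1kT" convention of the feature table.
* **Map files.** Two text dialects are auto-detected (φ ψ G triples, or a
  dense matrix with an axis-range header); energies in kJ/mol (declared in a
  header comment) are divided by k_BT at 298 K = 2.479 kJ/mol; [−π, π)
  domains are shifted. Grids are resampled to 200×200 by periodic bilinear
  interpolation. Whether the source grids are bin- or node-centered is not
  specified by their producers; this package treats them as node-centered.
* **Benoit–Doty inversion** brackets the root with `uniroot`; for
  L_P/L > 50 the closed form cancels catastrophically and an asymptotic
  series (L/4 − L/(20x) + …) replaces it. R_G at or above the rigid-rod
  bound L²/12 is a domain error.
* **Fit windows.** The persistence-length fit uses the largest contiguous
  lag range with C_k ∈ [0.05, 0.75] — past the short-range multi-scale
  transient, before the noise floor — overridable via `fit_window`. The
  Henderson–Hasselbalch fit uses |log₁₀(α/(1−α))| < 0.5 and needs ≥ 3
  points. C_n averages over all internal sub-chain windows, not only the
  chain ends, to reduce variance; the mean-*square* end-to-end distance is
  used throughout (the dimensionally consistent reading).
* **z_el and L_P,e.** The electrostatic excluded-volume parameter is
  z_el = (27L/2π)^{1/2} κ⁻¹ L_P^{−3/2}, the dimensionally consistent form,
  and the closed-form electrostatic persistence length is the OSF form
  λ_B/(4κ²A²) with A the mean contour spacing between charges — a pure
  κ⁻² λ_B expression is a volume, not a length. Both the OSF value and the
  simulation-derived L_P − L_P,0 are reported, because the two are known to
  disagree at intermediate screening.
* **α convention.** The degree of dissociation α is the fraction of
  *neutral* titratable sites: α = 0 is the fully charged polymer, α = 1 the
  neutral one.

# The synthetic map library

The bonded maps are, physically, potentials of mean force from all-atom
sampling; producing them is outside this package's scope, and the package
reads such maps from files. For building, testing and demonstration it
synthesizes a stand-in library: each link type gets a two-well surface
G = −ln Σ_w exp(−(B − D_w) − d_w²/2) with periodic Gaussian basins, whose
parameters are solved analytically from the published per-link features —
main-minimum position, ΔG₂ (as the well-depth gap), the sub-1 k_BT area
(main-well width: σ₁ = √(2π a₁)) and the 12 k_BT accessible area
(second-well width: σ₂² = 2π(a₁₂ − 12a₁)/(12 − ΔG₂)). The secondary well
sits at a fixed offset (−1.2, +π) from the main one — a distinct,
orientation-changing conformation — because the published features do not
locate it. One internal inconsistency in the published features (ΔG₂ printed
as 1.3 in the table but 1.35 in the accompanying text for GlcNH3+–GlcNAc) is
resolved in favour of the more precise text value.

What the generator emulates: the feature statistics of the real maps, their
ordering in flexibility (lower ΔG₂ → floppier link), and the complete
nine-key swap topology. What it does **not** emulate: the actual 2-D basin
shapes, the location of the secondary minimum, and any tertiary structure of
the real surfaces. Consequently:

* tests of map loading, feature extraction, restricted sampling, ensemble
  correctness, estimator correctness and the direction of structural trends
  (R_G growing with DP; map swapping making chains more compact than static
  all-protonated maps; monotone κ⁻¹ dependence) are meaningful on synthetic
  maps — these properties do not depend on basin shape;
* *absolute* chain-scale numbers — homopolymer intrinsic persistence
  lengths, the pivot acceptance percentage, the characteristic-ratio plateau
  value — are properties of the real map topology, and values computed from
  the stand-ins are reported as what they are. The acceptance script prints
  them; the corresponding assertions in the test suite document the
  published values and are expected to fail with the synthetic library. To
  reproduce them, place the real maps in a manifest
  (`load_map_manifest()`) and rerun.

The ideal-chain generators (`generate_ideal_chain_frames()`) supply the
estimator oracles: a freely jointed chain (C_k ≡ 0, ⟨R_G²⟩ = Nb²/6) and a
freely rotating chain with C_k = cosθ^n, i.e. a discrete worm-like chain
with L_P = −l/ln cosθ, on which the three persistence-length routes
(correlation fit, Benoit–Doty, C_n plateau) are required to agree within
10%.

# Problem sizes

The test suite and acceptance script run at deliberately reduced scale,
chosen so each statistical check has a comfortable noise margin: single-link
ensembles use 10⁶ sweeps against 20×20 coarse histograms; the three-monomer
enumeration oracle uses 16×16 maps and 5×10⁶ sweeps against all
(bin, bin, charge) states; chain observables use DP = 40–240 with
4×10⁴–1.5×10⁵ sweeps; titration scans use DP = 50–60 over 5–9 pH values.
Estimator oracles use ideal-chain ensembles of 120–400 chains at
DP = 200–1000. Full-scale reproduction of experimental R_G (DP up to ~2100)
is an overnight computation with the same code path; the package checks the
direction and monotonicity of those trends at reduced DP instead.

# Known limitations

* The model applies to chitosan *in solution*: there are no attractive or
  hydrogen-bond terms, so aggregation and the insoluble regime (pH above
  ~7 at moderate ionic strength) are outside its validity.
* One chain, implicit solvent and ions; no Manning condensation, no
  dielectric inhomogeneity.
* pK_i is a constant; coupling of the intrinsic dissociation constant to
  solubility and hydrogen bonding is not modelled, so titration curves lose
  quantitative accuracy for weakly charged (low-DD, high-pH) systems.
* Ring puckering, exocyclic rotamers and branched architectures are not
  represented.
* The pivot + site-titration move set is efficient for open coils; for
  collapsed states acceptance degrades, which is another face of the
  in-solution validity limit.
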