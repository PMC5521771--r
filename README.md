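# chitomc

Coarse-grained, constant-pH Monte Carlo simulation of chitosan
polysaccharides in aqueous solution, with the analysis toolchain used to
characterize weak polyelectrolytes: radius of gyration, persistence-length
decomposition, worm-like-chain estimators and titration-curve fitting.

## The problem

Chitosan is a linear (1→4)-linked copolymer of glucosamine (GlcN,
deacetylated, titratable) and N-acetyl-glucosamine (GlcNAc, acetylated,
neutral). Its size, stiffness and charge in solution depend on the degree of
deacetylation (DD), the chain length (DP), the pH and the ionic strength
c\_s — and these couple: protonation of the amino groups depends on the local
electrostatic environment, which depends on the conformation, which depends
on the charge. Atomistic simulation cannot reach the relevant chain lengths
(DP up to thousands), so this package implements a one-site-per-monomer model
whose only flexible degrees of freedom are the two glycosidic dihedrals
(φ, ψ) of each link.

## The model

* **Bonded term.** Each link samples a 2-D free-energy map G(φ, ψ) (in
  k\_BT, 200×200 periodic grid). Nine maps cover the ordered combinations of
  the three monomer states {GlcNAc, GlcNH2, GlcNH3+} at the two ends of a
  link. Maps are loaded from text files or synthesized as two-well surfaces
  parameterized by the published per-link features (minimum position,
  accessible areas, gap ΔG₂ to the second minimum).
* **Sterics.** Purely repulsive (WCA) Lennard-Jones between ring-center
  sites: U = 4ε[(σ/r)¹² − (σ/r)⁶ + ¼] for r ≤ 2^{1/6}σ, else 0.
* **Electrostatics.** Debye–Hückel screening between non-adjacent charged
  monomers: U = z\_α z\_β λ\_B e^{−κr}/r (k\_BT), with λ\_B = 0.714 nm in
  water at 298 K and κ = (8π λ\_B N\_A c\_eff)^{1/2},
  c\_eff = c\_s + 10^{−pH}.
* **Titration.** Semi-grand-canonical protonation moves on GlcN sites with
  F\_prot = Σᵢ μᵢ zᵢ + Σ U^{DH} (nearest neighbours included), where
  μ = ln(10)(pH − pK\_i), pK\_i = 6.6. When a monomer's charge flips, the
  free-energy maps of its (up to) two adjacent links are swapped to the new
  monomer states.
* **Sampling.** Metropolis pivot moves: one link is re-drawn uniformly over
  the region of its map below a 7 k\_BT cutoff and the downstream chain is
  rotated rigidly; each pivot move is followed by N\_t titration attempts.

Analysis follows the standard polyelectrolyte toolkit: bond-vector
correlation C\_k = ⟨b\_i·b\_{i+n}⟩/⟨|b|²⟩ fitted as exp(−nl/L\_P); intrinsic
vs electrostatic decomposition L\_P = L\_P,0 + L\_P,e from matched runs
without electrostatics; Benoit–Doty inversion of
3R\_G²/L = L\_P(1 − 3x + 6x² − 6x³(1 − e^{−1/x})); the Odijk–Houwaart
iteration with z\_el = (27L/2π)^{1/2} κ⁻¹ L\_P^{−3/2} and
α\_el² = 0.541 + 0.459(1 + 6.04 z\_el)^{0.46}; the characteristic ratio
C\_n = ⟨R\_ee²⟩/(n l²); and the modified Henderson–Hasselbalch fit
pH = pK\_app + n·log₁₀(α/(1−α)).

## Worked example

```r
library(chitomc)

cfg <- simulation_config(dp = 100, dd = 0.9, ph = 4.5, cs = 0.1,
                         n_sweeps = 50000, seed = 42,
                         collect_frames = TRUE, log_stride = 50)
run <- run_simulation(cfg)
run
#> MC run: DP 100, DD 0.90, pH 4.50, cs 0.1 M, 50000 sweeps (seed 42)
#>   <Rg> 7.665 nm, <Ree> 20.219 nm, <alpha> 0.100 (post burn-in)
#>   acceptance: pivot 0.164, titration 0.200

persistence_length_fit(bond_correlation(run), run$l)
#> Persistence length fit: L_P = 6.442 nm (lags 4-39, R^2 = 0.9975)

degree_of_dissociation(run)$mean
#> [1] 0.1004537
```

A 100-mer at pH 4.5 (two units below pK\_i = 6.6) is ~90% protonated
(α ≈ 0.10, the fraction of *neutral* titratable sites), swollen by
electrostatic repulsion (R\_G ≈ 7.7 nm), with a persistence length of
~6.4 nm from the bond-correlation decay. About 16% of pivot proposals are
accepted under the 7 k\_BT map cutoff.

`autoplot()` methods exist for maps, runs and fits; `tidy()`/`glance()`
return tibbles. A thin CLI lives at `inst/cli/chito.R`
(`maps analyze`, `maps synth`, `sim run`, `analyze rg|lp|cn|titration`).

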