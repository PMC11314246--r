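# peptsam

Analysis of peptide adsorption and conformation on self-assembled
monolayers (SAMs), for computational biophysicists studying how surfaces
reshape the ensembles of intrinsically disordered, amyloid-forming
peptides.  The package implements, as tested reusable R functions, the
full analysis stack for a single amyloid-beta(10–40)-like peptide above a
planar SAM — adsorption geometry and residue contacts, helix/strand
conformation metrics, conformational clustering and entropy, replica
ladders for solute tempering, and end-point binding energetics — and
ships a synthetic-trajectory generator with known ground truth so every
stage can be validated without running molecular dynamics.

## What it computes

* **Adsorption geometry** — per-frame mass-weighted centre-of-mass height
  above the surface reference plane z₀ (the mean terminal heavy-atom
  height), closest-residue statistics, per-residue separation profiles,
  and residue–surface contact probabilities at the 3.5 Å nearest-heavy-atom
  cutoff, with contact-fingerprint clustering (exact grouping plus
  single-linkage merge at Hamming distance ≤ 1) and geometric
  protein–surface hydrogen-bond counts.
* **Conformation metrics** — helical hydrogen bonds counted through the
  rational switching function s(r) = (1−(r/r₀)ⁿ)/(1−(r/r₀)ᵐ) with
  r₀ = 2.5 Å, n = 8, m = 12, summed over O(i)···H(i+4) (α) and
  O(i)···H(i+3) (3/10) pairs; the dihedral offset
  DH = ½ Σ [(1+cos(φᵢ−φref)) + (1+cos(ψᵢ−ψref))] with strand references
  ±2.36 rad (range 0 … 2(N−1)); the radius of gyration and the gyration
  tensor eigenvalue roots Gmax ≥ Gmid ≥ Gmin with
  Gmax²+Gmid²+Gmin² = Rg²; a documented dihedral-plus-hydrogen-bond
  secondary-structure assigner; 100°-per-residue helical wheels with
  hydrophobic-face detection.
* **Conformational clustering** — Kabsch superposition RMSD, Daura
  (greedy neighbour-count) clustering at a 3 Å cutoff, Shannon
  conformational entropy in kB units (0 ≤ Sconf ≤ ln Nconf),
  combined-ensemble overlap across labelled systems, and the
  low-free-energy-cluster equilibration diagnostic (2 kcal/mol window).
* **REST ladders** — geometric temperature ladders with scaling factors
  β = T₀/T, solute-tempered energies E = β·Epp + √β·Eps + Ess,
  Metropolis exchange, and a toy double-well solute-tempering sampler
  with analytic well occupancies.
* **Energetics** — single-trajectory MM-PBSA adsorption free energy
  ΔGads = G_complex − G_protein − G_surface with G = E_MM + G_PB + G_SA:
  internal terms cancel identically, E_MM is inter-group 12-6
  Lennard-Jones + Coulomb, G_SA = γ·SASA (γ = 0.005 kcal mol⁻¹ Å⁻²,
  Shrake–Rupley areas, 1.4 Å probe) and G_PB is a pluggable backend
  (default zero).

Everything returns tibbles; result objects have broom-style `tidy()` /
`glance()` methods and `autoplot()` ggplot2 graphics.

## Worked example

Generate a 500-frame synthetic trajectory of the peptide permanently
adsorbed on a hydrophobic (methyl-terminated) SAM, with designed helices
at Q15–A21 and I31–V36, and analyse it:

```r
library(peptsam)

surf <- build_sam_surface(8, 8, "CH3")
gen  <- generate_trajectory(scenario_preset("samch3-like",
                                            n_frames = 500, seed = 7), surf)

com_separation(gen$trajectory)
#> <ps_separation> 500 frames; mean separation 8.48 A

ss <- assign_secondary_structure(gen$trajectory)
dplyr::filter(tidy(ss), author_index %in% 15:18)[, c("author_index", "code", "H")]
#> # A tibble: 4 × 3
#>   author_index code      H
#> 1           15 Q      0.95
#> 2           16 K      0.95
#> 3           17 L      0.95
#> 4           18 V      0.95

helical_wheel(ab1040_sequence(), 15, 21)
#> <ps_wheel> segment 15-21; hydrophobic face: L17, V18, F20, A21
#>   hydrophobic moment at 220 deg (length 1.23)

build_ladder(300, 440, 12)
#> <ps_ladder> 12 replicas, 300-440 K
#>   scaling factors: 1.000 (300 K), 0.966 (311 K), ..., 0.706 (425 K), 0.682 (440 K)

glance(adsorption_free_energy(subset_frames(gen$trajectory, 1:5)))
#> # A tibble: 1 × 7
#>   n_frames dg_ads dg_ads_se d_emm d_emm_se d_gsolv d_gsolv_se
#> 1        5  0.269      7.27  2.79     7.52   -2.52      0.436
```

The mean separation sits near the designed 7 Å adsorption height (biased
slightly upward by conformations too thick to reach it); the designed
helix is recovered with ~0.95 propensity while residues outside the
designed segments stay below 0.1; the Q15–A21 wheel shows the known
hydrophobic face with Q15 opposite; the ladder's scaling factors run from
1 at 300 K to 0.682 at 440 K; and the frame-wise energy table satisfies
ΔGads = ΔE_MM + ΔGsolv exactly, with a negative γ·SASA term from buried
contact area.

`run_pipeline(run_config(...))` chains all stages and writes every table
as TSV with a provenance header.

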