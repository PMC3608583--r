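# pmhcdyn

Post-simulation analysis of peptide–MHC class II molecular-dynamics
trajectories.

MHC class II molecules present antigenic peptides to T cells in a binding
groove formed by the α1 and β1 domains of their two chains. How rigid that
groove is, how wide it is around the classical anchoring pockets, which
hydrogen bonds, stacking and hydrophobic contacts tie the peptide down, and
how strongly the peptide binds are the quantities a structural immunologist
extracts from an MD simulation of such a complex. `pmhcdyn` implements that
entire post-processing pipeline as reusable, tested R code, for people who
have trajectories (or want to prototype the analysis on synthetic ones) and
need numbers, not viewer sessions.

## What it computes

Given a structure, a per-atom parameter table and a trajectory
(multi-model PDB), per system:

* **Binding-site RMSD** — per-frame Cα RMSD of the binding-site residues
  (α 5–76, β 5–90) after optimal rigid superposition (Kabsch) on the initial
  frame, plus normalized histograms with kernel-density mode detection.
* **Groove-width dissection** — the groove is split into four compartments
  covering the anchoring pockets, D1 (α50–51/β85–86), D2 (α53–55/β78–83),
  D3 (α60–65/β65–70), D4 (α68–73/β56–61); per compartment the per-frame
  distance between mass-weighted heavy-atom centres of the two walls.
* **Interaction networks** — residue-pair records persisting a fraction of
  frames: hydrogen bonds (donor–acceptor ≤ 3.1 Å, donor–H–acceptor ≥ 130°),
  planar stacking (plane–plane angle ≤ 30°, centroid distance ≤ 5.0 Å,
  Arg guanidinium counts as planar) and hydrophobic contacts (side-chain
  heavy atoms ≤ 4.0 Å, no water oxygen within 4.0 Å), reported at ≥ 20%
  persistence.
* **Quasi-harmonic configurational entropy** — frames are superposed on
  their mean, the 3n×3n mass-weighted covariance of Cα fluctuations is
  diagonalized, each eigenvalue λ defines a mode ω = √(k_BT/λ), and
  S = k_B Σ[(ħω/k_BT)/(e^{ħω/k_BT}−1) − ln(1−e^{−ħω/k_BT})]; reported as
  T·S in kcal/mol at 310 K.
* **SIE binding free energy** — solvated interaction energy over frames at
  a 20 ps stride: ΔG = α·(E_coul + ΔG_RF + E_vdW + γ·ΔMSA) + C with the
  published AMBER-trained coefficients (α = 0.1048, D_in = 2.25,
  γ = 0.0129 kcal mol⁻¹ Å⁻², C = −2.89 kcal/mol); the reaction field is a
  generalized-Born continuum and ΔMSA a rolling-probe buried surface.
  Virtual alanine scanning truncates any side chain past Cβ and rescores
  the same frames (ΔΔG).
* **ΔG ↔ IC50** — ΔG = k_BT·ln(IC50), IC50 in nM, binder/non-binder
  classification at the standard 1000 nM threshold, and IC50 ratios
  relative to a reference peptide.

A configuration-driven pipeline (`runPipeline`, `compareSystems`, YAML
config, packaged defaults profile, CLI script under `inst/scripts/`) runs
everything per system and compares allele × peptide grids.

A first-class synthetic-data module (`makeToyComplex`, `sampleTrajectory`,
`plantInteraction`) generates toy MHC-like systems and trajectories with
*planted*, exactly known truth — two-state groove widths, interactions
present in an exact fraction of frames, waters that veto hydrophobic
contacts — so every stage of the analysis is testable without running MD.

## Worked example

```r
library(pmhcdyn)

## a toy complex: 80-residue alpha wall, 95-residue beta wall, 14-mer peptide
sys <- makeToyComplex(n_alpha = 80, n_beta = 95, n_pep = 14, seed = 1)
sys
#> MolecularSystem: 1551 atoms, 189 residues
#>   chains: A(657 atoms), B(780 atoms), P(114 atoms)

## a groove that breathes between two widths in compartment D1
spec <- fluctuationSpec("two_state", state_means = c(10, 13),
                        state_occupancy = 0.5, compartment = "D1", seed = 2)
traj <- sampleTrajectory(sys, spec, n_frames = 600)
widths <- compartmentDistanceSeries(traj, compartmentSelections(sys))
distributionSummary(widths$D1, bin_width = 0.25)
#> DistributionSummary: 13 bins, 2 mode(s)
#>   location mass
#> 1       10  0.5
#> 2       13  0.5

## free energies -> IC50, ratios, binder calls (310 K)
ic50 <- ic50FromDg(c(MBP = -17.5, EBNA1 = -12.2), temperature = 310)
signif(ic50, 2)
#>     MBP   EBNA1
#> 0.00046 2.50000
ic50Ratio(ic50, "MBP")
#>      MBP    EBNA1
#>    1.000 5450.427
classifyBinder(ic50)
#>      MBP    EBNA1
#> "binder" "binder"
```

The two planted groove widths come back as two modes of exactly half the
mass each; the two free energies, 5.3 kcal/mol apart, translate into IC50s
more than three orders of magnitude apart — both peptides still under the
1000 nM binder threshold.

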