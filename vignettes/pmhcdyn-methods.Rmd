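---
title: "Methods: groove geometry, interaction persistence, entropy and SIE in pmhcdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: groove geometry, interaction persistence, entropy and SIE in pmhcdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pmhcdyn` post-processes molecular-dynamics trajectories of peptide–MHC
class II complexes. This vignette is the package's account of the models it
implements, the parameters that matter, the numerical choices made where
several were defensible, and what its synthetic-data tests do and do not
demonstrate about real trajectories.

## Data model

A `MolecularSystem` couples a per-atom topology table (name, element,
chain, residue, mass, partial charge, Lennard-Jones ε and r_min/2, Born
radius seed) to reference coordinates in Å. Chains follow the MHC class II
convention: `A` = α chain, `B` = β chain, `P` = peptide, `W` = water;
water residue names HOH/WAT/TIP3 are mapped to `W` on input. Residue
numbers are taken verbatim from the structure file (1-based per chain, the
mature-protein numbering used for these complexes); insertion codes are
ignored — a deliberate simplification, documented here, since the default
selections are defined on plain residue numbers.

Parameters come from a packaged text table covering the twenty amino acids
(polar hydrogens explicit, nonpolar hydrogens implicit) and water. Masses,
LJ parameters and radii are standard element-level values; partial charges
are representative of fixed-charge protein force fields and sum to each
residue's formal charge. Absolute energies therefore carry force-field-level
uncertainty; every energetic claim the package tests is structural
(linearity, locality, closed-form limits), not an absolute value.

Trajectories are `T × N × 3` arrays read from multi-model PDB — a text
format every MD package can export — with a frame interval in ps (default
200 ps, i.e. 600 frames spanning 120 ns, the sampling density the analysis
defaults assume).

## Binding-site RMSD and distributions

RMSD is computed on the Cα atoms of the binding site (α1 5–76 ∪ β1 5–90 by
default) after least-squares rigid superposition (Kabsch, reflections
excluded) of each frame onto a fixed reference, by default the first frame.
Whether one should superpose on the binding site only or on the whole
protein is genuinely open; the package fits on the same selection it
measures, and both the reference frame and the fit atom set
(`fit_atoms = c("N","CA","C","O")` for a full-backbone fit) are arguments.

Distributions are normalized histograms (default bin width 0.1 Å for RMSD,
0.25 Å for groove widths) plus a mode list from a Gaussian kernel density
estimate with bandwidth fixed at twice the bin width. Local maxima below 5%
of the highest peak are discarded as noise; each sample is assigned to the
basin between the density minima flanking its mode, so mode masses sum
to 1. These three constants (bin widths, bandwidth factor, prominence) are
exposed because peak reporting is the one place where smoothing choices can
change a qualitative statement ("unimodal vs bimodal"); the package only
ever reports the mode list and leaves the labels to the user.

## Groove compartments

The groove is dissected into four α/β residue-range pairs covering the
anchoring pockets: D1 (α50–51, β85–86), D2 (α53–55, β78–83), D3 (α60–65,
β65–70), D4 (α68–73, β56–61). Per compartment and frame the package
reports the Euclidean distance between the mass-weighted centres of the
heavy atoms of the two walls — mass-weighted, not geometric, because the
observable is a centre-of-mass distance. It is an internal coordinate,
hence rigid-motion invariant, which the tests assert directly. The
compartment table is configurable (any number of named compartments).

## Interaction detectors and persistence

All three detectors return residue-pair records with a per-frame presence
vector; persistence is its mean, and records at or above the persistence
threshold (default 0.2, i.e. 20% of simulation time) are reported. Multiple
qualifying atom pairs within one residue pair OR-combine into a single
record, because the scientific unit of reporting is the residue pair.

* **Hydrogen bonds**: donor–acceptor heavy-atom distance ≤ 3.1 Å and
  donor–H–acceptor angle ≥ 130°. The angle cutoff is interpreted as a lower
  bound — the convention of the standard trajectory tools — since an upper
  bound would reject near-linear bonds, which cannot be what a cutoff of
  130° is for. Donors require explicit polar hydrogens.
* **Stacking**: acute angle between least-squares planes of the two
  side-chain ring/planar groups ≤ 30° and ring-centroid distance ≤ 5.0 Å.
  The planar class is {His, Phe, Tyr, Trp, Arg}: arginine's guanidinium
  (CZ + three N) is planar and participates in stacking with aromatic
  partners, so excluding it would silently drop a biologically reported
  interaction class. The Trp indole is fitted as a single plane.
* **Hydrophobic contacts**: minimum side-chain heavy-atom distance ≤ 4.0 Å
  between residues of the hydrophobic class {Ala, Val, Leu, Ile, Pro, Phe,
  Met, Trp}, vetoed if any water oxygen lies within 4.0 Å of any
  contact-forming atom. The water veto implements "isolated from water"
  as a purely geometric criterion.

The detectors take the two residue groups as explicit arguments; the
pipeline default pairs the β-chain binding-site residues with the peptide,
the comparison the groove analysis is usually about, and an α-side run is
one argument away.

## Quasi-harmonic entropy

Frames are superposed on their mean structure (two fit–remean iterations)
over the selection's Cα atoms; the 3n×3n mass-weighted covariance
σ = M^{1/2} C M^{1/2} (amu·Å²) is diagonalized; each eigenvalue λ gives a
mode frequency ω = √(k_BT/λ) and the quantum harmonic oscillator entropy
S/k_B = α/(e^α−1) − ln(1−e^{−α}) with α = ħω/k_BT; the package reports
T·S in kcal/mol at 310 K. Eigenvalues below 10⁻¹² amu·Å² are dropped as
rigid-body/rank artifacts (superposition itself zeroes six modes); short
trajectories trigger a rank warning rather than an error, because a
truncated spectrum is still interpretable as a lower bound.

The estimator is validated against the closed form evaluated on the true
covariance of a known Gaussian ensemble (30 Cα atoms, 90 coordinates;
agreement within 5% at 600 frames and 1% at 10⁴ frames). That test
covariance is constructed inside the rigid-motion-free subspace of the
reference coordinates (plus a negligible floor): superposition removes
rigid-body variance by design, so a test covariance with substantial
rigid-body content would measure the fitting step, not the entropy
estimator. Rigid-body variance is not configurational entropy, so this is
the physically meaningful comparison, chosen when the test was designed.
Per-mode amplitudes are kept at realistic magnitudes (~0.1–0.5 Å); the
superposition step is a linearization and degrades measurably if
fluctuations become comparable to the molecule's size.

One interpretive point: estimating a covariance-based entropy "per
extracted structure" is undefined; the package computes one estimate over
the whole extracted ensemble (600 frames by default), which is the only
reading under which the method exists.

## SIE binding free energy

Per frame, for disjoint receptor and ligand selections:

ΔG = α·(E_coul + ΔG_RF + E_vdW + γ·ΔMSA) + C

* E_coul: intermolecular Coulomb energy screened by D_in (332.0637·q_iq_j /
  (D_in·r_ij) kcal/mol).
* E_vdW: intermolecular 12-6 Lennard-Jones with Lorentz–Berthelot-style
  combination (ε_ij = √(ε_iε_j), r_min,ij = r_i/2 + r_j/2) and a 10 Å
  cutoff.
* ΔG_RF: change in reaction-field solvation on binding from a
  generalized-Born continuum (f_GB = √(r² + R_iR_j·e^{−r²/4R_iR_j}),
  D_in = 2.25 inside, 78.5 outside). With fixed Born radii the per-molecule
  self-terms cancel, leaving the receptor–ligand cross-term. The original
  SIE formulation uses a boundary-element Poisson solver; the GB continuum
  is this package's documented substitute, which is why absolute ΔG values
  from the package are not comparable to published SIE numbers — the
  package's validated claims about SIE are structural (the linear form,
  symmetry, locality, closed-form limits) plus the exact ΔG↔IC50
  arithmetic.
* γ·ΔMSA: buried molecular surface, ΔMSA = A(complex) − A(receptor) −
  A(ligand) ≤ 0, from a deterministic Shrake–Rupley rolling-probe estimate
  (probe 1.4 Å, 240 golden-spiral points per heavy atom). No installed R
  package computes solvent-accessible surface areas natively, so the
  estimator is implemented here; 240 points give areas stable to well under
  γ-weighted significance.
* Coefficients default to the published AMBER-trained SIE set (α = 0.1048,
  D_in = 2.25, γ = 0.0129 kcal mol⁻¹ Å⁻², C = −2.89 kcal/mol, T = 310 K),
  all overridable.

Trajectory scoring evaluates frames at a fixed stride (default 20 ps) and
reports mean, standard deviation and the IC50 of the mean. Virtual alanine
scanning deletes side-chain atoms past Cβ at one position, reassigns the Cβ
alanine parameters, and rescores the *same* frames (single-trajectory
approximation — no re-simulation, consistent with standard end-point
practice); glycine positions are an error (no Cβ), alanine positions a
warned zero.

IC50 conversion uses ΔG = k_BT·ln(IC50) with k_B = 1.9872×10⁻³
kcal mol⁻¹ K⁻¹ and IC50 in mol/L inside the logarithm, reported in nM.
This convention is pinned by the published protective-allele rows it
reproduces: −17.5 kcal/mol → 4.6×10⁻⁴ nM and −12.2 kcal/mol → 2.5 nM at
310 K, ratio ≈ 5.4×10³. The predisposing-allele printed IC50 cells are
internally inconsistent with their own ΔG values under any convention (the
two cells appear transposed), while the printed *ratio* (3) is consistent;
the package therefore validates against the consistent rows and the
ratios, and does not attempt to "correct" the published table. Binder
classification uses the standard threshold, binder ⇔ IC50 ≤ 1000 nM
(boundary inclusive, as stated wherever the threshold is defined).

## Synthetic data: what it emulates, and what passing tests show

The generator builds a coarse MHC-like architecture: two antiparallel
chain walls flanking an extended peptide, with the β chain offset so the
four default compartment pairs face each other across the cleft, plus
optional explicit waters parked outside the groove. Residues carry
backbone plus the minimal side-chain atoms each detector needs, at
approximate internal geometry. The default sequence palette deliberately
contains only short side chains so that the *unplanted* background is free
of incidental contacts — any interaction a detector reports on a clean
synthetic system is one that was planted; tests introduce Phe/His/Val/Ser
partners explicitly where a plant needs them.

Fluctuation modes: iid Gaussian displacement (amplitude in Å), a full 3N×3N
Gaussian (for oracle tests on small systems), and a two-state mode that
rigidly translates one compartment's β wall between two exact target
widths with occupancy realized exactly by seeded sampling without
replacement. Plants overwrite partner-residue coordinates frame by frame:
in exactly round(f·T) seeded frames the geometry satisfies the detector's
default criteria with margin (≥ 0.2 Å / 10°, so floating point cannot flip
a decision); in the rest the partner is displaced far outside every
cutoff. Water sub-plants place a water oxygen 3.0 Å from the contact in a
chosen fraction of satisfying frames.

What this does *not* emulate: force-field energetics in generation,
realistic side-chain rotamers, solvation shells, correlated backbone
dynamics, or real MBP/EBNA-1 sequences (sequence content is labels).
Passing tests therefore demonstrate that the analysis mathematics is
correct — geometry, counting, spectra, linear algebra, unit conversions —
not that any particular biological system behaves in any particular way.
All randomness flows through explicit integer seeds; identical seeds give
bit-identical systems, trajectories and pipeline artifacts, which the
end-to-end tests check byte for byte.

## Numerical choices and degenerate inputs

* Kabsch uses SVD with the determinant sign correction; fewer than three
  fit atoms is a geometry error. Agreement with a rotation-grid +
  Nelder-Mead oracle is asserted to 10⁻³ Å on 4-point sets.
* Histogram edges snap to multiples of the bin width; a constant series
  yields a single bin of mass 1 and one mode at the value.
* Plane fitting uses the smallest singular vector of the centered ring
  coordinates; plane–plane angles are folded to the acute range.
* Eigenvalue floors: 10⁻¹² amu·Å² (entropy), 10⁻¹⁰ relative (PSD check in
  the generator). Distances are floored at 10⁻⁶ Å inside energy kernels to
  avoid 0/0 on pathological inputs; genuine clashes (< 0.5 Å) warn with
  the frame index.
* The persistence filter at threshold 0 returns all candidate pairs,
  including zero-persistence ones, so callers can retrieve the full
  candidate grid.
* Test problem sizes were chosen as the smallest that make each statistical
  assertion sharp: 600 frames where exact planted counts are asserted
  (0.6·600 = 360), 5000 frames for covariance convergence on 30
  coordinates, 600/10⁴ frames for the entropy oracle at 5%/1%, 50 random
  frames on a ≤ 200-atom system for exhaustive brute-force detector
  comparison, and 5–6 frame runs for pipeline determinism checks.

## Known limitations

* The GB reaction field and the coarse charge set make absolute ΔG values
  indicative only; differences and scan ΔΔGs on the same system are the
  meaningful outputs.
* Entropy assumes the quasi-harmonic model: a single well, Gaussian
  fluctuations; multimodal dynamics (which the groove analysis itself can
  detect) inflate the estimate.
* Insertion codes and alternate locations in PDB files are ignored.
* DCD and other binary trajectory formats are not read; convert to
  multi-model PDB first.
* The detectors are criteria-faithful, not energy-aware: a geometrically
  qualifying contact counts regardless of its interaction energy.
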