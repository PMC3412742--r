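---
title: "Coarse-grained network modes and MM/PBSA ledgers for multi-stoichiometry receptor complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained network modes and MM/PBSA ledgers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anmpbsa)
```

## The scientific problem

TNF-family ligands are homotrimers with three equivalent receptor-binding
grooves, yet signalling complexes of intermediate stoichiometry — one
ligand trimer engaging only one or two receptor chains — are plausible
intermediates of receptor activation. Deciding whether such 3:1 and 3:2
complexes are mechanically and energetically feasible requires two
complementary instruments: a coarse-grained normal-mode model that asks
whether the receptor's functional motions change upon binding, and a
free-energy ledger that asks whether each successive receptor binds
favourably. This package implements both, together with the trajectory
observables (RMSD, RMSF, correlation maps, hydrogen bonds, buried
surface, distance monitors) used to characterise such complexes, and a
synthetic-data layer that makes every stage testable against exact ground
truth.

## The network model and its assumptions

The model is an anisotropic network model (ANM) extended with side-chain
resolution. Per residue there are up to two nodes: the Cα, and a
side-chain node at the heavy-atom centre of mass — except for ASP, ASN,
ARG, LYS, GLN and GLU, whose electrostatic business end is the side-chain
tip, so their node sits on the Cγ, Cγ, Cζ, Nζ, Cδ and Cδ atom
respectively. Glycine has no side-chain node. Springs connect all node
pairs within 1.2 nm; the harmonic energy is
$E = \sum_{(i,j)} \tfrac{k_{ij}}{2}(|r_i - r_j| - d_{ij}^0)^2$
with rest lengths equal to the build-time distances, so the input
structure is the mechanical ground state by construction.

Force constants encode bonding, in kcal·mol⁻¹·Å⁻² (converted to
kJ·mol⁻¹·nm⁻² internally, a choice observable only in eigenvalue units
since every reported quantity — mode shapes, overlaps, correlations,
fluctuation profiles — is scale-free):

* 10 for the intra-residue Cα–side-chain tether and for disulfide
  bridges between cysteine side-chain nodes (the receptor's cysteine-rich
  domains owe their rigidity to these bridges, so they must be springs of
  bonded strength);
* 6 for sequential Cα pairs inside one α-helix or β-strand;
* 3, 2, 1 by distance shell (≤ 0.4, 0.4–0.8, 0.8–1.2 nm).

When several rules could apply to one pair the first match in the order
tether, bridge, secondary structure, shell wins. This precedence is a
design choice the rules themselves do not force: the tether and bridge
describe covalent topology and must dominate; applying a distance-shell
constant to an already-tethered pair would silently double-count. Two
further readings were genuinely open:

* *Which Cα pairs does secondary-structure stiffening cover?* The
  conservative reading — only sequential (i, i+1) pairs within one
  contiguous element — is the default; stiffening all intra-element pairs
  is available via `enm_params(ss_mode = "all_pairs")`. Sequential
  stiffening changes only bonds that exist anyway, so it cannot alter
  network connectivity, which makes it the safer default.
* *Disulfide detection.* Rather than depending on an external assignment
  program, bridges are detected geometrically: SG–SG pairs within 0.25 nm
  (the canonical bond is ~0.205 nm), each cysteine in at most one bridge,
  closest distance first. Secondary-structure labels are likewise
  ingested as a plain (chain, residue, H/E/C) table from any assigner,
  since labels are the only information the model consumes.

The Hessian assembles the standard ANM super-elements
$H_{ij} = -(k_{ij}/d_{ij}^2)\, r_{ij} r_{ij}^{\mathsf T}$ with diagonal
blocks closing each row to zero, which makes uniform translations exact
null vectors. Masses are not used (pure ANM). Modes with
$|\lambda| \le 10^{-8}\lambda_{\max}$ are classified rigid; a connected
free-floating network has exactly six, and more than six raises an error
naming the disconnected components rather than silently analysing a
fragmented model. Eigenvector signs are fixed by making the
largest-magnitude component positive so that exports are reproducible;
overlaps use absolute values and are sign-blind.

Mode-derived observables: mean-square fluctuations
$\mathrm{MSF}_i \propto \sum_m |v^{(m)}_i|^2/\lambda_m$ and B-factors
$(8\pi^2/3)\,\mathrm{MSF}$, reported up to a global scale (experimental
comparison is by profile shape; `scale_to_bfactors()` provides the
least-squares match for plotting); overlap matrices between two models'
lowest modes restricted to a common node set, each sub-vector
renormalised; correlation maps from the n-mode pseudo-inverse; and
displacement arrows for one mode scaled so the two elongated structures
differ by a target RMSD (default 0.2 nm, i.e. 2 Å).

## Trajectory observables

All superposition-based metrics use an in-package Kabsch (SVD) fit.
RMSD series fit each frame to the reference over the selected Cα atoms
minus any exclusion windows — flexible terminal residues (for the TNFR1
receptor, the 134–153 tail spanning the end of CRD3 and CRD4) otherwise
dominate the series. RMSF and DCCM superpose on the average structure
with one refit iteration. Whether the fluctuation reference should be
fit per chain or over the whole selection was open; the whole selection
is used, which attributes inter-domain motion to the domains rather than
removing it.

Hydrogen bonds are geometric: donor–acceptor distance ≤ 0.35 nm and a
D–H⋯A angle within 60° of linearity. The angular text admits two
readings — a maximum deviation from 180° or a minimum D–H⋯A angle — and
the deviation reading is the default because it matches the common
geometric-criterion tools for united-atom models; both are exposed via
`hbond_criteria(angle_convention =)`. Donors are N/O atoms with a
hydrogen within 0.12 nm (united-atom structures carry only polar
hydrogens); acceptors are all N/O.

SASA is Shrake–Rupley with a 0.14 nm probe, Bondi-style radii and 960
deterministic golden-spiral points per atom, so results are exactly
reproducible for a fixed point count; doubling the count moves totals by
well under 0.5 % on the test fixtures. Buried area per residue is its
SASA with the partner removed minus its SASA in the complex, averaged
over frames.

## The free-energy ledger

Per snapshot the ledger books
$G = H_\mathrm{int} + H_\mathrm{vdW} + H_\mathrm{elect} + G_\mathrm{polar} + G_\mathrm{apolar}$,
with the entropy term identically zero and surfaced in the output
metadata as neglected: the dominant entropy loss — one receptor leaving
free solution — is comparable across the sequential binding steps and
cancels in their comparison. Gas-phase terms are full pairwise sums
(no cutoff, no periodicity); the Coulomb sum uses vacuum permittivity
(ε = 1, configurable), because the reduced solute dielectric belongs to
the Poisson–Boltzmann stage, not the mechanical model. Solving the PB
equation is out of scope by design: `G_polar` always enters as a
per-snapshot column whose provenance (solute/solvent dielectrics 2 and
78.54, 225³ grid at 0.5 Å, van der Waals boundary, no counterions) is
recorded verbatim with the import, so ledgers remain auditable. The
apolar term is linear in SASA, `γ·SASA + b` with γ = 0.0227 kJ·mol⁻¹·Å⁻²
and b = 3.85112 kJ·mol⁻¹.

Binding is `ΔG = G(complex) − G(protein) − c·G(ligand)` componentwise.
The unbound receptor reference is half a receptor dimer (receptors
crystallise as dimers in the absence of ligand), implemented by scaling
the dimer's per-snapshot values by ½ before differencing — this is what
`stoich_step(1..3)` encodes for the three sequential binding steps. In
single-trajectory (SITA) assembly the partners' coordinates come from the
complex trajectory, so all bonded terms cancel exactly (ΔH_int ≡ 0) and
the gas-phase differences reduce to explicit cross-partner sums — an
identity the tests enforce against brute-force pair enumeration. In
separate-trajectory (SETA) assembly each species is averaged over its own
snapshots and standard errors combine in quadrature with the
stoichiometric coefficients. H_int is computed only when bonded
force-field tables are supplied; otherwise the SETA ledger is emitted
without it and flagged incomplete — the bonded terms cannot be invented.
The error bar is the plain σ/√n standard error with no autocorrelation
correction (no estimator convention is imposed on the snapshot spacing);
ledgers print at 0.1 kJ/mol while machine output keeps full precision,
which is why componentwise sums can differ from a rounded total by
0.1 kJ/mol.

## What the synthetic data emulates — and what it does not

`make_toy_structure` builds Cα traces with ideal helix geometry (0.15 nm
rise, 100° twist), extended strands, compact coil, one pseudo side-chain
atom per non-glycine residue, and cysteine pairs placed to satisfy
requested disulfides at 0.203 nm. `sample_enm_ensemble` draws frames
from the network's exact Gaussian,
$x = x_0 + \sum_m z_m \sqrt{T/\lambda_m}\, v^{(m)}$, rather than running
toy dynamics: the model's analytic RMSF and correlation matrix are then
the *exact* ground truth, and the temperature is a pure variance scale
because every downstream comparison is shape-based. This closes the
package's central loop — model → ensemble → trajectory metrics →
recovered model — which the acceptance suite checks at 5000 frames of a
30-residue mixed-topology toy (profile correlations above 0.95, per-mode
variance χ² tests at a Bonferroni-corrected α = 0.01; the problem size
keeps the whole suite in seconds while leaving per-mode statistics
sharp). `make_planted_interface` plants hydrogen-bond geometries and
decoys violating exactly one criterion each; `make_energy_table` plants
Gaussian energy columns with known means.

What passing these tests does *not* show: real proteins are not Gaussian
ensembles (anharmonicity, multi-basin dynamics), real side chains are
not single pseudo-atoms, real trajectories have autocorrelated snapshots
(so σ/√n understates the true error), and the linear apolar model is a
parameterisation, not physics. The synthetic layer validates the
*bookkeeping and estimators*, not the force field.

## Numerical choices and degenerate inputs

* Coordinates are nm internally; PDB Å values convert on read/write, and
  residue ranges are author-numbered and inclusive.
* Alternate conformations resolve to the highest-occupancy copy (ties:
  first record) — the original structure processing convention for the
  crystal inputs is not documented anywhere, so this common default is
  used.
* Degenerate eigenvalues make individual eigenvectors arbitrary within
  their subspace; overlap diagonals are therefore only meaningful for
  modes separated by a spectral gap, and the tests restrict
  rotation-invariance assertions accordingly.
* A motionless trajectory has no correlation matrix; `dccm()` errors
  naming the zero-variance residues, and the pipeline records the
  condition instead of failing the run.
* Coincident charged atoms make the Coulomb sum singular and raise an
  error rather than returning infinity.
* The RMSD floor for structures round-tripped through PDB files is set
  by the format's three-decimal precision (~0.001 Å per coordinate).

## Known limitations

No Gaussian-network variant, no mass weighting, no all-atom NMA; no PB
or generalised-Born solver, no entropy estimation, no per-residue
MM/PBSA decomposition; no trajectory unwrapping or binary MD formats.
The structure comparison between the bound and unbound receptor crystal
forms (`receptor_state_rmsd`) operates on any two local PDB files but
the published accession pair must be downloaded by the user; the test
suite exercises the pathway on constructed two-state fixtures with
exactly known deformations instead.
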