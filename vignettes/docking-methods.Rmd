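---
title: "Rigid-body RNA-protein docking and RMSD-based rescoring: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body RNA-protein docking and RMSD-based rescoring: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpcdock)
```

## The problem

Predicting how an RNA molecule binds a protein, given the two structures
separately, is a two-stage problem: *sampling* candidate rigid-body
placements of the RNA (the ligand) against the protein (the receptor), and
*scoring* the candidates so that near-native placements rank first.
`rpcdock` implements both stages — an FFT-accelerated grid docking scan and
a knowledge-based residue-base pair potential — plus the decoy-assessment
metrics used to judge the result against a known native complex.

## Stage 1: the FFT docking scan

Both molecules are discretized onto one shared cubic grid (default spacing
1 Å). The receptor shape grid distinguishes a *surface* layer (occupied
cells whose center lies within `surface_thickness` = 1.5 Å of an empty
cell, value `surface_weight` = +1) from its *core* (deeper cells, value
`core_penalty` = -15); the ligand grid is binary. For one ligand
orientation, the geometric-complementarity (GC) score of every translation
$t$ is the circular cross-correlation

$$\mathrm{GC}(t) = \sum_x R(x)\, L(x+t),$$

so surface-surface overlap is rewarded while penetration into the core
self-penalizes through the negative core value. Electrostatics (ELEC)
enters the same way: the receptor grid holds the Coulomb potential
$\phi(c) = \sum_j q_j / (\varepsilon(r_{cj})\, r_{cj})$ with a
distance-dependent dielectric, and the ligand grid holds partial charges
spread trilinearly over the eight surrounding cell centers. The combined
score is $\mathrm{GC} + w_{\mathrm{elec}}\,\mathrm{ELEC}$ with
$w_{\mathrm{elec}} = 1$ by default. Both correlations are evaluated for all
$n^3$ translations at once via the convolution theorem; per orientation the
implementation needs one packed forward FFT (shape and charge grids share a
single complex transform) and one inverse FFT.

Orientations are swept on a uniform z-y-z Euler lattice,
$\alpha \in [0,360)$, $\beta \in [0,180]$, $\gamma \in [0,360)$ at
`rotation_step` (default 15 degrees; the convention is intrinsic z-y-z
about the ligand centroid — any proper three-angle convention would do, so
the choice is fixed and documented rather than configurable). Per
orientation the best `keep_per_rotation` = 3 translations are retained on
the combined score, with lexicographic translation order breaking ties;
retention happens after the electrostatic term is added, since retention is
defined on the full docking score.

Tunable parameters, defaults, and why:

| parameter | default | meaning |
|---|---|---|
| `grid_step` | 1 Å | grid spacing; 1 Å balances fidelity and $O(n^3 \log n)$ FFT cost |
| `surface_thickness` | 1.5 Å | depth of the rewarded receptor surface layer |
| `surface_weight` / `core_penalty` | +1 / -15 | classic soft-overlap weights from the FTDOCK lineage of grid-docking programs; the exact production values of the original tool are unpublished, so every knob is exposed |
| `rotation_step` | 15° | orientation lattice spacing (desk-scale tractability) |
| `elec_weight` | 1.0 | weight of the charge-potential correlation |
| `elec_cutoff` / `elec_rmin` | 12 Å / 2 Å | potential truncation and soft-core clamp keeping the grid finite near atoms |

The dielectric is the continuous piecewise-linear form
$\varepsilon(r) = 4$ for $r \le 6$ Å, $38r - 224$ for $6 < r < 8$ Å, and
$80$ for $r \ge 8$ Å (continuous at both knots). Partial charges come from
an embedded united-atom table for the 20 amino acids and 4 ribonucleotides:
hydrogen charges are folded onto their bonded heavy atom because deposited
structures are typically hydrogen-free, and one designated atom per residue
(CA, or C1' for nucleotides) absorbs the rounding residual so each complete
residue sums exactly to its formal charge. The table is the package's own;
it follows the magnitudes of a published all-atom force field for backbone
and phosphate atoms but is not the original authors' parameter set.

Sign convention: internally "better" is always "larger correlation". The
original tool prints negative scores; `negate_scores` flips the emitted
sign without changing the ranking.

The grid is sized automatically (`auto_grid_spec()`): a cube covering the
receptor and the ligand at its input position, padded by the ligand extent
plus the largest van der Waals radius, rounded up to an FFT-friendly size
(factors 2, 3, 5). The padding guarantees that the circular correlation
cannot wrap one molecule onto the other, and because the spec is a
deterministic function of the input structures and the step, the analysis
stage can rebuild the identical grid from the same files without any side
channel.

## Stage 2: the residue-base pair potential

The statistical unit is a contacting (amino-acid residue, nucleotide) pair:
every pair whose minimum heavy-atom distance is at most 10 Å (inclusive) is
extracted. Each pair is reduced to nine atoms — residue N, CA, C, O, CB
(CA doubles for glycine's missing CB) and nucleotide P (O5' for a
5'-terminal nucleotide), C4', C1', and the glycosidic nitrogen (N9 for
purines, N1 for pyrimidines) — so that pairs of the same (residue type,
base type) class always share an exact atom correspondence and their
conformational distance is a well-defined superposition RMSD (Kabsch).

Training pools the pairs of native complexes and clusters each type class
by greedy leader clustering in source order: a pair joins the first cluster
whose leader is within 6 Å RMSD, else founds a new cluster. Cluster
energies are inverse-Boltzmann in the member counts,

$$E_c = -\ln\!\left(n_c / \bar{n}\right),$$

with $\bar{n}$ the mean cluster size within the class, so the most
populated (most native-like) conformation class gets the lowest energy.
Scoring a decoy extracts its pairs, matches each to the nearest standard
pair of the identical class, assigns that energy when the match RMSD is
*strictly* below 6 Å and zero otherwise, and sums. The 10 Å extraction
boundary is inclusive and the 6 Å match boundary strict; pairs of different
type classes are never compared; the unmatched fallback of zero is a
package choice (the original description leaves it open). The trained
library serializes to versioned JSON and reloads byte-equivalently.

One scale caveat worth knowing: with this nine-atom reduction the
superposition RMSD between two *physically plausible* conformations of the
same pair class rarely exceeds ~4 Å (the reduced pair is compact, and
optimal superposition absorbs most of a rigid displacement), so at the
6 Å threshold realistic training data tends to form one cluster per class.
The synthetic training populations used in the tests therefore plant
deliberately exaggerated conformation classes (helix-parameterized
layouts with mutual RMSD above 6 Å) to exercise the clustering and energy
arithmetic; they are testbeds for the math, not chemistry.

## Decoy assessment

Metrics compare a rebuilt decoy against the native complex after residues
are mapped by global sequence alignment (Needleman-Wunsch, match +1,
mismatch -1, gap open -5, extend -1, affine; chains pair in order and the
map fails below 30% identity). The external alignment binary of the
original pipeline is replaced by this internal aligner so the package has
no build-time system dependency.

* `R_rmsd` — receptor backbone RMSD (N, CA, C, O) after superposing on the
  receptor backbone.
* `L_rmsd` — RNA backbone RMSD (P, O5', C5', C4', C3', O3') measured in the
  receptor frame: the complexes are superposed on the protein backbone and
  the RNA deviation is taken without refitting.
* `I_rms` — backbone RMSD over the native-interface residues (any heavy
  atom within 10 Å of the partner), superposed on that same interface set.
* `fnat` / `fnon` — a contact is a residue-nucleotide pair with minimum
  heavy-atom distance at most 5 Å; `fnat` is the fraction of native
  contacts present in the decoy, and `fnon` the fraction of the decoy's
  contacts that are non-native (denominator = decoy contact count; the
  other convention, native count, is a one-line change and the choice is
  documented here deliberately). Backbone sets and the 5 Å / 10 Å cutoffs
  follow CAPRI assessment practice; the metrics' one-word definitions in
  the original protocol fix neither.

## The synthetic fixture generator

`make_toy_complex()` builds a deterministic protein/RNA pair with a known
native pose so every stage is testable without downloading structures. The
protein is a chain threaded through a cubic lattice (1.8 Å spacing) filling
a slab whose top face carries a carved trench closed at both ends; the RNA
is a straight strand whose bases lie flat against the trench floor at a
2 Å gap with a low-profile backbone on top. Three features make the
generated placement the unique optimum of the geometric-complementarity
score, which the self-docking tests rely on: the trench walls and end caps
are part of one solid mass (so any deep penetration reaches core cells and
pays the clash penalty), every third base is raised over a floor knob (a
non-palindromic knobs-into-holes pattern that defeats strand reversal and
slides), and the flat top face outside the trench is checkerboard-pitted so
a rigid tile cannot seat closely anywhere else. Residue and base
identities, and the strand's ring-twist phase, derive from the seed; the
same seed reproduces byte-identical PDB files.

The generator emulates *geometry only*: occupancy, contacts, clashes,
charges on correct atom names. It does not emulate realistic backbone
torsions, base pairing, flexible loops, crystallographic noise, or the
composition biases of real RNA-protein interfaces. Green tests therefore
demonstrate that the scan, the scoring arithmetic, the metrics and the
formats are implemented correctly — not that the default score parameters
would reproduce benchmark success rates on real complexes, which the
original publication reports with parameters that were never published.

Manifest quantities (contact lists, pair counts, closed-form ligand RMSDs
of standard perturbations) are computed inside the generator by direct
distance geometry, independent of the analysis module, and serve as ground
truth in the cross-module tests.

## Numerical choices and degenerate inputs

* FFT correlation is exact to ~1e-12 relative against the direct sum;
  consistency between scanned scores and rebuilt poses is exact up to FFT
  rounding because integer-cell shifts commute with discretization.
* Translations stored in pose records live in $[0, n)$ grid units;
  components at or above $n/2$ wrap to negative shifts when a pose is
  rebuilt, matching the circular scan.
* Ties in the translation ranking break lexicographically on
  $(t_x, t_y, t_z)$; ties across rotations break on rotation index. Reruns
  are byte-identical.
* Kabsch superposition uses SVD with a determinant sign correction (always
  a proper rotation); degenerate inputs (< 3 points) are errors.
* Alternate locations resolve to the highest occupancy (ties prefer blank,
  then 'A'); only the first MODEL is read; HETATM water/ions are dropped;
  residues that are neither standard amino acids nor standard
  ribonucleotides are dropped with a warning rather than guessed at.
* All-zero charge input yields a warning and a zero electrostatic grid
  rather than an error, so shape-only docking remains possible.

## Problem sizes used in the bundled checks

The self-docking checks run five fixture complexes (about 460 protein
atoms, 5 nucleotides) at 1 Å grids (about $50^3$ cells) over a 30-degree
rotation lattice (1,008 orientations, three poses kept per orientation) —
sizes chosen so the full five-complex sweep completes in a few minutes on
one core while still exercising every code path at realistic grid
dimensions. The correlation oracle runs on grids up to $12^3$, where the
$O(n^6)$ direct sum is still affordable.

## Known limitations

* The production parameter values of the original tool (GC weights,
  dielectric form, electrostatic weight, trained pair potential) are not
  public; this package ships documented defaults from the same algorithm
  family and exposes all of them. Benchmark success rates from the
  original publication are therefore out of scope here.
* Rigid-body only: no flexibility, minimization, or clash relief on built
  complexes.
* The pair potential trains on whatever native set the user supplies; no
  curated training library is bundled.
* The aromatic stacking term is a centroid-distance count, off by default,
  provided as an optional rescoring column (`stacking_bonus()`); where the
  original pipeline applies its stacking correction is not documented, so
  it deliberately does not enter the default docking score.
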