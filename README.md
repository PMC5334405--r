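# rpcdock

Rigid-body docking of RNA onto proteins with FFT-accelerated translation
scans, knowledge-based rescoring of the docked poses, and CAPRI-style
decoy assessment — an R implementation of the classic two-stage
protocol for RNA–protein complex structure prediction, aimed at
structural bioinformaticians who want an inspectable, scriptable version
of the grid-docking pipeline.

## What it computes

**Stage 1 — docking.** The protein (receptor) and RNA (ligand) are
discretized onto a shared cubic grid. The receptor grid carries a
surface layer (+1) over a core penalty (−15); the ligand grid is binary.
For each orientation on a z-y-z Euler lattice the score of every
translation *t* is evaluated at once by FFT cross-correlation:

    score(t) = GC(t) + w_elec * ELEC(t)
    GC(t)    = sum_x R(x) L(x+t)
    ELEC(t)  = sum_x phi(x) q(x+t),    phi(c) = sum_j q_j / (eps(r_cj) r_cj)

with a distance-dependent dielectric (4 below 6 Å, 38r−224 between 6 and
8 Å, 80 beyond) and AMBER-style united-atom charges. The best three
translations per orientation are retained (G_DATA records).

**Stage 2 — rescoring.** Contacting residue–nucleotide pairs (minimum
heavy-atom distance ≤ 10 Å) are reduced to nine atoms each and compared
by superposition RMSD. Native training pairs are clustered per
(residue, base) class at 6 Å by greedy leader clustering and each
cluster gets an inverse-Boltzmann energy `E_c = -ln(n_c / n_bar)`; a
decoy's energy is the sum of the energies of its pairs matched strictly
below 6 Å.

**Assessment.** Rebuilt decoys are compared with a native complex via
sequence-alignment residue mapping: receptor RMSD, ligand RMSD in the
receptor frame, interface RMSD (10 Å interface), and native/non-native
contact fractions at 5 Å.

## Worked example

Everything below runs on the package's deterministic synthetic fixture —
a lattice protein slab with a carved trench and an RNA strand nested in
it at a known native pose:

```r
library(rpcdock)

tc <- make_toy_complex(1)          # protein + RNA + manifest, seed 1
write_pdb(tc$protein, "protein.pdb")
write_pdb(tc$rna, "rna.pdb")

p <- dock_params("protein.pdb", "rna.pdb",
                 receptor_chains = "A", ligand_chains = "R",
                 outfile = "toy.out", rotation_step = 90)
rec <- dock(p)
head(rec, 3)
#>   rotation_index score tx ty tz alpha beta gamma
#> 1             16   116  0  0  0   270    0    90
#> 2             27   116  0  0  0   180    0   180
#> 3             38   116  0  0  0    90    0   270
```

The top poses sit at translation `(0, 0, 0)` with `alpha + gamma = 360`
and `beta = 0` — identity rotations: the scan recovered the generated
native placement exactly (score 116, the planted optimum). The G_DATA
file carries the same records, score in column 4, translation in columns
6–8, rotation in columns 9–11:

```
G_DATA 16 0 115.98 0 0 0 0 270.0 0.0 90.0
```

Assessing the first three rebuilt decoys against the native complex:

```r
analyze_decoys("rmsd.par")   # step-13-style keys, see ?analyze_decoys
```

```
#Decoy R_rmsd L_rmsd I_rms fnat fnon
1 1.05558e-15 9.47638e-16 3.00576e-15 1 0
...
```

All three decoys are the native pose: zero RMSDs (to rounding), all
native contacts kept (`fnat = 1`), no spurious ones (`fnon = 0`).

Training and applying the pair potential on a planted population with
cluster sizes (9, 3, 3):

```r
lib <- train_potential(make_pair_training_set(c(9, 3, 3), seed = 1))
lib
#> pair_library: 3 standard pairs (15 training pairs), extraction 10 A,
#> cluster threshold 6 A
score_complex(read_pdb("complex1.pdb"), "A", "R", lib)
#> [1] -28.44464
```

The major cluster carries `-ln(9/5) = -0.588`; the docked complex's 48
extracted pairs match it repeatedly, giving the negative (favorable)
total.

A thin command-line front end mirrors the four pipeline stages:

```sh
exec/rpcdock dock    --par RPDock.par     # or: --mode 9 --system 9
exec/rpcdock build   --par RPDock.par
exec/rpcdock score   --par scoring.par
exec/rpcdock analyze --par rmsd.par
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "rpcdock",
                               load_package = "installed")'
```

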