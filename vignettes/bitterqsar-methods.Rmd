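---
title: "Methods: descriptor-based QSAR and contact profiling for T2R46 ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptor-based QSAR and contact profiling for T2R46 ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitterqsar)
```

# Scope and model

`bitterqsar` models the structure-activity relationship between small
polyphenol-like ligands and the human bitter taste receptor T2R46. Its
central statistical object is a two-descriptor linear model of the docking
binding-energy score $S$ (kcal/mol; more negative = stronger predicted
binding):

$$ S = -1.26777 \; - \; 0.01161 \cdot \mathrm{vsurf\_S} \; + \; 0.00007
\cdot \mathrm{wienerPath} $$

where `vsurf_S` is an interaction-field surface area (Å²) and `wienerPath`
is the Wiener path number of the heavy-atom graph — half the sum of all
entries of the topological distance matrix, a measure of molecular
extension and branching. `published_model_predict()` evaluates these frozen
constants and never refits them. Everything else in the package exists to
(a) compute analogous descriptors from structures, (b) re-derive models of
this form from descriptor tables by genetic-algorithm subset selection with
OLS fitting, and (c) profile receptor-ligand contact geometry and aggregate
it into per-residue population maps.

The package consumes docking output (poses and scores); it never generates
poses or scores itself. That boundary is deliberate: pose search and
scoring-function decomposition belong to the docking engine, and records
emitted here carry geometry (distances, angles) with an optional
pass-through field for externally supplied energies.

# Molecule model and descriptors

Molecules are heavy-atom graphs with implicit hydrogens; hydrogen counts
come from pinned standard valences (shifted by formal charge for N, P, O,
S), so molecular weight over a pinned atomic-weight table reproduces
printed reference values to two decimals (strychnine C21H22N2O2 =
334.41 g/mol). SMILES and SDF parsing is delegated to OpenBabel (via
ChemmineR/ChemmineOB); because OpenBabel kekulizes its output, aromatic
rings are re-perceived in-package as 5- and 6-membered rings of
sp2-capable atoms with an alternating double-bond pattern. This targets
benzenoid and ordinary heteroaromatic chemistry; exotic aromaticity is out
of scope. Multi-fragment inputs (salts) keep the largest fragment, since
every topological descriptor here assumes a connected graph.

`wiener_path()` works on the heavy-atom graph with unit bond lengths
regardless of bond order — the distance matrix is topological — and a
hydrogen-inclusive variant can be toggled (`include_h = TRUE`). Whether
the original commercial descriptor includes hydrogens is not documented;
the heavy-atom convention was chosen once and is tested against an
independent BFS oracle and the path-graph closed form $n(n^2-1)/6$.

`descriptor_pool()` computes eleven built-in descriptors (atom, ring,
H-bond-donor/acceptor and branching counts, the two Zagreb indices,
`wienerPath`, MW) and pads the vector to a configurable width (default
336) with deterministic nonlinear transforms of the built-ins. The exact
commercial descriptor list behind the original 336-column table is
proprietary and unpublished; what matters for the selection experiments is
the *width* and redundancy of the search space, not the identity of each
column, so the padding is an interface with a deterministic default fill.

# The interaction-field surface area

The exact definition of the commercial `vsurf_S` descriptor is
proprietary. The package defines a documented analogue with the same
semantics (bigger, branchier molecules expose more interaction surface,
which is all the published model's sign structure uses):

1. a single 3D conformer per molecule, from a seeded in-package embedder
   (classical MDS on the topological distance matrix, seeded jitter, then
   L-BFGS-B refinement of bond-length, 1-3-distance and aromatic-ring
   restraints). The embedder is a pure function of (graph, seed); no
   conformational averaging is performed, preferring determinism;
2. a water-oxygen probe field on a rectangular grid (default spacing
   0.5 Å, padding 4 Å): Lennard-Jones 12-6 with Lorentz-Berthelot
   combination against an OPLS-like water oxygen (r = 1.52 Å,
   eps = 0.152 kcal/mol) plus a Coulomb term over Gasteiger-type
   iterative-equalisation partial charges with a distance-dependent
   dielectric (eps = 4r). Missing charge parameters degrade gracefully to
   the pure steric field with a warning;
3. the area of the +0.2 kcal/mol isoenergy surface (the conventional
   molecular-surface level), estimated by face counting: every grid face
   whose adjacent nodes straddle the level contributes spacing². Axis-
   aligned face counting over-estimates any smooth surface by the surface
   average of $|n_x|+|n_y|+|n_z|$, which is exactly 3/2 for a sphere; the
   estimator divides this calibration constant out. After calibration a
   single van der Waals sphere is recovered within 5% at 0.2 Å spacing,
   disjoint surfaces add within 2%, and rigid-body motion moves the
   estimate by under 2% at default spacing.

Numeric `vsurf_S` values are therefore *not* comparable to any proprietary
implementation — no reference values exist to compare against — but the
descriptor's role in the model is fully exercisable.

# QSAR selection and validation

`split_train_test()` draws a seed-deterministic random split with
`round(fraction * n)` training compounds (490 at 0.8 gives 392/98).
`fit_ols()` is QR-based least squares; degenerate cases are explicit
conventions rather than silent NaN: a zero-variance response fits the
constant model with R² defined as 0, and a rank-deficient design errors
naming the collinear columns. `loo_q2()` holds the descriptor subset fixed
and refits only coefficients per fold, via the hat-matrix identity
$e_{(-i)} = e_i/(1-h_{ii})$, which equals the explicit refit loop to
machine precision (tested to 1e-10); the subset is not re-selected per
fold because the quantity reported is the cross-validated fit of one final
model.

`ga_evolve()` selects descriptor subsets: bit chromosomes over the table's
columns, tournament selection (size 2), one-point crossover at rate 0.8,
per-bit mutation at 0.01, elitism 1, at most 4 descriptors per model, and
fitness = training R² − 0.01·(subset size). The original selection tool's
internal settings are unpublished; these defaults were sized once so that
recovering 2 signal columns from a 336-column pool at n = 490 runs in
seconds per seed. Fitness is computed on the training set only (of the two
defensible readings of the published workflow, optimising on data the test
evaluation never sees is the conservative one). Because per-bit mutation
over hundreds of bits almost never emits the exactly-minimal subset, the
best chromosome receives a deterministic backward-elimination polish —
drop any descriptor whose removal improves the penalised fitness — a
standard finishing step in descriptor-selection GAs. Elitism makes the
best-fitness trace non-decreasing, which is asserted in the tests.

# Contact typing and population maps

`detect_interactions()` types contacts geometrically, in the vocabulary of
the reference tables (H-Donor, H-Acceptor, Ionic, H-pi, pi-H, pi-pi), for
receptor residues within 8 Å of the ligand:

* hydrogen bonds: donor-to-acceptor heavy-atom distance ≤ 3.5 Å, with a
  donor-H-acceptor angle ≥ 120° enforced whenever an explicit H is
  placeable (ligand explicit hydrogens); receptor hydrogens are not
  modelled, so receptor-donor geometry is distance-only;
* salt bridges: opposite charge-group centers ≤ 4.0 Å (Asp/Glu
  carboxylate midpoints deprotonated, Lys/Arg and aliphatic amines
  protonated — the standard pH-7 convention). The same residue pair may
  yield both an H-Donor and an Ionic record, the classic glutamate
  pattern;
* ring stacking: aromatic ring centroids ≤ 5.5 Å with inter-plane angle
  ≤ 30°;
* CH-pi: a carbon carrying hydrogens to a ring centroid ≤ 4.5 Å with
  elevation ≥ 45° above the ring plane (`H-pi` when the ligand donates
  into a receptor ring, `pi-H` for the converse). Aromatic carbons are
  excluded as carriers: their C-H lies in the ring plane and cannot point
  at a stacked ring face, so parallel aromatic pairs are typed `pi-pi`
  only — which is also the pattern the reference tables print.

The typing thresholds are config-exposed with those defaults; the source
tables print contact distances (3.24-4.19 Å) but never the thresholds that
typed them, so the defaults were chosen once to accept every printed
contact. Ring planes and elevations are computed from an SVD plane fit and
are side-agnostic; all typing is invariant under rigid-body motion of the
whole complex.

`population_map()` counts records per residue over a compound set
(conventionally each compound's lowest-energy pose, selected by
`lowest_energy_selection()` with first-occurrence tie breaking) and
reports each residue's share of all typed contacts rounded to one decimal,
e.g. 250 of 453 records at one glutamate = 55.2%.

Generic GPCR residue labels (Ballesteros-Weinstein style, "7.39") are an
optional user-supplied annotation map, never computed: the source
literature itself labels the same tryptophan inconsistently, so the
package refuses to guess.

# What the synthetic generators emulate

`gen_descriptor_table()` plants the published linear relationship as
generative truth: `vsurf_S` uniform on 150-1500 Å², `wienerPath`
log-uniform on 50-60000 (the dynamic range implied by the 94-2806 g/mol
compound-size span of the published ranking table), decoy columns of mixed
shapes and scales drawn independently of the response, and Gaussian noise
sized analytically so the population R² is 0.93, echoing the reported fit
quality at the same n = 490. Passing the recovery tests therefore shows
that the selection-and-validation machinery finds a relationship of the
published strength at the published problem size. It does *not* show
anything about real descriptor tables, whose columns are mutually
correlated in structured ways, whose noise is not Gaussian, and whose true
model need not be linear or sparse. `gen_random_molgraph()` grows random
valence-legal trees with optional ring closures for descriptor oracles;
it makes no attempt at realistic polyphenol chemistry.
`gen_toy_complex()` builds one-residue receptors with correctly named PDB
atoms and ligands placed to satisfy (or violate) exactly one detection
rule each, mirroring the printed contact geometries; they are fixtures
with known answers, not docking poses.

# Problem sizes and runtime choices

The default test and demonstration sizes are the study's own where they
are known (490 compounds, 336-column pool, 392/98 split) and desk-scale
otherwise: sphere-calibration grids at 0.2 Å spacing (about 200k nodes),
GA recovery over 10 seeds (about 20k model fits per seed), LOO oracles at
n = 50. The full test suite runs in well under a minute on one CPU.

# Known limitations

* SMILES coverage follows OpenBabel; stereochemistry is accepted but
  ignored throughout (no 3D descriptor here depends on it, but the
  embedder will happily produce either enantiomer's geometry).
* The embedder targets idealised local geometry, not force-field minima;
  it is adequate for surface-area descriptors, not for pose prediction.
* Gasteiger-type charges use a pinned small parameter table; elements
  outside it fall back to sp3-carbon parameters with a warning.
* Interaction typing omits cation-pi and halogen bonds by design, and
  per-contact energies are never computed.
* The published model's numeric descriptor inputs cannot be reproduced
  bit-for-bit from structures, because both original descriptors are
  proprietary; the frozen equation plus in-package analogues are the
  supported path.
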