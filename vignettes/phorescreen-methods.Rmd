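---
title: "PhoreScreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PhoreScreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhoreScreen)
```

## The scientific problem

The kinin peptides signal through two G-protein-coupled receptors, the
bradykinin B1 and B2 receptors. Ligand-based models of the two binding sites
share four pharmacophore points — a positive charge (P1), a hydrogen-bond
donor-or-acceptor (P2), an aromatic ring (P3) and a second donor-or-acceptor
(P4) — with a fixed set of consensus inter-point distances, while a fifth
point (P5) discriminates the receptors: a hydrogen-bond acceptor for B1, a
hydrophobic/aromatic moiety for B2. A small molecule whose conformers can
present features at the P1–P4 geometry is a candidate *non-selective*
antagonist of both receptors; this is the query behind the drug-repurposing
screen the package reproduces, in which eight approved drugs (raloxifene,
sildenafil, cefepime, cefpirome, imatinib, ponatinib, abemaciclib,
entrectinib) emerged as candidates from a molecular-weight-filtered subset
of a drug database.

PhoreScreen implements the full engine: feature perception, the pharmacophore
models with their distance matrices, distance-geometry diagnostics, seeded
conformer-ensemble generation, tolerance-based correspondence matching, and
the end-to-end screen. A bundled fixture library (the eight drugs plus
constructed decoys without any positive-ionizable group) stands in for the
licensed drug database.

```{r}
builtinModel("bk_consensus")
```

## Feature perception and the protonation model

Perception is rule-based and conformation-independent: which atoms carry
which feature is decided once per molecule from its graph and formal
charges; only the feature *positions* change between conformers. The rules
are SMARTS patterns shipped as a plain-text table
(`system.file("extdata", "feature_smarts.tsv", package = "PhoreScreen")`) so
the scheme can be inspected and swapped:

* POSITIVE — every atom with positive formal charge (one feature per
  ionizable group, carried by the charged atom);
* DONOR — every N or O bearing at least one hydrogen;
* ACCEPTOR — every N or O with an available lone pair, excluding pyrrole-type
  N–H, amide and sulfonamide nitrogen, and positively charged nitrogen;
  ethers and ester oxygens are retained as (weak) acceptors;
* AROMATIC — one feature per aromatic ring (5–7-membered), at the ring
  centroid;
* HYDROPHOBIC — one feature per non-aromatic carbocycle and per maximal
  chain of at least three acyclic carbons bonded only to carbon or
  hydrogen, at the group centroid.

Single-atom features sit exactly on their source atom. The composite
"donor/acceptor" character of P2 and P4 lives on the model side (those points
accept either type); perception stays atomic, which keeps it unambiguous and
testable.

Formal charges come from a fixed pH ≈ 7.4 rule table: aliphatic amines and
the sp2 nitrogen of amidines/guanidines are protonated (+1), carboxylic
acids and tetrazoles deprotonated (−1); pyridine-type, aniline, amide and
sulfonamide nitrogens stay neutral. Two basic centers within three bonds
(the two nitrogens of a piperazine, for instance) yield a single cation;
the nitrogen with more hydrogens, then the one farther from aromatic rings,
is preferred — aryl substitution lowers amine basicity, and this choice
reproduces the experimentally protonated nitrogen for the
methylpiperazine-containing drugs in the fixture set. The rules are
idempotent by construction (each pattern matches only the un-ionized form);
no pKa prediction or tautomer enumeration is attempted.

## Tolerances: sphere radii and pair allowances

Each model point carries a tolerance expressed as the radius of a sphere
around the point (1.5 Å by default; 2.0 Å for P5, whose printed distance
rows are not exactly consistent with the consensus block). Because matching
is performed on distance matrices — never on embedded model coordinates —
the operative quantity is the *pair allowance*: two points with radii
$r_i$ and $r_j$ accept a pairwise-distance deviation up to $r_i + r_j$
(features at the extremes of both spheres). For the consensus model every
pair therefore allows 3.0 Å; pairs involving P5 allow 3.5 Å. This is the
standard sphere-tolerance convention of ligand-based pharmacophore tools,
and it is the reading under which the eight known hit drugs are
geometrically able to satisfy the model: direct optimization in torsion
space shows that five of the eight have a minimax distance deviation floor
between 2.1 and 2.7 Å, so a flat 1.5 Å per-pair allowance would make the
published screen unreproducible for any conformer ensemble, while the
radius-sum allowance admits all eight and still excludes every decoy (which
fail on feature types, not geometry).

## Distance-geometry embedding and realizability

`embedModel()` realizes a model's distance matrix in 3D by classical
multidimensional scaling: the squared-distance matrix is double-centered to
a Gram matrix whose eigendecomposition yields coordinates. The matrix is
flagged *realizable* iff at most three eigenvalues are positive, none lies
below −1e−8 times the largest magnitude (a numerically scaled
positive-semidefiniteness condition equivalent to the Cayley–Menger
criterion), and the realized distances reproduce the targets within
1e−6 Å. Eigenvector signs are canonicalized (largest component positive) so
results are reproducible; coordinates are centered at the origin and are
unique up to rigid motion and reflection — distances cannot discriminate
chirality, which is also why matching is reflection-invariant.

The consensus matrix is exactly realizable. The two 5-point matrices are
not: trilaterating P5 against P1–P3 of the B1 set forces a negative squared
out-of-plane component (about −4.9 Å²), and the B2 set leaves an
irreducible residual on the P4–P5 distance. `embedModel(..,
"least_squares")` therefore also offers a stress-minimizing embedding
(BFGS refinement from the MDS start, analytic gradient) whose residual is
reported honestly; it is used only for visualization and for the
superposition-RMSD diagnostic. The matcher itself never embeds a model,
which is precisely how the 5-point inconsistency is absorbed by the P5
tolerance radius.

```{r}
embedModel(builtinModel("bk_b1"), "strict")
```

## Conformer generation

`generateConformers()` is a seeded, fully deterministic build-up in three
stages:

1. **Base geometries by stochastic distance geometry.** Distance bounds are
   assembled from force-field equilibrium bond lengths, hybridization-ideal
   angles (tetrahedral/trigonal/linear, polygon-interior angles in small
   rings), exact regular-polygon geometry within aromatic rings, cis/trans
   torsion extremes for 1–4 pairs and van-der-Waals lower bounds elsewhere,
   then triangle-smoothed. Four bound-biased samples are realized by
   metric-matrix embedding and minimized hard (3000 steps); up to three
   mutually distinct (≥ 1 Å heavy-atom RMSD) low-energy bases are kept so
   ring puckers are not frozen to a single form.
2. **Torsion-driven candidates.** Rotatable bonds (acyclic single bonds
   between non-terminal atoms, excluding amide C–N and sp centers) are
   driven from the bases with three cycling sampling modes — a 60° grid
   with jitter, an extended-biased mode that drives backbone dihedrals
   toward anti, and fully uniform angles — with a cheap steric pre-screen.
   The pool is oversampled (15× the requested count) and a maximally
   diverse subset is selected greedily in the space of feature-pair
   distances, the coordinates that matter downstream; the selection is
   query-agnostic.
3. **Force-field refinement and pruning.** Every candidate is minimized with
   MMFF94 (UFF fallback when MMFF94 lacks parameters) through the OpenBabel
   executables, which are deterministic for a fixed input file; energies
   come from the same force field. Conformers are pruned to an energy
   window above the ensemble minimum, rejected if any non-bonded atom pair
   comes below 0.5 Å, and deduplicated by heavy-atom RMSD (Kabsch).

Defaults: 200 requested conformers, 0.5 Å deduplication threshold,
20 kcal/mol energy window, 500 refinement steps per candidate. Every random
draw derives from the user seed through fixed per-candidate sub-seeds, so
ensembles are byte-identical across runs and candidate *t* is the same
whatever the requested count — which is what makes retained-conformer counts
monotone in `n` on rigid fixtures.

What the generator emulates is ensemble *coverage* of pharmacophore
geometry, not thermodynamics: gas-phase force fields over-stabilize
collapsed conformers of cations, there is no solvation, no conformer
free-energy weighting, and stereocenters are not constrained during the
distance-geometry stage (matching is reflection-invariant, so this does not
affect screen outcomes). Passing the bundled screen therefore shows that
the engine recovers the eight drugs' feasible pharmacophore geometries; it
does not validate conformer populations against experiment.

## Matching

`matchConformer()` returns *all* injective, type-compatible assignments of
model points to features whose pairwise deviations respect the pair
allowances. The search backtracks over model points ordered by fewest
compatible features and prunes each partial pair; an exhaustive
`bruteForceMatch()` oracle (guarded to ≤ 10 features) is part of the public
API and the test suite asserts set-equality between the two on hundreds of
random instances. Results are ordered by the sum of squared deviations with
lexicographic tie-breaks; `matchMolecule()` reports the best (conformer,
assignment) pair, breaking ties by conformer index, so reports are exactly
reproducible. The RMSD of the matched features onto the model's
least-squares embedding (optimal proper superposition) is reported as a
diagnostic only — it depends on the non-unique embedding of inconsistent
5-point models and is never a match criterion. Partial (3-of-4) matches are
not supported; all model points are essential.

## The screen

`runScreen()` executes, per molecule: closed-interval molecular-weight
filter ([200, 600] g/mol by default, computed on the parent structure with
implicit hydrogens before protonation), protonation, conformer generation
(sub-seed = screen seed + library position − 1), matching against the
configured models, and labeling: `no_match`, `non_selective_candidate`
(consensus matched; also when both or neither 5-point model matched),
`b1_biased`/`b2_biased` (exactly one 5-point model matched),
`consensus_only` (consensus matched and no 5-point model was screened),
`filtered_out`, or `error` (per-molecule conformer failures are recorded,
not fatal). Consensus hits are flagged for external docking — the published
workflow docks hits against receptor models to check steric hindrance, a
receptor-side step outside this package's scope. The CSV report has a
frozen column order and no timestamp (byte-identical across reruns);
run metadata including the timestamp lives in the side-car summary file.

## Numerical choices and degenerate inputs

* Realizability eigenvalue cutoff: relative, 1e−8 × the largest eigenvalue
  magnitude — robust across distance scales.
* Model validity requires symmetry, zero diagonal, positive off-diagonals
  and the triangle inequality within 2× the default tolerance radius;
  violations are construction errors.
* A molecule with zero atoms is invalid at construction; `weightFilter`
  rejects `lo >= hi`; `generateConformers` rejects `n < 1`; the brute-force
  matcher refuses more than 10 features.
* Kekulized bond orders plus `M CHG` blocks round-trip through the SDF
  writer byte-identically; all-zero coordinate blocks are read as "no
  coordinates".
* Kabsch superposition enforces a proper rotation (det = +1) and needs at
  least three points; conformer deduplication falls back to a
  distance-matrix RMSD below three atoms.

## Problem sizes in the shipped tests

The test suite embeds and round-trips all three models, compares matcher
and oracle on 500 random instances (≤ 8 features, ≤ 5 points), exercises
the property suites (tolerance monotonicity, rigid-motion/reflection
invariance, seed determinism) on dozens of random cases, and runs the full
screen — eight hits plus ten decoys at the default 200 conformers — once
with a fixed seed. The fixture screen is the expensive step (a few minutes
on one core); all other tests are seconds.

## Known limitations

* The perception table is a calibrated default, not a reimplementation of
  any particular commercial scheme; molecules relying on exotic feature
  definitions (projected H-bond points, charged aromatics) may be perceived
  differently.
* Protonation is rule-based; pH-sensitive or tautomeric molecules get the
  fixed convention described above.
* The conformer generator targets geometric coverage; do not interpret its
  energy ordering thermodynamically.
* The screen establishes necessary geometric conditions only — a
  `non_selective_candidate` label is a hypothesis for receptor-side
  checks and experiment, not a potency prediction.
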