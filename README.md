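# PhoreScreen

Ligand-based pharmacophore perception, matching and virtual screening in R,
built around the five-point pharmacophore of non-selective bradykinin
B1/B2-receptor antagonists.

## What it does, and for whom

The bradykinin receptors B1 and B2 are GPCRs whose ligand-based binding
models share four pharmacophore points — a positive charge (P1), a
hydrogen-bond donor/acceptor (P2), an aromatic ring (P3) and a second
donor/acceptor (P4) — with consensus inter-point distances

d(1,2) = 9, d(1,3) = 14, d(1,4) = 10.5, d(2,3) = 6, d(2,4) = 7,
d(3,4) = 7.5 (all in &#8491;),

while a fifth point P5 discriminates the receptors (B1: acceptor, with
d(i,5) = 9.5, 9.3, 9.5, 5.7; B2: hydrophobic/aromatic, with d(i,5) = 11,
9, 8.8, 8.4). A molecule able to present features at the P1–P4 geometry in
some accessible conformation is a candidate *non-selective* antagonist —
the query behind a drug-repurposing screen that surfaced raloxifene,
sildenafil, cefepime, cefpirome, imatinib, ponatinib, abemaciclib and
entrectinib.

PhoreScreen is for computational chemists who want that engine as an open,
scriptable library: SMILES/SDF input, rule-based protonation and feature
perception (SMARTS tables shipped as editable data), seeded
distance-geometry + torsion-driving conformer ensembles with force-field
refinement (OpenBabel MMFF94/UFF), classical-MDS embedding of pharmacophore
distance matrices with 3D-realizability diagnostics, tolerance-sphere
correspondence matching with a brute-force oracle, Kabsch superposition,
and an end-to-end screen with selectivity labels. A bundled fixture library
(the eight drugs plus decoys constructed without any positive-ionizable
group) stands in for the licensed drug database.

Matching is performed on distance matrices, never on embedded model
coordinates: the strict embedding proves the consensus matrix exactly
realizable while both 5-point matrices are not (for B1, trilaterating P5
forces a squared out-of-plane component of about −4.9 &#8491;²), and the
inconsistency is absorbed by the P5 tolerance radius. Two points with
tolerance radii r_i and r_j accept a pairwise-distance deviation up to
r_i + r_j (1.5 &#8491; default radius, 2.0 &#8491; for P5).

## Worked example

```r
library(PhoreScreen)

model <- builtinModel("bk_consensus")
embedModel(model, "strict")
#> EmbeddingResult (strict): realizable = TRUE, max residual = 4.44e-15 A
#> Gram eigenvalues:  1.015e+02  2.746e+01  3.136e+00 -4.655e-15

imatinib <- assignProtonation(fixtureLibrary(nDecoys = 0)@hits[[5]])
imatinib
#> Molecule 'imatinib': 37 heavy atoms, 41 bonds, net charge +1, no coordinates

ens <- generateConformers(imatinib, n = 60, seed = 15)
ens
#> ConformerEnsemble of 'imatinib': 11 conformer(s) (requested 60, seed 15)
#>   energy range: 101.59 .. 120.32 kcal/mol

res <- matchMolecule(ens, model)
res
#> MatchResult: 'imatinib' MATCHES 'bk_consensus' (conformer 3, max dev 1.629 A,
#>   sum sq 6.649 A^2, superposition RMSD 1.184 A)
round(res@best@deviations, 2)
#> P1-P2 P1-P3 P1-P4 P2-P3 P2-P4 P3-P4
#>  1.63  0.56  0.72  0.95  1.27  0.81
```

The embedding is exactly realizable (three positive Gram eigenvalues, zero
residual): the printed consensus distances are a genuine 3D geometry. The
protonated imatinib (piperazine mono-cation) matches the model: conformer 3
presents a positive charge, two H-bond partners and an aromatic ring whose
six pairwise distances deviate from the targets by at most 1.63 &#8491;,
within the 3.0 &#8491; pair allowance of two 1.5 &#8491; tolerance spheres.
The superposition RMSD (features onto the model's least-squares embedding)
is diagnostic only.

The full screen, with molecular-weight filtering to [200, 600] g/mol and
all three models:

```r
lib <- fixtureLibrary(nDecoys = 10, seed = 1)
rep <- runScreen(lib, screenConfig(seed = 11))
table(results(rep)$label)
#>               b1_biased                no_match non_selective_candidate
#>                       2                      10                       6
```

All eight drugs match the consensus model (six also match both or neither
5-point model, two additionally match only the B1 model); all ten decoys
fail, because without a positive-ionizable group P1 is unmatchable. A
command-line front-end is available at `inst/scripts/phorescreen`
(`model show|embed|validate`, `confgen`, `screen run|fixtures`).

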