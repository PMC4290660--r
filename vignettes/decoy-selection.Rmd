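---
title: "Selecting native-like protein decoys with pcSM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting native-like protein decoys with pcSM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoyrank)
```

## The problem

Conformational sampling in protein structure prediction produces far more
candidate models than anyone can inspect. The useful output of a pipeline
is a *handful* of models, so the scientific work is in the selection: how
to get from 10⁴–10⁵ decoys to five candidates without knowing the native
structure. `decoyrank` implements one complete answer — RMSD clustering,
a physico-chemical score, a quality re-ranking, and a staged merge — plus
the evaluation machinery (Cα RMSD, TM-score) needed to measure how well
the selection worked when a native is available.

## The pcSM score

Each decoy is reduced to seven descriptors, combined linearly:

$$\mathrm{CS} = c_{A1} A_1 + c_{A2} A_2 + c_{A3} A_3 + c_{A4} A_4 +
\max(c_{P_H} P_H,\; c_{P_S} P_S) + c_{M1} M_1$$

| term | meaning | units | default coefficient |
|------|---------|-------|---------------------|
| A1 | SASA fraction from nonpolar residues | – | 10 |
| A2 | SASA fraction from nonpolar (C, S) atoms | – | 0.1 |
| A3 | hydropathy-weighted SASA | Ų | 1e-5 |
| A4 | total SASA | Ų | 1e-3 |
| PH | % of predicted-helix residues not realized as helix | % (0–100) | 0.15 |
| PS | % of predicted-strand residues not realized as strand | % (0–100) | 0.21 |
| M1 | mean Cα distance from the Cα centroid | Å | 1e-3 |

All six contributions grow as a model gets worse — unfolding exposes
hydrophobic surface (A1–A3), inflates total area (A4) and the radius-like
M1, and destroys predicted secondary structure (PH, PS) — so the package
ranks by **ascending** CS. Three points here are package design decisions
rather than inherited definitions, and are therefore configurable or
prominently documented:

* **The penalty term** is realized as `max(0.15·PH, 0.21·PS)`: each
  penalty carries its own coefficient and the larger *product* enters the
  sum. This is the only reading under which both coefficients are usable.
* **M1** is defined as the mean Euclidean distance of Cα atoms from their
  centroid — a compactness measure on the Å scale, dimensionally
  consistent with its 10⁻³ coefficient.
* **A3 weights** are shifted Kyte–Doolittle hydropathies (`KD + 4.5`, so
  all weights are ≥ 0, range 0–9); the weight table and the nonpolar
  residue set `{ALA, VAL, LEU, ILE, PRO, PHE, MET, TRP, GLY}` are
  arguments of `surface_terms()` so users can substitute their own.

Penalties are on a 0–100 percent scale, which makes the penalty term
contribute O(0–21) — commensurate with the A1 term (O(0–10)) and the A4
term (O(5–20) for protein-sized areas).

## Surface areas

`sasa()` is a Shrake–Rupley implementation with a deterministic
generalized-spiral (Fibonacci) point lattice — no random sampling, so
areas are bit-stable across runs. Because the lattice is fixed in space,
coordinates are first moved to a canonical principal-axes frame (axis
signs fixed by coordinate skewness); this makes the measure invariant
under rigid motion of the input, which the descriptor tests rely on. The
default 960 points per atom agree with a 10,242-point lattice to about 1%
on protein-sized inputs; the probe radius defaults to 1.4 Å (water). Van
der Waals radii are a fixed table (C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20 Å); hydrogens are excluded by default because decoy sets are
typically heavy-atom only.

## Secondary structure

Decoys frequently lack amide hydrogens, so hydrogen-bond-based assignment
(DSSP-style) is deliberately avoided. `assign_ss()` uses φ/ψ windows:
helix for φ ∈ (−100°, −30°), ψ ∈ (−80°, −5°) in runs of ≥ 4; strand for
φ ∈ (−170°, −40°), ψ ∈ (90°, 180°) ∪ (−180°, −170°) in runs of ≥ 3; coil
otherwise. Chains with only Cα atoms fall back to the Cα(i)→Cα(i+3)
distance criterion (5.0 ± 1.0 Å, runs ≥ 4; helix only). The windows are
generous by design: the penalties PH/PS should punish *lost* structure,
not borderline torsions.

## Clustering

`kclust()` emulates an RMSD-radius K-means-style clustering with
centroid-distance assignment on heavy atoms at radius 1.0 Å. The exact
iteration semantics of the classic toolkit implementations are not
published, so the package uses a documented, deterministic stand-in: a
leader pass in lexicographic id order (assign to the first centroid
within the radius, else seed a new cluster), followed by Lloyd-style
refinement (centroid = coordinate mean of members after least-squares
fitting each member onto the current centroid; reassign to the nearest
centroid, seeding a fresh cluster when none is within the radius) until
membership stabilizes or `max_iter = 10`. Determinism is a contract:
shuffling the input pool changes nothing, which also makes internal
parallelization safe. Centroids are mathematical constructs; the
representative retained per cluster is the member closest to its
centroid. By the triangle inequality for superposed RMSD, representative
picking can cost at most 2·radius in best-retained RMSD, which the tests
verify empirically.

## Quality re-ranking

The published pipeline re-ranks with a six-tool meta-server whose
combination rule is unpublished; wrapping six external binaries is out of
scope here. `composite_quality()` is an explicit, transparent stand-in
(labelled `protsav-standin` in CLI output) with two components:
the fraction of residues outside generous Ramachandran boxes and the
number of non-bonded heavy-atom pairs closer than 2.0 Å per residue,
combined as `100·rama + 10·clash`. Low is good, 0 is an ideal chain; on
synthetic pools the composite correlates positively with true error. It
is *not* a calibrated reproduction of the meta-server.

## The staged selection protocol

`select_top5()` chains the stages: cluster → representatives → pcSM top
10 → quality ranking (top 5 kept, top 1 to the refinement hook) → hook
output pcSM-ranked (top ≤ 10) → merge with the quality top 5,
de-duplicated by id (a refined model that duplicates an unrefined one
structurally but not by id survives alongside it) → pcSM re-rank → final
≤ 5. The refinement hook defaults to the identity: the published
refinement stage (quantum-chemical bond-angle optimization, side-chain
rebuilding, force-field minimization) requires external engines, so the
hook contract — pool in, pool out, same sequence — lets users attach any
refiner. Likewise, no energy minimization is performed before scoring;
the clash report is attached to the selection report instead.

## Evaluation

`evaluate()` follows CASP practice: the model and native sequences are
globally aligned (Needleman–Wunsch, BLOSUM62, gap open 10 / extend 0.5 —
for two sequences this is equivalent to the progressive aligners used
interactively), aligned pairs where either side lacks a Cα are dropped so
the compared coordinate sets match exactly, and Cα RMSD and TM-score are
computed over the mapping. The TM-score is normalized by the *native*
length with d0 = 1.24·(L−15)^⅓ − 1.8, floored at 0.5 Å. The
superposition search seeds from contiguous fragments of lengths L, L/2
and L/4 (minimum 4) at every start, each refined by iterating
"superpose on pairs within the cutoff" (start at max(d0+1, 4.5) Å,
shrink by 0.5 Å while fewer than 3 pairs qualify, at most 20 iterations)
to a fixed point; the best score over all visited superpositions is
reported. This matches an exhaustive-seed oracle to < 0.005 in the test
suite. Kabsch superposition uses SVD with determinant sign correction, so
mirror images are never superposed away.

`summarize_targets()` takes the best of each target's ≤ 5 predictions and
reports the fraction of targets at TM ≥ 0.5 (the conventional same-fold
threshold) and Cα RMSD ≤ 5 Å, both inclusive.

## The synthetic benchmark

`make_toy()` builds ideal chains (full backbone + Cβ, ideal bond
geometry; helix φ/ψ = −57°/−47°, strand −120°/130°, turns/loops −90°/0°)
in three topologies; `perturb()` adds i.i.d. Gaussian Cartesian noise per
coordinate plus a random rigid transform, recording each decoy's true Cα
RMSD; `make_benchmark()` assembles multi-target suites (topologies
cycled, lengths drawn from 30–80 residues, the unperturbed native always
included under id `"native"`, predicted secondary structure taken from
the native — a best-case prediction). Defaults are a 5-rung noise ladder
σ ∈ {0.5, 1, 2, 4, 6} Å with 100 decoys per rung.

Cartesian noise was chosen over dihedral sampling deliberately: it yields
a controllable, monotone RMSD ladder and degrades compactness, surface
area and local geometry *together*, so pcSM enrichment on these pools is
a meaningful (if easier-than-life) test. What the generator does **not**
emulate: physically plausible decoys with native-like local geometry but
wrong topology, template-biased error structure, missing loops ‒ the
failure modes that make real decoy discrimination hard. Passing the
synthetic acceptance tests therefore demonstrates internal correctness
and sane behaviour of the selection machinery, not benchmark-grade
accuracy on real prediction targets.

## Numerical choices and degenerate inputs

* Superposition requires ≥ 3 non-collinear points; collinear input is an
  error. Singular-value ties leave the RMSD (the quantity used
  everywhere) unambiguous.
* Ties in every ranking are broken by input order (stable sorts); ties in
  representative picking by id order.
* Altloc records resolve to the highest occupancy, then alphabetically;
  HETATM and waters are skipped; elements are inferred from atom names
  when the element column is blank; nonstandard residues read as `"X"`
  and score as mismatches in alignment.
* `tm_score()` is exactly 1 for a self-comparison; an empty predicted
  class gives a zero penalty (PH/PS); chains under 3 residues assign as
  all-coil.
* Test and acceptance problem sizes: toys of 12–80 residues, pools of
  40–500 decoys, a 10-target × 501-decoy benchmark for the end-to-end
  check — small enough to run in minutes, large enough that clustering,
  ranking and evaluation all operate in their intended regimes.

## Known limitations

Single-chain monomers only (no mmCIF, nucleic acids, or complexes). The
quality module is a stand-in, not a meta-server reproduction. The
empirical-potential-energy descriptor sometimes listed alongside the
seven pcSM parameters has no printed coefficient and is not part of CS;
it is omitted here. Coefficients are taken as given — no re-optimization
is attempted — and the synthetic generator's noise model is a fixture,
not a physical decoy model.
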