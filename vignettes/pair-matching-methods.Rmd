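---
title: "Pair-matching bilateral bones by mesh-to-mesh value comparison: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair-matching bilateral bones by mesh-to-mesh value comparison: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteopair)
```

## The model

`osteopair` treats pair-matching as a surface-registration problem.  Left
and right antimeres of one individual are, to a good approximation, mirror
images of each other separated only by bilateral asymmetry — a smooth,
sub-millimetre shape difference.  Elements from *different* individuals
differ by the full between-individual variation in size and shape, which is
typically an order of magnitude larger.  Mirror one side, rigidly register
every candidate pair, and the residual surface difference — the
mesh-to-mesh value, in mm — separates true pairs from false ones whenever
that scale gap exists.  No landmarks, no measurements, no assumptions about
sex, population or chronology enter the comparison.

Three assumptions matter:

* **Rigid comparison.**  Only rotations and translations are allowed; size
  is part of the signal (two humeri differing mainly in length are not a
  pair), so no scaling or affine freedom is given to the optimiser.
* **Units are millimetres**, taken verbatim from the mesh files; nothing is
  inferred or rescaled.
* **Surfaces are reasonably complete.**  Fragmentation and taphonomic
  damage are outside the current scope; the `overlap_fraction` trimming
  knob exists for such work but defaults to 1 (no trimming).

## The registration procedure

Every candidate pair is aligned by a two-stage iterative closest point
(ICP) procedure whose default settings mirror an established automated
comparison protocol:

| parameter | default | meaning |
|---|---|---|
| `n_initial_positions` | 20 | rough-alignment starting orientations |
| `rough_sampling` | 0.01 | fraction of source vertices in the rough stage |
| rough metric / NN | point-to-point, approximate (eps = 0.1) | |
| `rough_iterations` | 100 | cap per start |
| `fine_sampling` | 1.0 | all vertices in the fine stage |
| fine metric / NN | point-to-plane, exact + normal compatibility | |
| `fine_iterations` | 100 | cap |
| `normal_angle_max` | 45 deg | correspondence rejection threshold |
| `overlap_fraction` | 1.0 | residual trimming (1 = none) |
| `convergence_tol` | 1e-7 mm | early stop on RMS change |

Choices the protocol leaves open, and what this package does:

* **Starting orientations.**  The 20 starts are constructed
  deterministically: principal-axes alignment, composed with the four
  proper axis-flips (the 180-degree ambiguities of an elongated bone), then
  quasi-uniform rotations from a Halton-sequence quaternion fill.  This
  covers the flip failure modes of long bones without randomness.
* **Winner selection.**  Each start optimises on a fixed, seeded 1 %
  subsample, but ~20 points cannot reliably *rank* the candidates — in
  particular they can prefer an end-for-end flip when an individual's two
  epiphyses happen to be similar in size.  The winner is therefore the
  candidate whose final transform has the lowest RMS residual re-evaluated
  over **all** source vertices with exact nearest neighbours (one extra NN
  pass per candidate).  The per-start optimisation itself still follows
  the 1 % / approximate-NN / point-to-point protocol.
* **"Approximate (fast)" nearest neighbours** are realised as a
  (1+eps)-approximate KD-tree query with eps = 0.1.  Exactness before the
  fine stage is irrelevant; the approximation only has to be good enough to
  steer the rough optimiser.
* **Degenerate geometry.**  The point-to-plane update solves a 6-unknown
  linearised system by truncated SVD.  Directions the current
  correspondences do not constrain are frozen at zero rather than
  extrapolated — this is what lets two concentric spheres register (their
  rotations are unobservable but harmless).  The exposed estimator
  `estimate_rigid_point_to_plane()` errors only when a *translation* is
  unconstrained (e.g. all normals parallel), naming the motion.
* **Convergence.**  The stated protocol caps iterations at 100; a
  `convergence_tol` of 1e-7 mm on the change in RMS residual stops earlier
  when the registration has settled.  The rough stage's residual trace is
  recorded from the distances the optimiser actually used (approximate NN);
  the classic nonincreasing-objective guarantee of point-to-point ICP holds
  for exact-NN runs and is asserted in the test suite for those.
* **Sampling.**  The 1 % rough subsample is drawn once per run (seeded),
  not re-drawn per iteration, so runs are exactly reproducible.

## The mesh-to-mesh value

A registration is summarised as the symmetric RMS of exact
**point-to-surface** distances: for every vertex of each mesh, the distance
to the nearest point on any triangle of the other mesh (an exact
point-to-triangle computation with KD-tree pruning), squared, pooled over
both directions, averaged, rooted.  This choice has three properties the
matching rule relies on: it is symmetric in its arguments, it is zero
exactly when the surfaces coincide, and it is expressed in mm.

Why point-to-*surface* rather than point-to-*vertex*: at desk-scale mesh
resolutions (~2000 vertices on a ~300 mm bone the vertex spacing is 2-5 mm)
a nearest-vertex distance is dominated by the sampling grid as soon as the
two vertex sets slide off each other, drowning sub-millimetre asymmetry
signals; distances to the continuous surface remove that floor.  Dense
scans of real bones make the two nearly identical, which is why tools
operating on them can use either.  ICP *correspondences* remain
vertex-to-vertex (the `correspondence` convention of the protocol); the
value deliberately characterises the surfaces, not the optimiser.

The registration direction is canonicalised (the mesh whose id sorts first
moves) so that `value(A, B)` and `value(B, A)` are bit-identical; the
metric itself is symmetric either way.  Alternative summaries
(`mean_absolute`, `hausdorff`, `one_directional`) are available through
`alignment_settings(value_metric = ...)` for sensitivity analyses.

A failed registration (all correspondences rejected) marks its matrix cell
`NA` — a diagnostic, never silently imputed as "very different".

## Matching and scoring

The declaration rule is **mutual best**: (L, R) is a pair iff each is the
other's single lowest-value candidate.  Agreement lower in the top-3 lists
is *not* sufficient — the classic confusion (left A points to right B, but
right B points to left C) declares nothing for any of the three; the top-3
lists are retained in the report so an analyst can audit such conflicts.
Exact value ties are treated conservatively (no pair, warning); a looser
`agreement = "topk"` mode implements the within-top-k reading for
comparison.  Mutual best needs no global assignment solver, and every bone
ends in at most one pair by construction.

Scoring is **per bone**, not per pair: each bone in a correctly declared
pair counts TP; each true singleton declared single counts TN; each bone
placed in a wrong pair counts FP even if it has a true mate elsewhere; each
truly paired bone left single — including one whose mate was stolen by a
wrong pair — counts FN.  With 21 pairs and 3 singletons, one wrong pair
drawing bones from two different true pairs therefore scores exactly
TP = 38, FN = 2, FP = 2, TN = 3 (sensitivity 95 %, specificity 60 %), and a
perfect result scores 42/0/0/3 (100 %/100 %).  A swap among two true pairs
counts all four bones FP; this reading is asserted in the test suite.
Sensitivity or specificity with a zero denominator is reported `n/a`, not
0, to distinguish "nothing to detect" from failure.

The mean + 2 SD **threshold analysis** computes the sample mean and SD
(n-1) of the true-pair values and counts how many true-pair and non-pair
cells fall at or below `mean + 2 sd`.  On well-separated populations the
non-pair count is zero; once the distributions overlap it grows — the
quantitative form of the finding that a single global cutoff cannot replace
the matrix rule.

## The synthetic population generator

No scan collections are deposited with the method, so validation uses a
procedural stand-in.  `generate_bone()` builds a closed, watertight
tube-with-epiphyses: a bowed shaft (length ~300 mm, radius ~10 mm), two
enlarged ends with opposite eccentricities, and a low-order radial
modulation field.  `generate_population()` draws per-individual shape
parameters (at `individual_variation = 1` the 2-sigma length range is
roughly 280-320 mm), generates the right side, then builds the left as the
mirror image of the same surface displaced along its normals by a smooth
low-order field scaled to `asymmetry_mm` RMS (default 0.3 mm) plus
per-vertex jitter (`surface_noise_mm`, default 0.05 mm); every mesh is
finally re-posed by a uniform random rotation and translation.  Defaults
were chosen once so that true-pair values land in the sub-millimetre range
reported for real humeri while between-individual differences sit several
times higher.

What this emulates — and what it does not.  The generator reproduces the
*relative scales* that make pair-matching work: small smooth within-pair
asymmetry against large between-individual variation, plus arbitrary
initial poses and the presence of singletons.  It does not reproduce
anatomical detail (muscle attachment sites, cortical texture), scan
artefacts (holes, topological noise), fragmentation, or taphonomy.  A
perfect score on these populations therefore demonstrates that the
pipeline recovers planted structure under the stated scale separation — it
does not certify performance on real scan data, where surface quality and
pathology can erode the separation.

Problem sizes used in the shipped tests and acceptance script: populations
of 10 pairs + 3 singletons at ~2000 vertices per mesh for the end-to-end
recovery runs, with coarser ~600-vertex meshes for unit-level properties;
the full planted-truth check repeats the pipeline over 20 seeds.

## Numerical choices and edge cases

* STL facet-vertices are welded at 1e-8 x bounding-box diagonal; welding is
  idempotent and OBJ round-trips preserve coordinates to 1e-6 mm.
* Vertex normals are area-weighted averages of incident face normals;
  isolated vertices get zero normals, are flagged, and are exempt from
  normal-compatibility tests.
* Mirroring reverses face winding so normals remain outward; the mirror
  plane (yz by default) is irrelevant downstream because registration is
  invariant to rigid motion.
* Per-cell seeds in `compare_all()` derive deterministically from the
  global seed and the two ids, so any cell can be recomputed in isolation
  and results are independent of evaluation order.
* Exact ties in the matcher declare no pair and warn; ties are measure-zero
  on real data but can occur in constructed matrices.
* Scoring requires truth to cover every id in the report (error otherwise);
  truth bones absent from the report are ignored.

## Known limitations

* Vertex-correspondence ICP on very coarse meshes can bias the registration
  by a fraction of the vertex spacing; the surface-based value compensates
  at evaluation time but the transform itself inherits the optimiser's
  resolution.
* The mutual-best rule is deliberately conservative: in a population where
  two individuals are nearly identical it will declare singletons rather
  than guess, trading sensitivity for specificity.
* Fragmented or partial elements need `overlap_fraction < 1` and have not
  been validated here.
* The generator's shape family is not an anatomical atlas; conclusions
  about absolute mm thresholds on real material should come from real
  scans.
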