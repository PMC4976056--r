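# osteopair

Pair-matching of bilateral skeletal elements from 3D surface meshes by
mesh-to-mesh value comparison (MVC).

## The problem

When skeletal remains from several individuals are commingled — mass graves,
disasters, ossuaries — re-individualization starts by re-associating paired
elements: which left humerus belongs with which right humerus?  Classical
approaches (visual matching, osteometric comparison, geometric
morphometrics) either depend on observer experience, on landmarking, or
cannot handle elements whose true mate is absent.  `osteopair` implements the
mesh-to-mesh value comparison approach for digitised bones: compare the
*entire* surface geometry of every left-right candidate pair and summarise
each comparison as one number in millimetres.

## The method

For a set of left elements and a set of right elements (as triangle meshes
in mm, from OBJ/STL/PLY files):

1. **Mirror** every right element (reflection with winding flip, so normals
   stay outward), making left and right directly superimposable.
2. **Register** every left x mirrored-right pair rigidly by two-stage ICP:
   - *rough*: 20 starting orientations (principal-axes alignment, its
     axis-flip group, quasi-uniform fill), point-to-point ICP on a 1 %
     vertex subsample with approximate (1+0.1) nearest neighbours, up to
     100 iterations per start; the winner is the candidate whose final
     transform has the lowest exact-NN residual over all vertices;
   - *fine*: point-to-plane ICP at 100 % sampling with exact nearest
     neighbours, correspondences rejected when surface normals disagree by
     more than 45 degrees, up to 100 iterations; estimated overlap is 100 %
     (no residual trimming) by default.
3. **Summarise** each registration as the mesh-to-mesh value: the symmetric
   RMS of exact point-to-surface distances pooled over both directions,

   `MVC(A, B) = sqrt( (1 / (nA + nB)) * ( sum_i d(a_i, surf B)^2 + sum_j d(b_j, surf A)^2 ) )`

   Lower = more similar; 0 iff the surfaces coincide.
4. **Declare pairs** by the mutual-best rule on the left x right comparison
   matrix: (L, R) is a pair iff R is L's lowest-value candidate *and* L is
   R's lowest-value candidate.  Everything else is a singleton; each bone's
   three lowest-value candidates are kept as evidence.
5. **Score** against known truth per bone: sensitivity = TP/(TP+FN),
   specificity = TN/(TN+FP), where a bone in a correct pair is a TP, a true
   singleton left single is a TN, any bone in a wrong pair is an FP, and a
   truly paired bone left single is an FN.

A `mean + 2 SD` threshold analysis of the true-pair values
(`threshold_analysis()`) quantifies why a single global cutoff is a poor
substitute for the matrix rule, and `deviation_map()` produces the
colour-band style per-vertex comparison (within / larger / smaller than a
band half-width, default 0.645 mm).

Because no public scan collections accompany the method, the package ships
a seeded generator of long-bone-like populations (`generate_population()`)
with controlled between-individual variation, within-pair bilateral
asymmetry (default 0.3 mm RMS), surface noise and random initial poses, so
the full pipeline is testable end to end against planted truth.

## Worked example

```r
library(osteopair)

pop <- generate_population(population_config(
  n_pairs = 10, n_left_singletons = 2, n_right_singletons = 1, seed = 101))
cm  <- compare_all(pop$lefts, pop$rights, alignment_settings(seed = 101))
rep <- mutual_match(cm)
score_matches(rep, pop$truth)
#> |                 |       |
#> |-----------------|-------|
#> | True positives  | 20 |
#> | False negatives | 0 |
#> | False positives | 0 |
#> | True negatives  | 3 |
#> | Sensitivity     | 100 % |
#> | Specificity     | 100 % |
threshold_analysis(cm, pop$truth)
#> threshold_analysis: true-pair mean 0.249 mm, SD 0.028 mm
#>   cutoff (mean + 2 SD): 0.306 mm
#>   true-pair values captured: 10 of 10
#>   non-pair values below cutoff: 0
```

All 20 truly paired bones are re-associated and the three singletons left
unmatched.  True-pair values sit near the planted 0.3 mm bilateral
asymmetry, far below the smallest between-individual value (here 0.70 mm),
which is what makes the mutual-best rule exact on this population.

The same pipeline is scriptable from a shell via the thin CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/mvc.R", package="osteopair"))') \
  simulate --out meshes --pairs 10 --seed 101
# then: compare, match, evaluate, deviation (see the script header)
```

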