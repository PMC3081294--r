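---
title: "Voronoi interface models and collaborative re-ranking of docking poses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voronoi interface models and collaborative re-ranking of docking poses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voroscore)
```

## The problem

Rigid-body protein–protein docking produces thousands to millions of
candidate conformations; the scoring problem is to rank them so that a
near-native pose appears among the first few. `voroscore` implements a
complete coarse-grain ranking stack built around a Voronoi model of the
protein–protein interface:

1. a **coarse structure model** — one node per residue at the geometric
   center of the side-chain heavy atoms plus the Cα (glycine: Cα alone);
2. a **Voronoi/Delaunay tessellation** of the node cloud, from which
   neighborhood, cell volumes, interface residues and the Voronoi
   interface area are read off;
3. a **pose generator** that pairs surface pseudo-normal vectors of the
   two partners and spins the ligand about the common axis;
4. a **96-attribute interface descriptor** with explicit missing-value
   semantics;
5. a **scoring function trained by a (μ+λ) evolution strategy** that
   maximizes ROC AUC, cross-validated at complex level and aggregated by
   rank sums over repeated runs;
6. a **collaborative-filtering (CF) layer** of binary classifiers whose
   precision-weighted votes re-rank (or pre-filter) the candidates;
7. **CAPRI-style evaluation**: fnat, interface RMSD, ligand RMSD, quality
   classes, enrichment, and per-target report tables.

Everything runs on synthetic fixtures generated in code, so the full
pipeline is testable without any database access.

## The coarse model and the tessellation

Each residue contributes one node (`load_partner()`); its mean residue
volume (Pontius-style Voronoi volumes, shipped as an editable TSV,
`volume_table()`) sets the radius used by the pose generator. Residues are
binned into six physico-chemical categories — hydrophobic (ILVM), aromatic
(FYW), small (AGSTCP), polar (NQ), positive (HKR), negative (DE) — which
drive all pair attributes.

`tessellate()` computes exact Voronoi cells by sequential half-space
clipping: each cell starts as a large cube and is clipped by the bisector
plane of every other point in nearness order, stopping when the next point
is farther than twice the largest vertex radius. Cells are tracked
combinatorially (each vertex is the meeting of three planes), so facet
polygons and volumes are exact up to floating point. The dual Delaunay
adjacency is read from the positive-area facets.

**Implicit solvent.** A Voronoi diagram of the two partners alone has
unbounded surface cells, and the facets between rim residues of the two
partners would extend arbitrarily far into empty space — any measured
"interface area" would then depend on how the diagram is truncated. We
therefore close the diagram with a *solvent blanket*: dummy points on a
body-frame grid kept where their distance to the nearest node falls in
[5, 10] Å (≈3.5 Å spacing), plus a distant sphere shell as a backstop.
The blanket plays the role of the water layer: it truncates surface and
rim facets at solvent distance, makes the measured interface area
independent of the outer shell radius (doubling the shell changes the area
of a compact complex by far less than 0.1%), and gives far-separated
partners an exactly empty interface. Because the blanket grid and the
shell are built in the cloud's principal-axis frame, the whole
construction is rigid-motion covariant, and tessellations of rotated
copies agree to ~1e−12 relative error. Dummy points never appear in
adjacency output or interface definitions; residues whose cells touch the
solvent are *not* pruned from the interface (they are flagged in
`$solvent`).

Degenerate inputs (duplicate or non-generic points) trigger one
deterministic jitter-and-retry (±5×10⁻⁴ Å, seed derived from the node
count) before failing.

## Pose generation

For each node, the vectors to its within-partner Delaunay neighbors are
summed and negated; a vector still pointing inward — negative dot product
with the node-minus-centroid direction, a star-convexity heuristic — is
flipped, and near-cancelling sums (deep interior nodes) are dropped. The
vector's length is the radius of the sphere holding the residue's mean
volume. On sphere-like test clouds these pseudo-normals track the outward
normal closely in the median (<30°), though individual vectors can tilt by
several tens of degrees — an inherent property of discrete neighbor sums,
which the pose enumeration tolerates because it tries all vector pairs.

`enumerate_poses()` translates the ligand so the two vector tips coincide,
rotates it so the vectors are exactly anti-parallel, and spins it about
the common axis every 5° (default), giving |U|·|V|·72 poses. The spin-zero
origin aligns the ligand's first principal axis projection with a fixed
reference perpendicular to the axis, making the stream byte-reproducible.
`build_decoy_set()` retains poses with interface area ≥ 400 Å² and
ligand-node RMSD > 10 Å from the native, then samples a fixed number per
native with a seed. The decoys-per-native default is 15 and is
configurable.

Note on scale: the 400 Å² floor is calibrated for real protein complexes.
The 15–40-residue toy complexes produced by `make_toy_complex()` have
interface areas of a few hundred Å² when docked face-to-face, but
vector-paired poses touch only tangentially (tens of Å²), so pipeline
demonstrations at toy scale use a proportionally lower floor.

## The 96-attribute descriptor

`featurize()` computes, over the *complete interface* (every residue with
at least one cross-partner Voronoi neighbor, both partners pooled):

| block | attributes | content |
|---|---|---|
| c1 | 1 | Voronoi interface area (Å²) |
| c2 | 1 | number of interface residues |
| c3–c22 | 20 | residue-type fractions (alphabetical by one-letter code) |
| c23–c42 | 20 | mean Voronoi cell volume per residue type (Å³) |
| c43–c63 | 21 | cross-pair fractions per category pair (row-major upper triangle) |
| c64–c84 | 21 | mean node–node distance per category pair (Å) |
| c85–c90 | 6 | category fractions |
| c91–c96 | 6 | mean cell volume per category (Å³) |

A value is *missing* (NA, mask true) exactly when its defining set is
empty — e.g. no polar:negative cross pair at this interface. Fractions are
taken over present entities, so the three fraction blocks each sum to 1 on
any non-empty interface. Missingness is a data-quality property, not a
value: scoring treats masked attributes as contributing zero, and
`assemble_learning_set()` drops decoys whose missing count exceeds twice
(configurable) that of their native, mirroring how sparse decoy interfaces
carry no usable signal.

The block-internal orderings (alphabetical types; the fixed category
order; row-major pairs) are a package convention — learning is
order-agnostic, but serialized models depend on it, so it is fixed and
documented here.

## The evolution-strategy scoring ensemble

`es_scoring()` fits the centered linear score

S(x) = Σᵢ wᵢ (xᵢ − cᵢ)   (over unmasked attributes)

by a (μ+λ) evolution strategy with training-fold ROC AUC (the rank /
Mann–Whitney formulation with average-rank ties) as fitness. Individuals
are (w, c, σ) with per-gene step sizes; children are produced by discrete
recombination of the genes and intermediate recombination of the step
sizes, then mutated by the standard log-normal self-adaptation rule
(τ = 1/√(2√d), τ′ = 1/√(2d), d = 192 genes) followed by Gaussian gene
mutation; survivor selection keeps the best μ of parents ∪ children, so
the best training fitness is non-decreasing by construction. Runs stop at
`generations` (default 500) or after `stagnation` generations without
improvement. An absolute-deviation variant Σ wᵢ|xᵢ − cᵢ| is available via
`form = "absdev"` for sensitivity checks.

Defaults μ = 10, λ = 70 follow the conventional 1:7 ES ratio; both are
configurable, as are the fold count (10) and the runs per fold (30).
Attributes are standardized internally (the exported weights and centers
are back-transformed to the raw scale, so serialized functions are
self-contained). Folds are assigned at *complex* level — all conformations
of a complex share a fold — so a native can never inform the scoring of
its own decoys; with a single complex the folds fall back to row level.

Because the ES is stochastic, the ensemble keeps all folds × runs
functions and `predict()` aggregates by rank sums: each function ranks the
candidates by descending score, and the final order is ascending in the
summed ranks (average-rank ties). On synthetic planted-signal sets the
variance of the aggregated held-out AUC decreases monotonically as more
runs are aggregated, which is why repeated runs are the default.

## The collaborative-filtering layer

`cf_ensemble()` fits a roster of binary classifiers (default: logistic
regression, SVM with RBF and quadratic kernels, CART trees with minimum
leaf sizes 2/5/10 under Gini and information splits, and binary-tree
variants with minimum cut sizes 2/5/10 — twelve learners spanning four
method families). The roster is data, not structure: any object obeying
the two-function `base_classifier()` contract plugs in. The classical
C4.5/RIPPER/PART rule learners have no direct counterpart in this
package's R dependency set; the tree variants stand in for them, which we
note as a substitution — the CF layer treats all base
learners as black boxes, so only the diversity of the roster matters.

Each classifier's precision TP/(TP+FP) is measured on cross-validated
held-out predictions only; classifiers below 0.5 (worse than random) are
discarded. Votes are fused three ways:

* **uniform**: rank by the number of + votes (k classifiers → k+1
  categories);
* **weighted**: rank by the category score S⁺ − S⁻, where S⁺ (S⁻) is the
  sum of the precisions of the classifiers voting + (−); with k distinct
  precisions the 2ᵏ vote patterns are distinguishable categories;
* **CF-GA fusion**: fused value = GA_rank × exp(S⁻ − S⁺), ranked
  ascending. A unanimous positive consensus multiplies the GA rank by
  exp(−Σpₖ) (the best possible factor); conformations with *only* negative
  votes take a maximal sentinel and occupy the last ranks in stable input
  order. This orientation — ascending-better with sentinel-worst — is the
  only reading under which all-negative conformations rank last, and the
  package fixes it as a documented convention.

`cf_then_ga()` implements the alternative composition (retain the best T
CF classes, rank them by GA); `granularity()` (distinct scores ÷ items)
quantifies how finely each method can order a set; and
`rmsd_diversity_filter()` greedily removes conformations within 5 Å
(default) of a better-ranked one, so the top of the list samples distinct
binding modes.

With the twelve precisions of the reference classifier table, some subset
*sums* collide (e.g. 0.650 + 0.645 = 0.665 + 0.630), so counting distinct
category *scores* gives slightly fewer than 2¹² categories; the package
therefore keys categories by the vote pattern and uses scores only for
ordering.

## Evaluation

`fnat()` is the fraction of the native's cross-partner residue contacts
reproduced by a pose. The default contact relation is a 5 Å node–node
distance cutoff (the field's atom-level convention transported to the
coarse model); a Voronoi-neighbor mode is provided as an alternative since
either relation is defensible on coarse nodes. `interface_and_ligand_rmsd()`
superposes by least squares (via bio3d) on the native-interface nodes
(i_rmsd) or the larger partner (l_rmsd); all RMSDs are coarse-node RMSDs —
the package never builds all-atom models, and reports flag this. Quality
classes come in two flavors: fnat-only thresholds (0.5/0.3/0.1) and the
standard three-measure CAPRI rules; the published rendering of the
Medium/Acceptable boolean clauses contains evident transcription slips, so
the package implements the standard criteria and documents the divergence
here. `class_contingency()`/`class_concordance()` compare the two schemes;
because every CAPRI tier requires at least the fnat floor of that tier,
the CAPRI class never exceeds the fnat-only class — the lower triangle of
the contingency is structurally empty.

`enrichment()` reports the ratio of the qualifying fraction in the best
(and worst) 20% of a ranking to the overall fraction; `rank_report()` and
`summarize_report()` build per-target tables (best class in the top 10,
top-10 hit count N, first-hit rank R) and their summary means, with
explicit target exclusions for first-hit means when a target's hits are
too deep to be meaningful.

## Synthetic fixtures, and what passing tests do and do not show

`make_toy_complex()` packs two clouds of residue nodes at ≥3.8 Å spacing
(the Cα–Cα distance of adjacent residues) and docks them along the line of
centers until a requested number of cross-partner contacts is planted; the
default of 20 contacts yields native interface areas of roughly 490–720 Å²
on 30-residue partners, comfortably above the 400 Å² floor the decoy
filter assumes. `make_planted_feature_set()` draws positives and negatives
from Gaussians differing only in a planted attribute subset, with
missingness planted per the learning-set semantics; at the default effect
size the reduced-budget ES (μ=5, λ=20, 50 generations, 3 runs, 3 folds)
recovers held-out ensemble AUCs above 0.95, and at effect size 0 it stays
near 0.5. `make_vote_fixture()` simulates classifiers whose + votes on
true positives follow their nominal precision-linked rates.

These fixtures emulate the *structure* of real learning sets — class
ratios, missingness, planted contact zones, a 1:15 native:decoy ratio —
but not real fold geometry, side-chain packing, or the contact statistics
of evolved interfaces. Passing tests therefore demonstrate that the
machinery is correct and internally consistent at desk scale; they do not
re-establish the published accuracy of this method on curated PDB
benchmarks, which depends on data this package deliberately does not
fetch. Quantities that are pure arithmetic on published tables (category
counts, concordance percentages, per-target summary means) are recomputed
exactly; learning-performance figures are reproduced only as trends on
synthetic data.

All problem sizes in the test-suite and acceptance script were chosen so
the full pipeline (generate → featurize → train → rank → evaluate) runs in
well under a minute per fixture on one CPU: 10–20-residue partners for
geometry-heavy paths, ≤48-node clouds for the brute-force Voronoi oracle,
and 20–30 complexes for learning checks.

## Numerical choices and degenerate inputs

* Geometric tolerances: facet areas below 10⁻⁷ Å² are treated as zero
  (non-adjacent); clip feasibility uses a 10⁻⁹-scaled tolerance; vertices
  are deduplicated at 10⁻⁷ Å.
* Ties in every ranking use average ranks; the CF-GA sentinel ranks after
  all finite values in stable input order.
* AUC requires both classes and errors otherwise; individuals with
  non-finite fitness are discarded by the ES selection.
* Classifier fitting imputes masked attributes at the training-set median
  (trees could split on NA, but the SVM/logistic members cannot); the ES
  path never imputes — masked terms contribute zero by the model's
  definition.
* `pseudo_normals()` drops vectors whose raw neighbor sum is below
  10⁻⁶ Å (symmetric interior nodes) with a warning.

## Known limitations

* Coarse nodes only: no all-atom contacts, hydrogens, or side-chain
  repacking; nucleic-acid chains are out of scope.
* The pose generator keeps the paired normals exactly anti-parallel; the
  angle between them is not sampled, so some near-native geometries are
  reachable only through neighboring vector pairs.
* The solvent blanket is implicit and geometric; explicit crystallographic
  waters are not modeled.
* Laguerre/power-diagram weighting of the tessellation is deliberately not
  implemented.
* Training assumes each complex contributes one native; CV with a single
  complex falls back to row-level folds and cannot hold out its only
  positive.
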