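---
title: "Quantitative cytoarchitectonics from soma contours: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative cytoarchitectonics from soma contours: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somamorph)
library(dplyr)
```

## The problem

Classical cytoarchitectonics distinguishes cortical regions and layers by
the size, shape and packing of neuronal cell bodies, but the classical
descriptions are qualitative. somamorph implements an objective version of
that workflow: starting from closed 2D contours of neuron somata (as drawn
on NeuN-immunolabeled sections), it computes ten standard shape
descriptors, assigns each cell to one of eight morphological types — either
by explicit threshold rules or by a supervised classifier with a
certainty-based reject option — and summarises the morphological
composition of each cortical region and layer.

Because suitable contour data sets are rarely public, the package also
contains a first-class synthetic-data generator that produces labeled soma
contours per morphological class and assembles whole cortical columns with
configurable laminar compositions. Every downstream stage is tested
against data from this generator.

## Morphometric descriptors

A contour is an implicitly closed, simple polygon with vertices in µm.
On construction (`contour_table()`, `read_contours()`) duplicate
consecutive vertices are removed (tolerance 1e-9 µm), simplicity is
verified by pairwise segment intersection (O(n²); soma contours have well
under a thousand vertices) and winding is normalized counterclockwise.
`compute_features()` then computes, per cell:

* **Perimeter** — edge-length sum, including the closing edge.
* **Area** — shoelace formula; polygons below 1e-9 µm² are rejected.
* **Feret Max / Feret Min** — the extreme caliper diameters. Feret Max is
  the largest vertex-pair distance of the convex hull. Feret Min is
  computed by rotating calipers: the minimum width of a convex polygon is
  attained flush against one of its edges, so the exact minimum is the
  smallest over hull edges of the maximal vertex distance to that edge's
  line. (An exhaustive 0.01°-direction sweep is kept in the test suite as
  an oracle, not used in production.)
* **Aspect Ratio** = Feret Max / Feret Min (≥ 1).
* **Compactness** = √(4·Area/π) / Feret Max — the diameter of the
  area-equivalent circle relative to the longest caliper diameter.
* **Roundness** = Compactness² = 4·Area/(π·Feret Max²).
* **Form Factor** = 4π·Area/Perimeter² (1 for a circle; the isoperimetric
  inequality bounds it by 1 for every simple polygon).
* **Convexity** = convex-hull perimeter / perimeter.
* **Solidity** = Area / convex-hull area.

Two conventions deserve comment, because vendor software glosses them
loosely. A "ratio between Area and Feret Max" is dimensionally
inconsistent with a Roundness that is its square and lies in (0, 1]; the
definition above is the convention that satisfies both constraints, and it
is the one this package uses. Likewise "Convexity" is defined here as the
perimeter ratio (the standard contour-indentation measure); the area ratio
is already Solidity.

All descriptors are rigid-motion invariant; under scaling by *s* the
lengths scale by *s*, Area by *s²*, and the five dimensionless descriptors
are unchanged. These invariances are enforced by property tests to 1e-9
relative tolerance.

## Threshold classification

`classify_cells()` applies a deterministic decision procedure with seven
thresholds (`ruleset()`; defaults are published ROC-derived values):

1. Form Factor < 0.79 **and** Solidity < 0.95 → *polymorphic*;
2. otherwise Aspect Ratio < 1.38 → *granule*;
3. otherwise Aspect Ratio < 1.86 → *pyramidal*, split by Area at
   202.2 µm² and 394.5 µm² into small / medium / large;
4. otherwise → *fusiform*, split by Area at 161.2 µm².

The polymorphic criterion is evaluated first because it is defined
against *all* other classes (irregular cells exist at any size or
elongation); a flag reverses this if wanted. Interval endpoints are
lower-inclusive/upper-exclusive — the published ranges are printed as
closed intervals without endpoint semantics, so a convention had to be
chosen; the choice is visible and tested. Every feature vector maps to
exactly one class, verified on 10⁵ random feature vectors.

`derive_ruleset()` re-derives all seven thresholds from labeled data by
ROC analysis of the binary contrasts (granule vs pyramidal and pyramidal
vs fusiform on Aspect Ratio, the size splits on Area, polymorphic vs all
on Form Factor, polymorphic vs fusiform on Solidity). Candidate
thresholds are the midpoints between adjacent distinct scores plus ±∞,
so sensitivities and specificities are exact counts. Selection targets
specificity ≥ 0.90 and maximizes sensitivity, breaking sensitivity ties
toward the highest specificity and then the smallest threshold; for
separable contrasts this lands in the middle of the class gap. When no
threshold reaches the specificity aim the selection falls back to
maximizing Youden's J and flags the result.

## Supervised classification with a reject option

`train_mlp()` fits a single-hidden-layer perceptron with softmax output
(`nnet`), the standard R incarnation of the multi-layer perceptron, on
z-score-standardized descriptors; hidden size (default 16), weight decay
(1e-3) and iteration cap (500) are exposed, and the random weight
initialization is seeded so training is exactly reproducible.
`predict_filtered()` implements the certainty filter: a cell is assigned
its maximum-probability class only when that probability reaches
`certainty_min` (default 0.5), otherwise it is excluded and later dropped
from composition denominators. Exclusion is monotone in `certainty_min`
by construction, and this is property-tested.

## Synthetic data

`generate_cell()` maps each class to a shape family: ellipse-like
(granule), rounded triangle — corner-cut smoothing of a slightly
asymmetric triangle (pyramidal sizes), tapered spindle — an ellipse
thinned toward the poles (fusiform sizes), and a radially perturbed
polygon with cosine-harmonic lobes (polymorphic). All families are
star-shaped about the origin, hence simple by construction; each contour
gets a random rotation and mild radial jitter.

Generation is calibrated to classification targets rather than to raw
microanatomical sizes: the classical height × width entries (granule
4–8 × 4–10 µm, small pyramidal 12 × 10, medium 25 × 15, large 30–45 ×
15–20, gigantic > 50 × 25, small fusiform 15 × 10, large fusiform
30 × 15) describe shape proportions, but the measured areas of real
NeuN-reconstructed somata are considerably larger, so each class draws a
target area from a truncated lognormal aligned with its rule region and
an elongation from its target Aspect Ratio range, and the contour is
rescaled exactly to the drawn area. A candidate is accepted only if its
*measured* descriptors classify to the generating class under the default
rules (for polymorphic cells, lobe depth is increased until Form Factor
< 0.79 and Solidity < 0.95); after 100 failed attempts generation errors
out. This rejection step is what makes ground-truth labels and the
classifier under test mutually consistent, which is the property the
round-trip and agreement suites rely on. Setting `target_area_range =
NULL` switches to literal height × width geometry. Gigantic pyramidal
cells can be generated but are absent from all default composition
profiles, mirroring a study sample that contained none.

`composition_profile()` encodes per region (BA9, BA14r, BA24) the
relative laminar thicknesses and per-layer class probabilities,
reflecting the reported qualitative patterns: layer I > 80% granule with
no medium/large pyramidal or large fusiform cells; pyramidal-dominated
layers III/V/VI; a large-pyramidal-rich layer III in BA9 (about 23% of
pyramidal cells, versus 3–7% elsewhere); smaller cells and very few
large pyramidal cells in BA14r; an excess of large fusiform cells in
layer V of BA24 (von Economo neuron territory) and more polymorphic
cells throughout BA24. Exact probability values are the package's own
defaults, chosen once to sum to 1 per layer; they are study-condition
stand-ins, not estimates of any real tissue sample.
`generate_column()` assigns cells to layers proportionally to thickness
and draws classes per layer.

`simulate_feature_table()` bypasses geometry: it draws the descriptors
directly from per-class truncated distributions centered inside each
class's rule region and truncated at the rule boundaries, deriving the
dependent descriptors (Perimeter from Form Factor and Area; Feret Max
from Area and Aspect Ratio with a small shape-inflation factor;
Roundness = Compactness²) so every row satisfies the descriptor
invariants. Because class supports adjoin the boundaries, ROC
re-derivation on these tables recovers the generating thresholds nearly
exactly — except the Form Factor threshold: fusiform Form Factor is
allowed below 0.79 (spindles genuinely have low Form Factor; only their
high Solidity keeps them out of the polymorphic region), so
polymorphic-vs-all on Form Factor alone is not separable and the
selected threshold sits a few percent below 0.79 at specificity 0.90.
This mirrors the published observation that Form Factor alone cannot
separate polymorphic from fusiform cells, which is why the Solidity
criterion exists.

### What passing tests do and do not show

The generator produces clean, single-cell, simple polygons whose
descriptor distributions are consistent with the classification rules by
construction. Real reconstructions carry segmentation noise, touching
cells, partial profiles at section boundaries, and class-boundary
ambiguity that no rule set resolves; classifier accuracies and exclusion
rates measured on synthetic data are therefore upper bounds, and the
composition-recovery tests validate the bookkeeping (sampling,
measurement, classification, renormalization), not biological truth.

## Statistics

* `descriptive_stats()`: n, mean, sample SD, t-based 95% CI for the
  mean, CV (100·SD/mean, %), median, type-7 IQR, mode after rounding to
  2 decimals (continuous data have no mode without discretization; 2
  decimals matches the reporting precision of the descriptor tables),
  min, max.
* `dagostino_pearson_k2()`: the omnibus K² test, implemented from the
  standard skewness (D'Agostino 1970) and kurtosis (Anscombe–Glynn 1983)
  normalizing transformations, p from χ²(2); requires n ≥ 20. A
  1,000-replicate simulation in the test suite confirms the 5% nominal
  size within ±2 percentage points.
* `kruskal_wallis_dunn()`: tie-corrected H (via `stats::kruskal.test`)
  with Dunn's pairwise z on pooled midranks, Bonferroni-adjusted by
  default (any `p.adjust` method available). For total n ≤ 10 the global
  p-value is computed from the exhaustive permutation distribution of H
  instead of the χ² approximation, which is unreliable at those sizes;
  both groupings of interest (regions pooled over layers, layers pooled
  over regions) are just different `group` columns.
* `chi_square_composition()`: Pearson X² without continuity correction
  on the stratum × class count table; errors when an expected count is
  below 1 and warns below 5.
* `factor_analysis()`: principal-component extraction from the
  correlation matrix (consistent with scree/eigenvalue-criterion usage;
  not maximum-likelihood FA), retention by eigenvalue > 1, varimax
  rotation (the standard orthogonal rotation behind a "rotated component
  matrix"); communalities are preserved by rotation to 1e-9 and factor
  signs are normalized so the dominant loading is positive.
* `tsne_embed()`: an exact O(n²) t-SNE (perplexity calibration by
  bisection, early exaggeration 12 for 100 iterations, momentum 0.5→0.8,
  learning rate 200, adaptive gains), deterministic per seed. Intended
  for up to a few thousand cells, which is the regime where a 2D map is
  readable anyway.

## Composition tables and displays

`build_composition()` counts predictions per stratum, removing excluded
cells from denominators while keeping their count; strata whose cells
were all excluded are flagged rather than silently dropped.
`ternary_coords()` collapses to the three principal classes (pyramidal
and fusiform subtypes summed) and renormalizes the triple to 1, so
polymorphic cells drop out of that display; `radar_coords()` keeps all
seven observed classes. `plot_ternary()`, `plot_radar()`, and the
`autoplot()` methods render these with ggplot2.

## Numerical choices and degenerate inputs

* Polygons: duplicate-vertex tolerance 1e-9 µm; degenerate area cutoff
  1e-9 µm²; collinear hulls (zero width) are rejected.
* ROC candidate thresholds strictly between observed scores make
  count-based sensitivity/specificity unambiguous at data values.
* Feature CSVs serialize doubles at 17 significant digits and re-parse
  through `strtod`, so round trips are bit-exact.
* Constant descriptor columns make rank correlations undefined; the
  offending column is named in the error.
* Zero-variance samples are rejected by the normality test and by
  Kruskal–Wallis ("H undefined").

## Problem sizes used in the checks

The shipped verification suites run at deliberately moderate sizes: 500
random polygons against the geometry oracles, 5,000 simulated rows per
class for threshold re-derivation, an MLP trained on 2,850 rows (the
size of the manually classified set in the motivating study) and tested
on 5,000–8,000, columns of 10,000 generated cells for composition
recovery, and 1,000 replicates of n = 5,000 for the normality-test
calibration. These sizes give binomial standard errors comfortably
inside the asserted tolerances.

## Known limitations

* No image processing: contours are taken as given; segmentation and
  contour extraction from micrographs are out of scope.
* 2D only; no 3D soma reconstruction.
* The MLP is a single-hidden-layer network; the reference toolchain's
  exact architecture and hyperparameters are unpublished, so agreement
  is defined against the rule classifier, not against any fitted model.
* Synthetic composition profiles are plausible encodings of reported
  patterns, not estimates; proportions derived from them should never be
  quoted as biology.
* Proprietary reconstruction formats (Neurolucida ASC/XML, ImageJ ROI)
  are not parsed; the JSONL contour format is the interchange point.
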