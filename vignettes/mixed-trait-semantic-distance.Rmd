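---
title: "Semantic distances for mixed, incomplete trait data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic distances for mixed, incomplete trait data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodist)
```

## The model

`phenodist` analyses individuals-by-variables trait tables in which most
variables are qualitative, the qualitative modalities carry real-world
structure, and many cells are missing. The core quantity is a semantic
distance between two individuals A and B:

$$D(A,B) = \frac{1}{\sum_{i\in M} w(i)} \sum_{i\in M} w(i)\, d_{A,B}(i)$$

where $M$ is the set of variables observed in *both* individuals, $w(i)$ a
non-negative per-variable weight (default 1, i.e. equal weights), and
$d_{A,B}(i)$ the per-variable distance: a lookup in the variable's
normalised modality distance matrix for qualitative variables, a
normalised absolute difference for quantitative ones. Missing data are
deliberately *ignored*, not imputed — in sparse phenotype collections
imputation fabricates trait values that experts never observed, while the
restriction to $M$ uses exactly the evidence available. The price is that
each pairwise distance rests on a different number of variables; the
cardinality $|M|$ is therefore carried alongside every distance and
surfaces in the visualisation (dot size) as a reliability cue. A pair with
$|M| = 0$ has no defined distance; this is a value, not an error, and the
embedding stage chooses a policy (abort, or impute the mean defined
distance — the default pipeline policy logs how many entries were filled).

### Where modality distances come from

* **Expert ontologies.** Small concept graphs (typically trees of a dozen
  concepts) whose unordered leaf pairs carry hand-assigned distances.
  On disk these are OWL RDF/XML files: concepts are `owl:Class` nodes,
  hierarchy is `rdfs:subClassOf`, and each expert distance is an annotated
  `has_distance` object-property assertion (an `owl:Axiom` block holding a
  real-valued `distance` literal). Pure OWL has no canonical way to attach
  a number to a relationship instance, so the reader is tolerant — it also
  accepts a reified `Distance` individual linking two concepts — while the
  writer always emits the annotated-assertion form. A CSV edge list
  (`concept_a,concept_b,distance`) is supported as a lightweight dialect;
  it cannot carry hierarchy, so only concepts and distances round-trip
  through it. Distances are unordered: files storing one triangle are
  mirrored automatically, and only a pair stored twice with *conflicting*
  values is an error, as is any negative value. An optional fallback can
  fill a missing leaf pair by summing annotated distances along the unique
  tree path; it is off by default because hand-tailored leaf-pair values
  are the reference semantics.
* **Colour tables** map modality labels to L\*a\*b\* coordinates. The
  default colour difference is the Euclidean ΔE in L\*a\*b\* space; the
  CIEDE2000 refinement is available as an opt-in (`method = "ciede2000"`).
  The Euclidean form is the default because it is the exactly testable
  definition and a true metric; CIEDE2000 weights lightness, chroma and
  hue perceptually but violates the triangle inequality, which the
  property tests therefore exempt.
* **Geographic tables** map region labels to latitude/longitude; distances
  are haversine great-circle distances on a sphere of radius 6371 km. A
  composite region (one with no single reference point) is located at the
  arithmetic mean latitude and longitude of its named sub-areas; longitude
  averaging has no wrap-around handling, a documented limitation for
  regions straddling ±180°.
* **Period tables** map period labels to integer year bounds
  $[S, E]$; the distance between two periods is
  $\lfloor |(S_1 + (E_1-S_1)/2) - (S_2 + (E_2-S_2)/2)| \rfloor$ — the
  floored gap between period midpoints. Open-ended labels are data, not
  code: the bundled table resolves "<1700" to (1600, 1700) and ">1920" to
  (1920, 2020).

### Normalisation

Raw per-variable scales are wildly different (unitless expert scores,
ΔE units, kilometres, years), so every modality matrix is max-scaled to
0–100: each entry is multiplied by $100/\max$. The minimum is always 0 (the
diagonal), so max-scaling is the simplest linear map onto the target range;
it fixes 0, preserves all ratios and orderings, leaves all-zero matrices
unchanged, and is idempotent. Quantitative variables have no modality
matrix; their pairwise absolute differences are rescaled at
individual-distance time so the largest *observed* difference maps to 100,
putting them on the same footing as the qualitative variables.

### The Gower-style comparison distance

For benchmarking, the package implements a Gower variant with the same
missing-data semantics: each qualitative variable is one-hot dummy-coded
with an extra missing indicator and contributes the Dice dissimilarity of
the dummy vectors (0 for a match, 1 for a mismatch), with pairs flagged by
the missing indicator masked out; quantitative variables contribute
Manhattan distances divided by the variable's observed range (a flag
restores raw Manhattan; range normalisation is the default because an
unscaled quantitative variable would otherwise dominate the per-variable
mean). The final distance is the element-wise mean over defined
per-variable entries. On complete all-qualitative data this reduces to
simple matching, and if every modality matrix is binary {0, 100} with
equal weights the semantic distance is exactly 100 times the Gower one —
both facts are exploited as test oracles. Pairs where both members are
missing on a variable are masked too (undefined), never silently counted
as agreement.

## Dimension reduction

* **PCoA** double-centres the squared distance matrix and
  eigendecomposes; coordinates are eigenvectors scaled by the square roots
  of the top-k positive eigenvalues. Negative eigenvalues (non-Euclidean
  input, which masked means readily produce) are reported for the scree
  plot but excluded from coordinates, with no Cailliez/Lingoes correction
  — the reported spectrum makes the non-Euclideanity visible instead of
  hiding it.
* **Metric MDS** minimises raw stress by SMACOF majorisation (Guttman
  transform). Defaults: 4 random Gaussian starts plus a classical-scaling
  start, 300 iterations, relative convergence tolerance 1e-6, all seeded;
  the lowest-stress configuration wins and the final Kruskal stress-1 is
  computed from it. The deterministic classical-scaling start makes the
  stress-by-dimension profile well behaved (non-increasing in k) and the
  whole operation bit-reproducible under a fixed seed.
* **Laplacian eigenmaps** build a Gaussian affinity
  $W_{ij}=\exp(-D_{ij}^2/2\sigma^2)$ with $\sigma$ = median off-diagonal
  distance — a parameter-light, scale-adaptive rule chosen because the
  affinity construction is otherwise unconstrained — and embed with the
  smallest non-trivial eigenvectors of the symmetric normalised Laplacian.
  The full spectrum is reported for the scree diagnostic. All-identical
  inputs yield a flat zero-variance embedding rather than an error.

**Choosing k.** Kruskal stress-1 (`stress1()`, with $\hat\delta$ the
Euclidean distances between coordinate rows) below 0.2 is the conventional
"good representation" bound; `select_dimensions()` either applies that
threshold (smallest k whose stress falls below it) or, by design, only
*reports* the stress/eigenvalue series: reading an eigenvalue elbow is a
judgement call, and automating it would invent a criterion the methodology
does not define.

## Clustering, concordance, archetypes

Clustering consumes the embedding coordinates (not the raw distance
matrix) because half of the supported algorithms require coordinates;
silhouettes are computed in the same space for coherence. Six algorithms
are exposed with contiguous 0-based labels, deterministic under the run
seed: k-means (`stats::kmeans`, 10 restarts), Ward (`hclust`/`ward.D2`),
k-medoids (PAM), Gaussian mixture (EM via mclust), spectral (the package's
Gaussian/median-bandwidth affinity, spectral embedding, then seeded
k-means — the same affinity rule as the eigenmaps, since no other setting
is prescribed), and BIRCH. The BIRCH implementation is a two-phase scheme:
a single pass condenses points into clustering features (count, linear
sum, squared sum) under a radius threshold (default 0.5), then Ward
agglomeration of the feature centroids produces the k clusters and points
inherit their feature's label; the CF-tree height optimisation is omitted
because at the package's target sizes the flat feature list is already
linear-time in practice.

Partitions are compared by concordance tables: entry (r, o) counts
individuals in reference cluster r and other-partition cluster o (rows =
reference, so row sums are reference cluster sizes). A greedy
diagonal-maximising row reorder is available purely for display. Mean
silhouettes over a k range guide the choice of cluster count; singleton
clusters get silhouette 0 by the common convention.

Archetypes declutter the final scatterplot matrix: `single_archetype()`
picks each cluster's member nearest its centroid (ties broken towards the
id that sorts first, for determinism), `multiple_archetypes()` samples
$\lceil 0.05\cdot\text{size}\rceil$ members per cluster uniformly without
replacement, with a floor of one so no cluster goes unrepresented — the
ceiling-with-floor rounding is the package's choice, as a bare "5%" has no
rounding rule. The dual-triangle scatterplot matrix places the full
population in the lower triangle (cluster colours from an 8-colour
colour-vision-deficiency-safe palette, alpha-blended dots whose size
increases strictly with the individual's missing-variable count) and the
archetypes plus per-cluster 2-D kernel density contours in the upper
triangle; densities use ggplot2's kde2d with the normal-reference (Scott
type) bandwidth, as no bandwidth is otherwise specified, and clusters with
fewer than three points or zero variance simply skip their contour layer.
The exact dot-size map is a strictly increasing linear ramp over a
configurable size range — any strictly monotone map satisfies the intent.

## The synthetic generator

Real reference collections of this kind are typically available only on
request, so the package ships a generative benchmark instead:
`default_synthetic_spec()` draws 300 individuals in 3 equal clusters over
four qualitative variables (backed by the bundled prickles ontology and
colour/geographic/period tables) and one quantitative variable, with 30%
of each variable missing completely at random. Each cluster's probability
mass sits on a small support of *related* modalities — e.g. one cluster
draws petal colour from the pink/red neighbourhood and origin from France,
another from yellow/orange and East Asia — so within-cluster variation
stays near the cluster profile while different clusters remain distinct;
quantitative cluster means are three standard deviations apart. A
`separation` knob interpolates the profiles towards the uniform
distribution and drives a power study: mean recovery (adjusted Rand index
over 20 seeds) must not decrease as separation grows.

What the generator does *not* emulate: structured (non-MCAR) missingness,
correlated variables, unbalanced modality frequencies, measurement error
in the expert distances, or any breeding-history realism. Passing the
recovery tests therefore shows the machinery is sound end to end — it does
not certify performance on observational data whose missingness is
informative.

## Numerical choices and degenerate inputs

* Text exports (CSV and the Excel XML workbook) print doubles with 17
  significant digits so re-reading reproduces values exactly.
* Matrix symmetry is enforced with tolerance 1e-8, zero diagonals 1e-12;
  PCoA treats eigenvalues above `1e-9 * max` as positive.
* An all-zero distance matrix errors in `stress1()` (division by zero) and
  in PCoA (no positive eigenvalue); silhouettes refuse fewer than three
  distinct coordinate rows.
* `k = 1` returns the trivial partition; `k = n` returns singletons when
  all points are distinct.
* One pipeline seed deterministically derives per-stage sub-seeds, so a
  config file plus its seed reproduces every numeric artifact
  bit-identically; figures may differ only in file metadata.

## Problem sizes

The test-suite benchmarks run at deliberately modest sizes — 300
individuals for end-to-end recovery, 90 for the separation power study,
n ≤ 20 for brute-force oracle comparisons, 100 points for the metric-MDS
stress summary — sizes at which every oracle can be computed exactly and
the whole suite stays interactive. The algorithms themselves are dense
O(n²) in memory like any distance-matrix workflow, and have been run
comfortably at a few thousand individuals.

## Known limitations

* Expert distances are powerful but subjective; eliciting consistent
  numeric values from domain experts is the method's main practical cost,
  and the package validates only their formal properties (symmetry,
  non-negativity, conflict-freedom), not their biological soundness.
* Undefined pairs (no shared observed variable) must be imputed or
  rejected before embedding; mean imputation is a blunt instrument and is
  logged whenever used.
* CIEDE2000 is not a metric; embeddings of colour-heavy datasets using it
  can be strongly non-Euclidean (watch the negative PCoA eigenvalues).
* Longitude averaging for composite regions ignores antimeridian wrap.
* Visualisations are static; there is no interactive display.
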