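---
title: "Quantifying microglial morphology and phagocytosis with microgliaMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial morphology and phagocytosis with microgliaMorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgliaMorph)
```

## The problem

Microglia, the resident immune cells of the brain, change shape as they
change state: a resting cell may be small and round, an activated one
hypertrophic and branched, an inflamed one swollen with enlarged
cytoplasm. In two-channel live imaging of neuron–glia cultures — a red
cytoplasmic reporter marking the microglia and a green nucleic-acid
stain marking debris from dying cells — two questions recur: *what
morphological population does each cell belong to*, and *how much debris
is each cell engulfing*. This package implements a complete pipeline for
both: segmentation of the reporter channel into per-cell label masks,
per-cell morphometry, classification into seven morphology classes
(round, inflamed ameboid, fried egg, inflamed fried egg, hypertrophic,
inflamed hypertrophic, bipolar), and phagocytosis quantification from
the debris channel of a time-lapse.

Because the interesting guarantees of such a pipeline are properties —
does segmentation recover cells it should recover, are derived features
exact functions of base features, does the classifier recover classes it
can see — the package ships a synthetic-data module that renders
parameterized cell archetypes and debris particles with complete ground
truth. Every downstream stage is validated against that ground truth.

## Segmentation

`segmentFrame()` runs three steps, each exposed separately:

* **Smoothing** (`anisoDiffuse()`): Perona–Malik anisotropic diffusion
  with conductance `g(s) = exp(-(s/K)^2)`, explicit four-neighbour
  updates with time step 0.2 and reflecting boundaries. `K` (default 5
  intensity units) sets the gradient scale below which smoothing acts;
  cell outlines, whose contrast is far above `K`, are preserved while
  background noise is averaged away. Because fluxes are antisymmetric
  the filter conserves total intensity, which the tests check to 0.1%.
* **Relative thresholding** (`relativeThreshold()`): foreground is
  every pixel strictly above `factor ×` the background level. The
  reference point for "relative" has to be defined; we use the mode of
  the image histogram (refined as the median of the modal bin), which
  is a robust background estimate whenever background dominates the
  field, as it does at typical microglia densities. The default factor
  is 1.5.
* **Labeling and filtering** (`labelAndFilter()`): 8-connected
  components, labelled 1..K in raster-scan order of their first pixel
  (a bit-reproducible convention), then filtered: components smaller
  than 200 µm² are discarded (debris, fragments), and components whose
  total skeleton length exceeds 450 µm are discarded (merged clumps and
  strands that cannot be a single cell). Whether "skeleton length"
  means the total or the longest branch is a genuine ambiguity in such
  filters, so `skeletonLengthMode` exposes both; the default is the
  total.

Manual mask curation is replaced by scripted, reproducible edit records
(`maskEditSplit()`, `maskEditMerge()`). A split polyline is rasterized
4-connected, which is the minimal digital line that actually severs an
8-connected component. Tracking (`trackMasks()`) links cells across
frames by greedy maximal overlap with a 20% minimum-overlap gate —
microglia move little between frames relative to their size, so overlap
linking is reliable; unmatched cells always receive fresh ids.

The default pixel size throughout is 0.758 µm, the lateral resolution
the pipeline was designed around; every function takes the pixel size
explicitly.

## Morphometry

`measureCells()` measures each label: area, convex area, perimeter,
moment-ellipse axis radii, geodesic diameter, largest inscribed circle
radius, the inscribed radius at the brightest pixel, skeleton
statistics, intensity summaries, centroid, and the count of pixels on
the image border. Pixel-grid measurements depend on conventions, so the
package states its own:

* **Perimeter** is the length of the 8-connected boundary chain of
  pixel centers (axial step 1, diagonal step √2), summed over the
  components of the label. Circularity inherits this convention.
* **Convex area** is the area of the convex hull of the pixel *squares*
  (not centers), so `Area ≤ ConvexArea` holds exactly and Solidity
  never exceeds 1.
* **Ellipse radii** are the semi-axes of the uniform best-fit ellipse
  from second-order moments, with the 1/12 single-pixel variance term
  so thin shapes have a nonzero short axis.
* **Geodesic diameter** is the exact maximum over boundary-pixel pairs
  of the shortest within-mask path, using axial/diagonal/knight steps
  (1, √2, √5). The knight steps keep the chamfer error against true
  Euclidean length below about 2%; knight moves require both stepping
  stones inside the mask so paths cannot tunnel through background.
* **Skeletons** are Zhang–Suen thinned; spur branches shorter than 6
  pixels are pruned (they are artifacts of jagged boundaries), and a
  *branch point* is a connected cluster of skeleton pixels with three
  or more neighbours. Thinning is direction-dependent, so skeleton
  features are computed in a canonical quarter-turn orientation chosen
  from the bitmap alone; together with the conventions above this makes
  every shape feature exactly invariant under integer translation and
  90° rotation, which the tests assert.
* **The brightest pixel** (for `RadiusAtBrightestPoint_Pixel`) is found
  on the raw intensity by default (a switch selects a 3×3-smoothed
  image); ties are resolved by the largest inscribed radius among the
  tied pixels, a rotation-invariant rule.

`deriveFeatures()` then computes the ten derived ratios exactly as
defined (Solidity, Roundness, Roundness2, GeodesicElongation,
AspectRatio, Circularity, Somaness, Branchiness, Straightness,
Thickness). Roundness is implemented literally as
`Area / EllipsoidLongestAxisRadius²`, without the π normalization of
the classical roundness index — the formula is the contract. Note one
consequence of taking the formulas literally: nine of the ten ratios
are dimensionless, but Branchiness (a count divided by a length) scales
inversely with physical length, which the tests document explicitly.
A zero denominator (for example, the skeleton of a small round cell can
degenerate to a point) yields `NA`, never 0.

`filterIncomplete()` drops cells whose border-contact pixel count is
*strictly above* 1% of their perimeter in pixels; a cell exactly at 1%
is retained.

## Classification

The classifier follows a metric-learning design: learn, from annotated
cells, a 2-D projection in which the classes separate; project all
cells; cluster the projection with a density clusterer that has a noise
class; give every cluster the majority class of its annotated members.

* **Embedding** (`fitEmbedding()`): features (base shape + derived, no
  intensity sums by default) are z-scored on the training cells and
  reduced by PCA (dropping numerically null directions — this absorbs
  the exact collinearity between base and derived features). The two
  embedding axes maximize the regularized discriminant criterion
  `W⁻¹B + αT` (between-class scatter ratio plus a small
  total-variance term, α = 0.05). With informative labels this is
  Fisher discriminant analysis; as label information vanishes it
  degrades gracefully to a principal-component projection, so the
  embedding keeps the unsupervised structure of the data instead of
  collapsing — the property that makes the permutation control behave
  (chance-level accuracy rather than degenerate output). The transform
  is linear, so projecting the training cells reproduces their training
  coordinates exactly and the model serializes losslessly.
* **Clustering** (`clusterEmbedding()`): density clustering with a
  noise class. Core points have at least `minPts` neighbours within
  `eps`; clusters are connected components of core points; border
  points join their nearest core; everything else is noise. `eps`
  defaults to the 95th percentile of the distance to the
  (minPts−1)-th neighbour, a data-driven scale at which only genuinely
  isolated points stay noise. Clusters below `minClusterSize`
  (default 10) are demoted to noise.
* **Voting** (`voteClusters()`): a cluster with a unique majority
  annotation labels all its members; clusters with tied majorities or
  no annotated member, and noise points, are `"unassigned"`. Ties are
  deliberately conservative — a wrong confident label is worse than an
  honest abstention.
* **Evaluation** (`crossValidate()`): stratified k-fold (default 5).
  Held-out cells are projected, clustered together with the training
  cells, and voted on. Three numbers are reported: accuracy over
  assigned cells, the unassigned fraction, and *recovery* (correct over
  all held-out cells, an unassigned cell counting as not recovered).
  Accuracy-over-assigned can stay high while assignment collapses, so
  recovery is the metric that degrades monotonically as class
  separation shrinks; the tests check exactly that.

## Phagocytosis

`phagoAnalysis()` quantifies debris engulfment in a two-channel
time-lapse given tracked cell masks. The particle channel is
auto-thresholded per frame — `autoThreshold()` implements Huang's
fuzzy-entropy minimization and the IsoData intermeans iteration on a
256-bin histogram; IsoData suits the punctate particle channel, Huang
the diffuse reporter channel. Each particle's host is the cell
overlapping *more than half* of its area (an exact 50/50 straddle has
no host); inside/outside areas therefore partition the total exactly.
Particles are linked over frames by nearest centroid with a step limit
of one particle diameter.

A tracked particle is a **confirmed engulfment** iff it moves with its
host cell (per-frame deviation within `coMoveTol`, default 2 px; the
pipeline configuration uses 3 px to absorb the centroid shifts of
shrinking particles) and its area decreases by at least `minShrink`
(default 10%) over the window. Thresholding a noisy field also yields
single-pixel speckles in the particle channel; a minimum particle area
(default 2 µm², the analogue of the minimum cell size) removes them. The third published confirmation cue — visible phagosome
pouches — is inherently visual; the package does not pretend to
automate it and instead flags every confirmed event `needs_review`.

The summary statistics are: the phagocytosis index
`[100 × (debris area inside microglia / total debris area)] / n
microglia`, the percentage of microglia containing at least one
confirmed particle, and the signed debris-area change between two named
frames (reported as-is, negative values meaning net clearance).

## The synthetic-data module

`renderCell()` draws a cell as a soma ellipse plus capsule processes
with optional side branches, in continuous micrometre coordinates
sampled at pixel centers — identical specs and seeds are
bit-reproducible. The seven archetypes are this package's own
quantitative construction (the morphology classes themselves are
qualitative); the defaults were chosen once, with three constraints:
classes must be pairwise separable in derived-feature space, the
inflamed variants must follow their cognates (soma area ×2; for
inflamed hypertrophic also process length ×2 and two extra branch
points), and every archetype must pass the default segmentation
filters (which is why hypertrophic processes are 20 µm and inflamed
ones 40 µm — five 40 µm processes with branches sit comfortably under
the 450 µm skeleton cap, where 50 µm ones would not). Within-field
variation comes from seeded multiplicative jitter.

Two caveats the synthetic data cannot cover: rendered cells are cleaner
than real ones (no intensity texture, no touching cells unless
requested, additive Gaussian noise on a constant background rather than
real camera noise), and `syntheticFeatureTable()` — used for classifier
stress tests — samples feature vectors log-normally around rendered
archetype centroids rather than rendering every cell, so its rows are
not geometrically consistent records (its derived columns *are* exact
functions of its base columns, by construction). Passing tests on
synthetic data therefore demonstrates correctness of the algorithms and
their contracts, not performance on any particular real culture.

One semantic note: a rendered multi-process cell's skeleton genuinely
contains junctions where processes radiate from the soma, so the
measured `SkeletonNumBranchPoints` of, say, a hypertrophic archetype
exceeds its `branchPoints` parameter (which counts only side
branches). The generator's ground truth for branch counting is
validated against an independent thinning oracle in the tests rather
than against the parameter.

## Numerical and design choices

* Background estimation for the relative threshold: histogram mode, not
  mean or median — correct whenever background dominates; a flat image
  yields an empty foreground with a warning.
* Labels, cluster ids and split pieces are always assigned in
  deterministic raster/first-occurrence order; the whole pipeline is a
  pure function of its configuration and seed, and `runPipeline()`
  reruns byte-identically.
* The chi-squared composition comparison is Pearson's statistic on the
  2×C count table with df = C−1; classes empty in both groups carry no
  information and are pooled out (and reported). Pairwise comparisons
  against a control adjust p-values with Benjamini–Hochberg.
* Problem sizes used by the validation suite — ten-cell fields for
  segmentation recovery, 50 cells per class for cross-validation,
  four-frame time-lapses for engulfment — were chosen as the smallest
  sizes at which the properties under test are meaningfully exercised.

## A worked example

```{r example, eval = FALSE}
library(microgliaMorph)

# a synthetic field with all seven archetypes and debris particles
fs <- demoFieldSpec(n = 14, seed = 1, noiseSd = 1,
                    nFreeParticles = 2, nEngulfed = 3)
tl <- renderTimelapse(fs, nFrames = 3, motion = c(2, 0), shrinkRate = 0.2)

# segment and track
cfg <- segmentationConfig()
masks <- trackMasks(lapply(tl$fields, segmentFrame, config = cfg))

# measure and classify
rec <- deriveFeatures(measureCells(masks[[1]], redChannel(tl$fields[[1]]),
                                   pixelSize(tl$fields[[1]])))
rec <- filterIncomplete(rec)

# phagocytosis
pa <- phagoAnalysis(tl$fields, masks)
pa$report

# or everything at once, reproducibly
res <- runPipeline(list(pixelSize = 0.758, seed = 1,
                        outDir = "out"))
res$composition
```

## Known limitations

* 2-D only: z-stacks are maximum-projected before analysis.
* The embedding is linear; morphology manifolds with strongly
  non-linear class boundaries would need a non-linear metric learner in
  its place (the module contract would not change).
* Overlap tracking assumes displacements small relative to cell size;
  fast-moving cells at low frame rates would need motion-model
  tracking.
* The engulfment confirmation automates two of the three published
  criteria; the phagosome-pouch criterion remains a human check, which
  is why confirmed events carry `needs_review`.
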