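---
title: "Trabecular bone network analysis: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trabecular bone network analysis: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabnet)
```

# The problem

Trabecular bone in the femoral head is a lattice of struts (trabeculae) whose
architecture reorganizes in hip osteoarthritis: struts thicken, structures
compress, and the lattice fragments. Conventional morphometry (bone volume
fraction, mean trabecular thickness and separation) summarizes this per
volume and misses how connectivity changes. `trabnet` treats each micro-CT
slice as a spatial graph — junctions and strut endpoints are vertices, traced
trabecular ridges are edges — and quantifies architecture with graph
statistics, depth-resolved profiles, and a classification experiment that
asks whether the extracted network is a better input representation than the
raw image.

# Extraction pipeline

A slice passes through six deterministic stages:

1. **Read** (`readSlice`): 8/16-bit TIFF or PNG rescaled to [0, 1]; RGB
   converted by ITU-R BT.709 luminance.
2. **Adjust** (`adjustIntensity`): linear contrast stretch between the 1st
   and 99th intensity percentiles (defaults), clipped. Degenerate constant
   images pass through with a warning.
3. **Binarize** (`binarize`): explicit threshold, or Otsu's between-class
   variance criterion at 256 bins — the standard choice for the bimodal
   bone/marrow histogram of micro-CT. A manual override is always available.
4. **Clean** (`cleanMask`): drop 8-connected foreground objects under
   `minObjectPx` and fill 4-connected background holes under `minHolePx`
   (both default 20 px; at 20.5 um pixels that is ~0.008 mm^2, below one
   trabecular width, i.e. scanner speckle rather than anatomy). Foreground
   uses 8-connectivity, background 4-connectivity (the standard duality).
5. **Thin** (`skeletonize`): sequential deletion of simple points (Yokoi
   connectivity number 1) that are not endpoints, in four directional
   subiterations until stable. Every deletion is individually topology-safe,
   so the 8-connected component count is preserved exactly — a property the
   component statistics downstream depend on. Endpoints are protected so arm
   lengths survive. Residual 2x2 blocks can remain only where removing any
   member pixel would change topology; such blocks are junction clusters and
   are merged into single vertices in the next stage, so no count is
   inflated.
6. **Graph** (`detectNodes`, `traceEdges`): skeleton pixels are classified
   by 8-neighbor count (1 endpoint, 2 ridge, >= 3 junction); 8-connected
   junction clusters merge into one vertex at their centroid; ridges are
   walked pixel-by-pixel from node to node, each ridge pixel assigned to
   exactly one edge. Edge length is the chamfer arc length (1 per lateral
   step, sqrt(2) per diagonal, times the pixel size): the length of a curved
   trabecula is its arc length, not its endpoint distance. Isolated pixel
   cycles become a self-loop on a synthetic degree-2 "anchor" vertex, which
   keeps both pixel conservation and component counts exact.

Degenerate inputs are handled explicitly: constant images binarize to an
empty mask with a warning; an empty mask produces an empty skeleton, an
empty graph, and NA metrics (never silent zeros).

Whether "number of vertices" should include endpoints is a reporting
convention; both counts are emitted (`nVertices` counts all vertices,
`nJunctions`/`nEndpoints` split them), so either convention can be read off.

# Graph statistics

For a simple undirected graph (self-loops dropped, parallel edges
collapsed — the multigraph is preserved in the stored object, simplification
happens at metric time):

* Clustering coefficient of vertex $i$ with $k_i$ neighbors and $E_i$ edges
  among them: $C_i = 2E_i / (k_i(k_i-1))$; $C$ is the arithmetic mean over
  all vertices, with $C_i = 0$ for $k_i < 2$. Endpoint-heavy trabecular
  graphs would leave the mean undefined if low-degree vertices were
  excluded; exclusion is available as an option.
* Characteristic path length $L$: mean breadth-first shortest-path distance
  (in edges, unweighted) over vertex pairs of the largest connected
  component. Trabecular networks are routinely disconnected — the component
  count is itself a reported statistic — so the all-pairs mean would be
  infinite; restricting to the largest component is the package's
  convention, with size-weighted per-component averaging as an option.
* Small-worldness: $\sigma = (C/C_r)/(L/L_r)$ against an equivalent random
  network. The reference is the uniform $G(N, E)$ model with matched vertex
  and edge counts, 20 samples by default, seeded and reproducible.
  $\sigma = 1$ exactly for complete graphs (the reference is then forced);
  $\sigma$ is flagged NA when $C_r = 0$ or $L$ is undefined.

Implementation note: clustering is computed by triangle counting over
adjacency lists and distances by an all-pairs BFS in compiled code; both are
cross-checked in the test suite against independent brute-force enumeration
(Floyd–Warshall, exhaustive neighbor-pair counting) to 1e-12 on hundreds of
random graphs, and against igraph as a second oracle.

# Morphometry (2D analogues)

The conventional panel is computed per slice on the binary mask: bone area
fraction; mean local thickness (largest-inscribed-disc transform on the
Euclidean distance map, Hildebrand-style painting approximation) and its
background counterpart, trabecular separation; box-counting fractal
dimension (boundary mode by default, area mode by flag, default box sizes
2–32 px spanning four octaves by least squares). These are per-slice 2D
analogues of volumetric measures and all output columns carry a `2d` suffix
to say so. Volumetric vendor measures with no published definition
(structure model index, degree of anisotropy, trabecular pattern factor,
trabecular number) are deliberately out of scope.

# Depth profiles and group statistics

Per-slice records become per-specimen depth profiles
(`depthMm = depthIndex x pixel size / 1000`; slice spacing equals the pixel
size for isotropic scans). Group curves are across-specimen means with
sample-SD bands on the depth grid of the shortest profile (linear
interpolation, exact when grids already align). Moving-average smoothing is
applied to displayed curves only, never to stored records.

Group tests compare per-specimen region means — slices within one femoral
head are not independent, so the specimen is the unit of analysis. Regions
follow the floor rule: first (proximal) half `[0, floor(n/2))`, second half
`[floor(n/2), n)`, whole. Shapiro–Wilk normality p-values are reported per
group, followed by an unpaired t test (Student's pooled-variance by default,
Welch by flag) at alpha = 0.05. The test suite calibrates the type-I error
on 1000 seeded null replicates. Covariate adjustment (age/sex mixed models)
is out of scope — no covariates ship with synthetic data — and outputs are
accordingly unadjusted.

# The phantom generator

Because no public scan stacks accompany the methodology, every stage is
exercised on a synthetic phantom whose ground truth is exact by
construction. One slice is the raster of a planar **Voronoi ridge lattice**:

* `seedPoints` uniform seeds over a frame padded by 18% per side (so finite
  ridges cover the window); the ridge graph of their Voronoi diagram is the
  trabecular lattice. Voronoi cells visually and topologically resemble
  trabecular cross-sections, and the lattice is an explicit graph — hence
  exact ground truth.
* `anisotropy` stretches the row axis (the diagram is computed in compressed
  coordinates and mapped back), the simplest controllable analogue of
  preferential strut alignment.
* `fragmentationProb` deletes each ridge independently — deletion at the
  *edge* level, not pixel erosion, so the ground-truth component count stays
  exact.
* Survivors are rasterized (Bresenham), dilated by a disc of radius
  `strutThicknessPx - 1` (1 = raw one-pixel raster), and additive Gaussian
  noise of sd `noiseSigma` is applied and clipped — enough texture to
  exercise Otsu thresholding.
* Slice `i` of a stack is drawn under seed `rngSeed + i`; cohort sample `j`
  under `rngSeed + j`. Identical specs regenerate bit-identical images.

Default conditions are chosen at a typical ex vivo acquisition scale of 20.5 um
isotropic pixels: a 512 px frame (~10.5 mm), 150 seeds (mean cell size
~0.8 mm, the scale of trabecular separation), strut radius 3 (~100 um strut
width), fragmentation 0.05, noise 0.08. The HOA-like preset
(`phantomPreset("hoa")`) thickens struts (radius 6, ~230 um, sclerosis),
doubles the seed density (halved cell area, visibly shorter ridges —
compressed structures; a smaller increase is largely swallowed by the thick
junction clusters), raises
fragmentation to 0.25 (more graph components) and lowers anisotropy —
the qualitative contrasts reported for osteoarthritic femoral heads.

What the phantom does **not** emulate: gray-level beam hardening, ring
artifacts, plate-like (as opposed to strut-like) structures, cortical shell,
and genuine 3D continuity between slices. Passing tests on phantoms
therefore demonstrate correctness of the extraction and statistics on
lattice-like structures with known topology, not clinical performance on
patient scans.

# The classifier

The network is deliberately small and fixed: four blocks of [3x3
convolution, stride 1, batch normalization, ReLU], 2x2 stride-2 max pooling
after blocks 1–3, two fully connected layers (64, then 2) and a softmax. At
the default 128 px input and 8/16/32/64 channels, the feature map entering
the FC layers is 16x16x64 and the trainable parameter count is 1,073,274
(dominated by the first FC layer). Forward/backward passes are implemented
in the package (im2col + GEMM convolutions in compiled code; batch-norm,
pooling and Adam in R), with seeded initialization, splitting and shuffling,
so runs are reproducible per BLAS backend.

Training hyperparameters are not architectural commitments: Adam at 1e-3,
batch 16, 20 epochs by default, all overridable. The two-arm experiment in
the acceptance surface uses 10 epochs — ample for the strongly separated
phantom cohort it trains on, chosen as the experiment's own budget.

The two-arm experiment (`runTwoArmExperiment`) trains the identical
architecture, split and seeds on (i) raw slices and (ii) binary renderings
of the extracted networks (`renderNetwork`: edge paths plus 3x3 vertex
blocks — the encoding is a design choice, since a graph must become an image
again to enter the same CNN). A stratified 90/10 split is used; on
single-slice phantom cohorts each image is its own sample, so slice-level
and sample-level splitting coincide; on real stacks, slices of one specimen
should never straddle the split (a leakage-sensitive choice the API leaves
to the caller, flagged here). Evaluation reports the confusion matrix at the
argmax decision, accuracy, the ROC over softmax-score thresholds, and
trapezoidal AUC.

The reference experiment (also run by `scripts/acceptance.R`) draws 100
phantom slices per regime at 128 px — strut radius 2 versus 6, fragmentation
0 versus 0.4, noise 0.1 — a deliberately strongly separated pair standing in
for the expert-labeled scan cohort that is not publicly available. Headline
accuracies reported on patient scans are not reproducible from synthetic
data and are not claimed; the experiment verifies the machinery and the
qualitative ordering (the network arm performs at least on par with the raw
arm).

# Numerical choices and problem sizes

* Delaunay triangulation for the Voronoi lattice is a brute-force
  circumcircle test (compiled), adequate to ~600 seeds; degenerate
  (near-collinear) triples are skipped with a relative tolerance of 1e-10
  and co-circular ties broken by the strict in-circle inequality.
* Otsu threshold uses 256 bins on [0, 1]; ties in maxpool argmax break
  toward the upper-left pixel; ROC thresholds sweep the distinct scores from
  +Inf downward.
* Random reference graphs decode uniformly sampled pair indices, so the
  ensemble is exactly uniform over simple graphs with the given N, E.
* The test suite and acceptance script use reduced problem sizes chosen for
  a desk-scale run: 96–256 px phantoms, 10–30 seeds for unit checks,
  200 random graphs (<= 15 vertices) for oracle equivalence, 1000 replicates
  for t-test calibration, and the 100-per-class 128 px cohort for the
  two-arm experiment.

# Known limitations

* 2D only: no 3D skeletonization, no graph merging across slices.
* The phantom is a topological stand-in, not a biomechanical simulation.
* $L$ on disconnected graphs depends on the largest-component convention;
  comparisons across graphs with very different fragmentation should also
  inspect `nComponents`.
* Bit-level reproducibility of training is promised only per BLAS backend.
* Whether endpoint vertices belong in "number of vertices" is a convention;
  both counts are emitted.
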