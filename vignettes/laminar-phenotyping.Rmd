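---
title: "Laminar-window phenotyping of multiplexed tissue images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar-window phenotyping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the models and
their assumptions, the parameters that matter, what the synthetic phantom
does and does not emulate, and the numerical and design choices made where
the problem left them open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The measurement problem

Laminated neural tissues — the retina and retinal organoids prototypically —
organize along an inner–outer axis: cell types and subcellular structures
occupy characteristic depths from the tissue boundary, and the depth profile
changes as the tissue matures. Highly multiplexed immunofluorescence (4i)
provides dozens of aligned protein channels per section, but the axis along
which to read them is different at every point of a curved, irregular
boundary. The package's core abstraction is the **laminar window**: a
rectangle anchored on the tissue contour and rotated to align with the local
inner–outer axis, inside which transverse averaging turns the 2D image into
a 1D depth profile. Everything downstream — distances, trajectories,
maturation scores — operates on those profiles.

## Pixel-level tissue units (MTUs)

**Normalization.** Sections imaged in batches drift in intensity. Reverse
z-scoring removes per-image offset and scale while retaining group-level
(timepoint × channel) differences: each image channel is z-scored by its own
mean and sd, then multiplied by the pooled sd and recentred at the pooled
mean of its group; finally every channel is mapped to [0, 1] with the global
1st percentile at 0 and the 99th at 1, clipped. The transform is
monotone-affine per image, so intensity rankings within an image are
untouched. Within a group of equally sized images, every reverse z-scored
image carries the group mean and sd exactly; note that the *pooled* sd of
the group after the transform is slightly smaller than the input group sd
whenever input image means differ, because per-image z-scoring removes the
between-image variance component. A zero-variance image is passed through
unchanged and flagged rather than dividing by zero.

**SOM + metaclustering.** A random in-mask pixel subset (default 1 in 1,000)
trains a batch self-organizing map: rectangular grid (default 30 × 30),
Euclidean distance, Gaussian neighbourhood whose radius decays linearly from
half the grid width to 0.5 over 20 epochs, 10 restarts with consecutive
seeds, keeping the codebook with the lowest quantization error. Batch
training (weighted means per epoch rather than per-sample updates) is
deterministic given the initialization and robust at the small sample sizes
a subsample produces. Per-node channel *medians* over assigned training
pixels (empty nodes keep their codebook vector, so no grid node is dropped)
are then clustered for each k in a sweep (default 5, 10, …, 40) with a
k-nearest-neighbour graph and Louvain community detection at resolution 1;
edges are unweighted by default, with Jaccard weighting available. The final
k sits at the knee of the (k, #clusters) curve, located with the Kneedle
rule: normalize both axes, flip the decreasing convex curve to concave
increasing, and take the first local maximum of the difference-to-diagonal
curve that is confirmed by a subsequent drop below its sensitivity
threshold. MTU ids are assigned in order of decreasing member pixel count,
and all pixels are labelled by the nearest metacluster centroid (ties to the
lowest id), so assignment is idempotent and order-independent.

**Granularity is data- and scale-dependent.** Louvain on kNN graphs
fragments large homogeneous point clouds; on real 54-channel data this
produces the fine-grained tissue units the method is designed to find
(dozens of clusters), while on a 4-class phantom at desk scale it
over-segments. The SOM grid is therefore a first-class parameter: the
validation suite uses a 12 × 12 grid for the four-class phantom (roughly 36
nodes per class, enough for the classes to appear as near-cliques across the
k sweep), and the default 30 × 30 for production-scale data. The number of
clusters found on any particular dataset is not a correctness criterion.

## Laminar windows

**Contour and distance map.** The tissue mask (percentile-scaled structural
channels averaged, Otsu threshold, disk dilation, hole filling, largest
component) is Gaussian-smoothed (σ = 50 by default) and re-thresholded;
the longest marching-squares iso-contour at that level, extracted at
subpixel resolution and oriented counter-clockwise, is the tissue boundary.
The inner–outer axis field is the exact Euclidean distance transform of the
mask smoothed with σ = 25. Smoothing regularizes the rotation objective but
shrinks the distance peak by roughly 1.25 σ (the blur of a cone apex), so σ
should stay well below the tissue radius; the defaults assume
production-scale images (thousands of pixels across), and the test suite
scales σ with its phantom sizes.

**Placement and orientation.** Windows (default 100 × 1,000 px; 16.25 ×
162.5 μm at 0.1625 μm/px) anchor at every `stride`-th contour coordinate
(default 100) at the midpoint of their outer short edge. The initial angle
is the inward normal estimated by PCA over ±10 contour points, the sign
chosen toward the higher distance-map value. Orientation then maximizes the
summed bilinearly sampled distance-map signal under the footprint over
initial ± 90° in 2° steps, refined at 0.5°; ties take the angle closest to
the initial normal, and a window scoring zero everywhere keeps its initial
angle and is flagged out-of-bounds. The ±90° arc (full-circle scan
available) prevents flips onto the outward side on thin tissue. Window
length matters: rectangles long relative to the local radius of curvature
integrate signal from converging normals and bias the argmax away from the
local normal, so window length should stay a modest fraction of the tissue
radius — the validation geometry uses ~0.7 R and recovers analytic normals
to ~1° median error.

**Profiles and filtering.** Each window is resampled on its width × length
grid (bilinear for intensities, nearest-neighbour for label images; label
features are one-hot encoded per MTU id, giving occupancy profiles that sum
to 1 where fully in-mask). Transverse (width) samples are averaged at every
inner–outer position; out-of-mask samples are excluded from the mean and
recorded as missing; position 1 is the outer edge. Windows are retained only
if strictly more than 99 % of their footprint lies in the mask. A
straightness filter (maximum perpendicular deviation of the window's contour
span from its chord, default threshold 2 px) is available but off by
default: it existed to remove acquisition-crop artifacts specific to the
original imaging setup, not a property of tissue.

## Profile distances, DISTATIS and trajectories

Profiles are reverse z-scored per (section, timepoint) group per feature,
min-max scaled to [0, 1] across windows (constant features are set to 0.5
and flagged), mean-filtered along the inner–outer axis (width 20, windows
truncated at the edges so no positions are lost) and downsampled by 2.
Missing positions are imputed from the nearest valid position before any
statistics.

**FFT distance.** The distance between two windows for one feature is the
Euclidean norm of the difference of the first 10 complex DFT coefficients of
their profiles, DC term included — comparing real and imaginary parts
jointly, as the Fourier distance for time series does. Including DC makes
the distance sensitive to mean level, which is intended: overall intensity
differences between laminar states are signal here. A magnitude-only variant
is deliberately not offered as a default because discarding phase would
equate profiles that are circular shifts of each other — exactly the
geometry the windows were oriented to resolve.

**DISTATIS.** Per-feature distance matrices are squared, double-centred with
uniform masses into cross-product matrices, normalized by their first
eigenvalue, compared by RV coefficients, and combined with weights from the
first eigenvector of the RV matrix (rescaled to sum 1); the compromise
cross-product back-transforms to the compromise distance. Negative squared
distances arising from floating-point noise are clamped at zero with a
warning. K identical tables produce exactly uniform weights and a compromise
proportional to the input — the package's invariant test.

**Diffusion embedding and pseudotime.** The aggregated distance (mean over
features of log10(x+1)-transformed FFT distances) feeds a Gaussian kernel
with local bandwidths σᵢ equal to the distance to the k-th neighbour
(default k = 30, reduced to W/4 for small window counts), density-normalized
with α = 1 and symmetrically normalized before eigendecomposition; the
trivial constant component is removed and components are scaled by their
eigenvalues. Disconnection is decided on the kernel *support* graph, not the
spectrum: tight but connected data can push the second eigenvalue against 1
in double precision, which is legitimate geometry, whereas exact zero
bridges mean the items fall apart into groups. The default policy errors
with the component sizes; `on_disconnected = "keep"` proceeds (used for pure
clustering, where the embedding still separates the components and no
pseudotime is read across them). Pseudotime is the Euclidean distance from a
root window in the λ/(1−λ)-rescaled eigenspace, min-max scaled to [0, 1];
eigenvalues numerically at 1 on connected kernels are clamped to 1 − 10⁻¹²
so the weights stay finite. The single-root distance form (rather than a
full accumulated transition construction) reflects the single-branch laminar
trajectory this analysis targets; the root defaults to the window of the
earliest timepoint with the most extreme first diffusion component and can
be overridden.

**Clusters, maturation, cluster graph.** Per timepoint, a 2D UMAP of the
first 10 diffusion components is clustered by Louvain on its
k-nearest-neighbour graph (k = 15, resolution 1, fixed seeds; subsets
smaller than k + 1 windows collapse to a single cluster with a warning).
The maturation score of a window is its mean compromise distance to the
earliest 5 % pseudotime quantile set minus that to the latest, min-max
scaled to [−1, 1]; passing an explicit end set (for example reference adult
windows) turns the same operation into a similarity-to-reference score. The
cluster graph connects clusters of the same or adjacent timepoints only,
weights edges by mean inter-cluster compromise distance, keeps the k = 4
smallest-weight edges per node, symmetrizes by union, and lays the result
out force-directed with attraction proportional to 1/weight; the adjacency
constraint is asserted on every run. Trajectory heat maps clip-scale each
feature between its lower 1 % and upper 5 % quantiles and mean-filter along
the pseudotime axis (width 15; 25 for the position-averaged variant).

## Nuclei and neighbourhoods

Per-nucleus features are computed over member pixels: area, centroid, bottom
and top 5th percentiles, median, mean and sum per channel, the mean
distance-map value (radial distance), and local density as the number of
centroids — self included — inside an axis-aligned ellipse with a 100 × 100
px bounding box. Radial neighbourhood profiles average channel intensity
over rings of *rounded* Euclidean pixel distance r = 1…40 from the centroid
(rounding gives unbiased ring widths), excluding pixels that belong to any
nucleus — the conservative reading of nuclear masking; focal-only exclusion
is available — and recording rings with no eligible pixels (outside the
image, or inside the nucleus disk) as missing rather than zero. At 0.1625
μm/px the default 40 px radius is 6.5 μm; the radius is configured in
pixels and the micron equivalence is informational. Neighbourhood clustering
chains the shared machinery: normalization, smoothing/downsampling, FFT
distances averaged across channels (plain mean — the log transform is the
laminar trajectory's choice), diffusion embedding with the permissive
disconnection policy, UMAP and Louvain.

## Spatial feature correlation

Per-nucleus feature values become spatial densities by weighted kernel
density estimation with an axis-aligned bivariate normal kernel: every
centroid contributes a kernel scaled by its (nonnegative; shifted if
necessary, with the shift recorded) feature value, so the grid integrates to
the total weight. Kernel-weight scaling is exact, unlike point replication.
Bandwidths follow the normal reference rule on the centroid coordinates
divided by 4 — the same convention as the classical 2D KDE in MASS, making
the unweighted case directly comparable. Densities are evaluated on a
200 × 200 grid over the section bounding box. The occupancy mask is the
unweighted nuclei density rescaled to maximum 1 and thresholded at 0.05
(max-1 normalization chosen because the reference analysis leaves its
normalization unstated); correlations are Pearson over occupancy-masked
cells, averaged per feature across sections, with the top 115 positive and
negative correlates reported as ranked lists.

## The phantom: what it emulates and what it does not

The generator produces a filled ellipse whose polar radius carries a
low-frequency sinusoidal wobble (so contours are not trivially circular and
orientation is non-degenerate), channel intensities that are sums of
Gaussian layers in normalized depth (distance transform over its maximum)
with per-channel amplitudes interpolating linearly between immature (t = 0)
and mature (t = 1) states, additive Gaussian noise (optionally
signal-scaled), ground-truth pixel classes (argmax layer contribution),
non-overlapping nuclei disks placed by rejection sampling (bounded at
10,000 attempts), and an analytic contour with exact inward normals.
Sections are bit-reproducible from their spec, including the seed.

It deliberately does **not** emulate: point-spread functions or illumination
gradients, multi-cycle registration error, elution background, 3D structure,
non-convex or multi-lobed tissue, cell-scale texture, or biologically
realistic channel correlations. Passing tests on the phantom therefore
demonstrate the geometric and numerical correctness of the pipeline —
orientation against known normals, profile fidelity against closed forms,
ordering against a known maturation parameter — not robustness to
acquisition artifacts, which must be assessed on real data.

Validation problem sizes were chosen to exercise every code path in minutes
on one CPU: 192–256 px sections, 20 × 60 to 50 × 200 px windows, five
timepoints with ~67 windows per section for trajectory recovery, a 12 × 12
SOM on a four-band phantom for MTU recovery. Defaults inside the package
remain the production-scale values quoted above.

## Numerical choices and degenerate inputs

- Coordinates are 1-based (row, col) with pixel centres at integers — the
  native R convention; angles are radians from the +col axis toward the
  +row axis. Bilinear samples outside the image contribute 0 to orientation
  scores and are *missing* (not 0) in profiles.
- Rotation-scan ties resolve to the angle nearest the initial normal;
  nearest-centroid ties to the lowest MTU id; both make results
  permutation-stable.
- The moving mean truncates its window at profile edges rather than padding,
  so smoothing introduces no phantom intensity at the boundary.
- Empty SOM nodes keep their codebook vector as their "median"; empty rings
  and fully-out-of-mask profile positions are NA; a constant profile feature
  normalizes to 0.5 and is flagged; an all-equidistant maturation score
  collapses to 0 with a warning.
- One global seed fans out to per-stage seeds by a stable string hash kept
  below 2³¹; every stochastic stage (subsampling, SOM restarts, Louvain
  vertex order, UMAP, layouts) is seeded from it, and identical inputs with
  identical seeds reproduce all numeric outputs bit-exactly.
- Channel stacks are stored as 16-bit unsigned TIFF with a per-stack
  intensity scale recorded in the manifest; masks and label images are
  16-bit exact. Arrays travel as long-format TSV with a JSON sidecar naming
  the axes; the MTU model is a single JSON archive that `run_pipeline()`
  reuses when present and re-fits (logged) when absent.

## Known limitations

- Open (non-closed) contours — cup-shaped sections — are out of scope; the
  contour is assumed to be a single closed curve.
- "Every 100th contour coordinate" is in marching-squares coordinate units,
  whose spacing varies with local geometry; an arc-length-uniform placement
  would space windows more evenly but is not the default behaviour.
- Louvain granularity depends on graph size and k; cluster counts are not
  comparable across datasets of different scale without revisiting the SOM
  grid and k sweep.
- The maturation score is relative to the analyzed window set (min-max
  scaled), so scores are not comparable across independent runs.
- Pseudotime assumes a single-branch trajectory; branching laminar
  topologies would need a different construction.
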