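---
title: "Voxel-based analysis of segmented marker images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based analysis of segmented marker images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markload)
```

## The problem

Immunohistochemistry reveals a protein of interest — for example amyloid-β
plaques in a mouse model of Alzheimer's disease — as a binary "marker
present" signal after segmentation, at micrometre resolution. Comparing two
cohorts of such images voxel-by-voxel at full resolution is hopeless: at
that scale inter-individual variability dwarfs any group effect, and the
signal is binary rather than continuous. **markload** addresses this by
summarising each high-resolution binary image as a low-resolution
continuous *parametric map* of local marker load (the fraction of tissue
occupied by marker), on which standard voxel-wise statistics become
meaningful. The package assumes its inputs are already segmented and
registered to a common template; segmentation and registration are upstream
concerns.

## Marker-load estimators

Three estimators convert a binary image $M$ into a map, all ending with
non-overlapping window binning (default $18 \times 18$ voxels in 2D,
$18 \times 18 \times 1$ for section-wise 3D volumes, so a 2560-pixel image
yields a 143-bin axis with a partial final window):

* **Binning alone** — each output voxel is the mean of its window. Unbiased
  but noisy, because the number of marker objects per window is small.
* **Voronoi tessellation + binning** — connected foreground components are
  reduced to centroids, the plane is partitioned into their Voronoi cells,
  and each voxel of a cell receives load = component area / cell area.
  Parameter-free; adapts to object density but smears loads across cell
  boundaries. Cell assignment is exact nearest-centroid (Euclidean), with
  distance ties resolved deterministically toward the site with the smaller
  column coordinate; per-cell loads are capped at 1 in degenerate
  geometries where a component leaks outside its own cell.
* **Gaussian smoothing + binning** — convolution with a unit-sum Gaussian
  kernel of standard deviation $\sigma$ (truncated at $3\sigma$,
  zero-padded) before binning. The bias–variance trade-off is governed by
  $\sigma$, which is the one genuinely consequential tuning parameter of
  the pipeline.

Binning with partial boundary windows averages over the voxels actually
present, so no tissue is discarded when the window does not divide the
image. With a brain mask, smoothing renormalises by the smoothed mask so
loads remain unbiased near the mask border, and masked-out voxels are
excluded everywhere downstream.

## Choosing the kernel width by out-of-bag bootstrap

The smoothed-map sample mean should estimate the population marker load as
precisely as possible. `bootstrap_error()` estimates its squared error
without knowing the truth: draw $B$ bootstrap samples of individuals with
replacement; for individual $j$ average, over the samples that do not
contain $j$, the voxel-mean squared difference between the sample's mean
smoothed image and $j$'s raw binary image; average over individuals.
`select_kernel()` computes this curve per experimental group (reusing the
same bootstrap draws across candidate $\sigma$, a common-random-numbers
choice that removes spurious curve wiggle) and selects the $\sigma$
minimising the across-group mean curve, breaking ties toward the smaller
$\sigma$. The default candidate grid is geometric with ten values from 2 to
64 voxels; for physical data the grid should be given in voxels derived
from physical units. The error is evaluated at full voxel resolution by
definition; a `stride` option evaluates it on a regular subgrid instead,
which leaves the curve's expectation essentially unchanged (the subgrid is
an unbiased subsample of the voxel mean) and is used for the large
benchmark runs (stride 6, i.e. one evaluation voxel in 36).

On simulated cohorts, where the truth is known, the bootstrap curve's
argmin tracks the true-error argmin (`true_error_curve()`); this is one of
the package's acceptance checks. Under the default simulated cluster
geometry both curves are minimised at the top of the default grid — the
bias incurred by a 64-voxel kernel is still smaller than the variance it
removes, because the planted clusters are large (512 px across); the
true-error curve turns upward shortly beyond the grid (around
$\sigma \approx 90$), and with smaller structures the minimum moves into
the grid interior.

## Inference

`tstat_map()` computes the voxel-wise two-tailed two-sample Student t
statistic (pooled variance, $df = n_a + n_b - 2$; Welch available).
Voxels with zero pooled variance and equal means are reported as $t = 0$,
$p = 1$. Suprathreshold voxels ($p < 0.05$ by default) are partitioned
into connected components separately per sign (8-connectivity in 2D,
26-connectivity in 3D by default), and each cluster's *mass* is the sum of
$|t|$ over its voxels.

For family-wise error control, `permutation_null()` re-runs the test under
random relabelings of the individuals (group sizes preserved), recording
each permutation's maximum cluster mass; the observed labelling is not
included in the null set, and when fewer distinct relabelings exist than
requested, all of them are enumerated instead. Corrected p-values use the
add-one convention $p = (1 + \#\{\text{null} \ge \text{observed}\}) /
(1 + n_{perm})$, which cannot reach zero with the default 100 permutations;
a cluster is significant when $p < \alpha$, equivalently when its mass
strictly exceeds the $\lfloor \alpha (1 + n_{perm}) \rfloor$-th largest
null mass. In the simulation benchmark, detection quality is scored
*without* permutation correction (uncorrected $p < 0.05$ thresholding),
with voxel-wise F1 $= 2TP / (2TP + FP + FN)$ against the true cluster mask;
detections in the direction opposite to the planted effect count as false
positives, and a binned voxel is "true" when more than half of its source
voxels lie in a planted cluster.

## The Boolean–Poisson simulator

The generator plants disks — round objects of varying size, as plaques
are — at the points of an inhomogeneous Poisson process and takes their
union as the binary image. Its defaults are the benchmark study
conditions:

* image size 2560 × 2560 px (5 µm pixels);
* disk radii Gaussian with mean 7 px and sd 2 px (a typical plaque radius
  at this resolution), with non-positive draws resampled (the alternative
  clip-to-zero rule is available; at 3.5 sd the difference is negligible);
* a piecewise-constant seeding intensity: a background integrating to
  $\Lambda_0 \in \{40, 80, 160\}$ expected seeds per image, and four square
  clusters whose per-pixel rate is a multiple (20, 10, 5, 2.5) of the
  background rate;
* cluster geometry: four 512 × 512 px squares centred in the four image
  quadrants (multipliers 20, 10, 5, 2.5 in reading order) — cluster size
  and placement are free parameters of the design, configurable via
  `cluster_spec()`;
* 10 images per group, a realistic animal-study sample size.

$\Lambda_0$ is interpreted as the *expected background seed count over the
whole image*, so the exacerbated field integrates to
$\Lambda_0 (1 + \sum_i f_i (m_i - 1))$ with $f_i$ the cluster area
fractions — 93.6 expected seeds at $\Lambda_0 = 40$. Seed positions are
continuous; a pixel is foreground when its centre lies inside a disk, and
disks are clipped at the image border.

The model's coverage probability — the *true marker load* — is known in
closed form: $\mu_x = 1 - \exp(-\int \lambda(y) P(R \ge \|x - y\|) dy)$,
reducing to $1 - \exp(-\lambda \pi E[R^2])$ in homogeneous regions.
`true_marker_load()` evaluates the integral as a lattice convolution of the
intensity grid with the radius survival function, with the discrete kernel
normalised to its continuous mass $\pi E[R^2]$ so that homogeneous
interiors match the closed form exactly; $E[R^2]$ uses the truncated-normal
moments (53.01 under the default resampling rule, against 53 for the
untruncated Gaussian). Zero padding of the convolution mirrors the
renderer's border clipping: coverage genuinely drops near the border
because no seeds fall outside the window.

What the simulator does *not* emulate about real data: registration error,
segmentation noise, anisotropic section geometry, object shapes other than
disks, and between-group differences in object size or shape rather than
density. Benchmark results therefore validate the estimator and inference
machinery under a density-difference model, not the upstream imaging
pipeline.

## Benchmark problem sizes and reproducibility

`run_benchmark()` reproduces the three-experiment design at full scale
(2560², 10 vs 10, all three estimators) with five replicate cohorts per
experiment, bootstrap kernel selection with $B = 500$ draws evaluated at
stride 6, and reports per-replicate true error (MSE between the
exacerbated-group mean map and the aggregated truth) and F1. One replicate
of one experiment takes roughly half a minute on one CPU; the full
three-experiment, five-replicate benchmark runs in a few minutes. The
type-I calibration study uses 512 × 512 px control-vs-control cohorts with
$\Lambda_0 = 40$: keeping the expected object count (rather than the
per-pixel density) on the smaller frame preserves the statistical character
of the maps — scaling the density down instead yields maps so sparse that
the cluster-forming threshold never fires and the calibration becomes
vacuous.

Every stochastic step (cohort generation, bootstrap draws, permutations)
consumes the standard R RNG; cohort generation derives per-image
sub-stream seeds deterministically from its seed, so fixed seeds give
bit-identical cohorts and byte-identical pipeline outputs.

## Numerical choices

* Gaussian kernels are truncated at $3\sigma$ and renormalised to unit
  sum, so interior mass is conserved exactly.
* For unmasked binary 2D images, smoothing-then-binning is computed by
  scattering each foreground pixel's kernel mass directly into the output
  bins; this is algebraically identical to dense smoothing followed by
  binning (the test suite checks equality to $10^{-12}$) and makes the
  full-scale benchmark tractable.
* The coverage-probability convolution uses FFTs with 7-smooth padded
  sizes; values are clamped to $[0, 1]$ against roundoff.
* Components whose centroids coincide exactly share a Voronoi cell, with
  their sizes pooled.
* Count comparisons with a zero-mean reference group report the percent
  change as `NaN` with a warning rather than failing.

## Limitations

Adaptive (per-voxel) kernel widths, random-field-theory thresholds,
cluster-extent inference, and non-stationarity adjustments are out of
scope. The Voronoi estimator is 2D-only. The hierarchical (mixed) model
for within-cluster object *size* differences is deliberately delegated:
`export_size_table()` writes the tidy per-object table that `nlme::lme` or
`lme4::lmer` consume directly, since that fit is standard statistical
practice rather than part of this package's contribution.

## A worked micro-example

```{r example, eval = FALSE}
cfg <- sim_config(image_shape = c(512, 512), basal_expected_count = 40,
                  clusters = default_clusters(c(512, 512)), n_per_group = 10,
                  seed = 1)
cohort <- simulate_cohort(cfg)
curve <- select_kernel(list(control = cohort$control,
                            exacerbated = cohort$exacerbated),
                       sigmas = sigma_grid(2, 32, 8), n_bootstrap = 200)
maps <- lapply(c(cohort$exacerbated, cohort$control), estimate_map,
               estimator = "gaussian_binning", sigma = curve$selected_sigma)
sm <- tstat_map(maps[1:10], maps[11:20])
clusters <- extract_clusters(sm, 0.05)
null <- permutation_null(maps, rep(c("e", "c"), each = 10), n_perm = 100)
significant_clusters(clusters, null)
```
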