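# markload

Voxel-based statistical analysis of segmented (binary) marker images, such
as immunostained amyloid-β plaques in rodent brain tissue.

## The problem

Modern 3D histology and microscopy deliver whole-brain images in which a
marker of interest has been segmented into a binary "present / absent"
signal at micrometre resolution. Detecting *where* an experimental
intervention changes the marker between cohorts is hard at that scale:
voxel-to-voxel comparison of binary high-resolution images is meaningless,
and region-of-interest averages miss effects confined to small areas.
**markload** implements the middle road: each individual's binary image is
summarised as a low-resolution continuous *parametric map* of local marker
load (the tissue fraction occupied by marker), and cohorts are compared
voxel-wise on those maps with permutation-corrected cluster inference.

The package is aimed at image-analysis scientists working with cohorts of
pre-registered segmented 2D images or 3D volumes (PNG/TIFF/NIfTI), and
ships a stochastic-geometry simulator for validating the statistical
machinery.

## Methods at a glance

* **Map estimators** (`estimate_map`): window binning; Voronoi tessellation
  of object centroids (load = object area / cell area) + binning; Gaussian
  kernel smoothing + binning. Default window 18 × 18 voxels.
* **Bandwidth selection** (`select_kernel`): the Gaussian kernel sd σ is
  chosen by minimising the out-of-bag bootstrap error

  $$\widehat{Err}^{boot} = \frac{1}{T}\sum_{j=1}^{T} \frac{1}{|C_{-j}|}
  \sum_{b \in C_{-j}} \frac{1}{n} \sum_{i=1}^{n}
  \left(\hat\mu^{b}_{x_i} - M_j(x_i)\right)^2,$$

  where $\hat\mu^b$ is the mean smoothed image of bootstrap sample $b$,
  $M_j$ the raw binary image of individual $j$, and $C_{-j}$ the samples
  not containing $j$; curves are computed per group and the σ minimising
  their mean is selected.
* **Inference** (`tstat_map`, `extract_clusters`, `permutation_null`,
  `significant_clusters`): voxel-wise two-tailed Student t-tests; clusters
  of suprathreshold voxels (p < 0.05) scored by their *mass* (sum of |t|);
  family-wise error controlled by permuting individuals and comparing each
  cluster mass with the permutation distribution of the maximum mass,
  $p_{corr} = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + n_{perm})$.
* **Simulator** (`simulate_cohort`, `true_marker_load`): a Boolean–Poisson
  model — disks with Gaussian radii N(7, 2) px seeded by an inhomogeneous
  Poisson process over a piecewise-constant intensity (background plus four
  square clusters at rate multipliers 20/10/5/2.5) — with the exact
  coverage probability $\mu_x = 1 - e^{-\int \lambda(y) P(R \ge \|x-y\|) dy}$
  available for benchmarking (F1 detection scores and true MSE).
* **Object statistics** (`label_objects`, `objects_in_cluster`,
  `compare_counts`, `export_size_table`): per-individual counts and sizes
  of marker objects inside significant clusters, count t-tests, and a tidy
  size table for mixed-model analysis.

## Worked example

Simulate one benchmark-style cohort at a reduced size, pick the kernel,
and run the inference:

```r
library(markload)

cfg <- sim_config(image_shape = c(512, 512), basal_expected_count = 40,
                  clusters = default_clusters(c(512, 512)),
                  n_per_group = 10, seed = 1)
cohort <- simulate_cohort(cfg)

curve <- select_kernel(list(control = cohort$control,
                            exacerbated = cohort$exacerbated),
                       sigmas = sigma_grid(2, 32, 8), n_bootstrap = 200)
curve
#> <bootstrap_error_curve> 8 candidate sigmas, 2 group(s), B = 200
#> selected sigma: 14.49 voxels

maps <- lapply(c(cohort$exacerbated, cohort$control), estimate_map,
               estimator = "gaussian_binning", sigma = curve$selected_sigma)
sm <- tstat_map(maps[1:10], maps[11:20])
null <- permutation_null(maps, rep(c("exac", "ctrl"), each = 10),
                         n_perm = 100, alpha = 0.05)
sig <- significant_clusters(extract_clusters(sm, 0.05), null)
cluster_table(sig, dim(sm$t))
#>   cluster sign size     mass corrected_p   centroid       bbox
#> 1       1    1   62 392.4380  0.00990099  7.56;7.06  3-11;3-11
#> 2       2    1   48 198.3987  0.01980198 8.08;22.17 5-12;19-25
```

The two significant clusters of elevated load (corrected p = 1/101 and
2/101) sit over the two strongest planted clusters — the multiplier-20
square in the top-left quadrant and the multiplier-10 square in the
top-right; the weaker planted clusters at multipliers 5 and 2.5 are below
detectability at this reduced frame, as expected.

`run_benchmark()` reproduces the full three-experiment comparison of the
estimators (basal counts 40/80/160 at 2560², 10 vs 10 images), reporting
per-replicate true error and F1 per estimator; `summary()` averages over
replicates. On these benchmarks Gaussian smoothing + binning dominates
Voronoi + binning, which dominates binning alone, in both error and F1.

## Command line

A thin CLI over the same functions supports staged, re-runnable pipelines
with manifests and provenance JSON in every output directory:

```sh
$(Rscript -e 'cat(system.file("cli", "markload", package = "markload"))') \
    simulate --config run.yaml --out out/sim --seed 7
```

Subcommands: `simulate`, `maps`, `select-kernel`, `infer`, `objects`,
`benchmark`.

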