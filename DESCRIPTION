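Package: markload
Title: Voxel-Based Statistical Analysis of Segmented Marker Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for voxel-based group comparison of high-resolution binary
    (segmented) marker images, such as immunostained amyloid-beta plaques in
    rodent brain sections. High-resolution binary images registered to a
    common template are converted into low-resolution continuous parametric
    maps of local marker load by binning, Voronoi tessellation, or Gaussian
    kernel smoothing; the smoothing bandwidth is selected by out-of-bag
    bootstrap error minimisation. Maps are compared voxel-wise with two-sample
    t-tests, and family-wise error is controlled by permutation inference on
    the maximum cluster mass. A Boolean-Poisson simulator (Poisson-seeded
    disks with Gaussian radii and piecewise-constant seeding intensity)
    generates synthetic cohorts with analytically known marker load for
    benchmarking, and post-hoc object statistics summarise marker object
    counts and sizes within significant clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    png,
    tiff,
    RNifti,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
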