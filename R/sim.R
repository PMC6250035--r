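# Boolean-Poisson simulator: Poisson-seeded disks with Gaussian radii over a
# piecewise-constant seeding intensity, plus the exact coverage probability
# (true marker load) used for benchmarking map estimators.

#' Disk radius model
#'
#' Radii of simulated marker objects (disks) are drawn from a Gaussian
#' distribution. Because a Gaussian can produce non-positive values, a
#' truncation rule is applied: `"resample_nonpositive"` redraws until the
#' radius is positive (the default; negligible at 3.5 sd), `"clip_to_zero"`
#' replaces non-positive draws by zero (a zero-radius seed covers no pixel).
#'
#' @param mean_radius mean radius in pixels.
#' @param sd_radius standard deviation of the radius in pixels.
#' @param truncation one of `"resample_nonpositive"`, `"clip_to_zero"`.
#' @return an object of class `radius_model`.
#' @examples
#' radius_model(7, 2)
#' @export
radius_model <- function(mean_radius = 7, sd_radius = 2,
                         truncation = c("resample_nonpositive", "clip_to_zero")) {
  truncation <- match.arg(truncation)
  stopifnot(mean_radius > 0, sd_radius >= 0)
  structure(list(mean_radius = mean_radius, sd_radius = sd_radius,
                 truncation = truncation),
            class = "radius_model")
}

# P(R >= d) for the truncated radius distribution.
radius_survival <- function(model, d) {
  mu <- model$mean_radius; s <- model$sd_radius
  if (s == 0) return(as.numeric(d <= mu))
  p <- pnorm(d, mu, s, lower.tail = FALSE)
  if (model$truncation == "resample_nonpositive") {
    z <- pnorm(0, mu, s, lower.tail = FALSE)
    p <- ifelse(d <= 0, 1, p / z)
  } else {
    p <- ifelse(d <= 0, 1, p)
  }
  p
}

# E[R^2] under the truncation rule (closed forms for the truncated normal).
radius_mean_square <- function(model) {
  mu <- model$mean_radius; s <- model$sd_radius
  if (s == 0) return(mu^2)
  a <- -mu / s                       # standardised truncation point
  z <- pnorm(a, lower.tail = FALSE)
  if (model$truncation == "resample_nonpositive") {
    # E[X^2 | X > 0] for X ~ N(mu, s^2)
    mu^2 + s^2 + s * mu * dnorm(a) / z
  } else {
    # E[max(X, 0)^2]
    (mu^2 + s^2) * z + s * mu * dnorm(a)
  }
}

sample_radii <- function(n, model) {
  r <- rnorm(n, model$mean_radius, model$sd_radius)
  if (model$truncation == "resample_nonpositive") {
    bad <- which(r <= 0)
    while (length(bad) > 0) {
      r[bad] <- rnorm(length(bad), model$mean_radius, model$sd_radius)
      bad <- bad[r[bad] <= 0]
    }
  } else {
    r[r < 0] <- 0
  }
  r
}

#' Rectangular high-rate cluster
#'
#' A square or rectangular region in which the seeding rate is a multiple of
#' the background rate.
#'
#' @param origin `(row, col)` of the top-left pixel of the rectangle
#'   (1-based).
#' @param size `(height, width)` in pixels.
#' @param multiplier dimensionless rate factor (> 0) applied to the
#'   background per-pixel intensity inside the rectangle.
#' @return an object of class `cluster_spec`.
#' @export
cluster_spec <- function(origin, size, multiplier) {
  stopifnot(length(origin) == 2, length(size) == 2, multiplier > 0,
            all(size >= 1), all(origin >= 1))
  structure(list(origin = as.numeric(origin), size = as.numeric(size),
                 multiplier = as.numeric(multiplier)),
            class = "cluster_spec")
}

#' Default cluster geometry
#'
#' Four square clusters centred in the four image quadrants with side length
#' one fifth of the image side, carrying rate multipliers 20, 10, 5 and 2.5
#' (top-left, top-right, bottom-left, bottom-right).
#'
#' @param shape image shape `(H, W)`.
#' @param multipliers rate multipliers for the four quadrant clusters.
#' @param side cluster side length in pixels; default `round(min(shape)/5)`
#'   (512 px for a 2560 px image).
#' @return list of four [cluster_spec()] objects.
#' @export
default_clusters <- function(shape = c(2560, 2560),
                             multipliers = c(20, 10, 5, 2.5),
                             side = round(min(shape) / 5)) {
  H <- shape[1]; W <- shape[2]
  centres <- list(c(H / 4, W / 4), c(H / 4, 3 * W / 4),
                  c(3 * H / 4, W / 4), c(3 * H / 4, 3 * W / 4))
  Map(function(ctr, m) {
    cluster_spec(origin = round(c(ctr[1] - side / 2, ctr[2] - side / 2)) + 1,
                 size = c(side, side), multiplier = m)
  }, centres, as.list(multipliers))
}

#' Piecewise-constant seeding intensity field
#'
#' Builds the intensity function of the seed point process: a constant
#' background whose integral over the image equals `basal_expected_count`,
#' with the per-pixel intensity inside each cluster replaced by
#' `multiplier * background`.
#'
#' @param shape image shape `(H, W)` in pixels.
#' @param basal_expected_count expected number of background-rate seeds over
#'   the whole image.
#' @param clusters list of [cluster_spec()]; must lie within the image and be
#'   pairwise disjoint. Empty for a homogeneous (control) field.
#' @return an object of class `intensity_field` with elements `shape`,
#'   `basal_expected_count`, `clusters`, `lambda_bg` (background per-pixel
#'   intensity) and `total_expected` (integral of the field).
#' @examples
#' f <- build_intensity_field(c(2560, 2560), 40, default_clusters())
#' f$total_expected  # 40 * (1 + 0.04 * (19 + 9 + 4 + 1.5)) = 93.6
#' @export
build_intensity_field <- function(shape, basal_expected_count,
                                  clusters = list()) {
  stopifnot(length(shape) == 2, all(shape >= 1), basal_expected_count >= 0)
  H <- shape[1]; W <- shape[2]
  for (cl in clusters) {
    if (!inherits(cl, "cluster_spec")) stop("clusters must be cluster_spec objects")
    if (cl$origin[1] + cl$size[1] - 1 > H || cl$origin[2] + cl$size[2] - 1 > W)
      stop("cluster rectangle extends beyond the image bounds")
  }
  if (length(clusters) > 1) {
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ov_r <- max(a$origin[1], b$origin[1]) <=
        min(a$origin[1] + a$size[1], b$origin[1] + b$size[1]) - 1
      ov_c <- max(a$origin[2], b$origin[2]) <=
        min(a$origin[2] + a$size[2], b$origin[2] + b$size[2]) - 1
      if (ov_r && ov_c) stop("clusters overlap")
    }
  }
  lambda_bg <- basal_expected_count / (H * W)
  areas <- vapply(clusters, function(cl) prod(cl$size), numeric(1))
  mults <- vapply(clusters, function(cl) cl$multiplier, numeric(1))
  total <- basal_expected_count +
    lambda_bg * sum(areas * (mults - 1))
  structure(list(shape = c(H, W), basal_expected_count = basal_expected_count,
                 clusters = clusters, lambda_bg = lambda_bg,
                 total_expected = total),
            class = "intensity_field")
}

#' Intensity field as a dense grid
#'
#' @param field an [build_intensity_field()] object.
#' @return numeric matrix of per-pixel seeding intensity.
#' @export
intensity_grid <- function(field) {
  stopifnot(inherits(field, "intensity_field"))
  g <- matrix(field$lambda_bg, field$shape[1], field$shape[2])
  for (cl in field$clusters) {
    r <- cl$origin[1]:(cl$origin[1] + cl$size[1] - 1)
    c <- cl$origin[2]:(cl$origin[2] + cl$size[2] - 1)
    g[r, c] <- field$lambda_bg * cl$multiplier
  }
  g
}

# Binary indicator of the union of cluster rectangles.
cluster_indicator <- function(field) {
  g <- matrix(0L, field$shape[1], field$shape[2])
  for (cl in field$clusters) {
    r <- cl$origin[1]:(cl$origin[1] + cl$size[1] - 1)
    c <- cl$origin[2]:(cl$origin[2] + cl$size[2] - 1)
    g[r, c] <- 1L
  }
  g
}

#' Sample seed locations from the intensity field
#'
#' Realises the inhomogeneous Poisson point process: per constant-intensity
#' region the seed count is Poisson with mean equal to the region's intensity
#' integral, and positions are uniform within the region. Positions are
#' continuous; pixel `(i, j)` occupies `[i - 0.5, i + 0.5) x [j - 0.5,
#' j + 0.5)`.
#'
#' @param field an [build_intensity_field()] object.
#' @return two-column matrix of `(row, col)` seed coordinates (may have zero
#'   rows).
#' @export
sample_seeds <- function(field) {
  stopifnot(inherits(field, "intensity_field"))
  H <- field$shape[1]; W <- field$shape[2]
  out <- matrix(numeric(0), ncol = 2,
                dimnames = list(NULL, c("row", "col")))
  if (field$total_expected == 0) return(out)
  areas <- vapply(field$clusters, function(cl) prod(cl$size), numeric(1))
  mults <- vapply(field$clusters, function(cl) cl$multiplier, numeric(1))
  bg_integral <- field$lambda_bg * (H * W - sum(areas))
  in_any_cluster <- function(r, c) {
    inside <- rep(FALSE, length(r))
    for (cl in field$clusters) {
      inside <- inside |
        (r >= cl$origin[1] - 0.5 & r < cl$origin[1] + cl$size[1] - 0.5 &
         c >= cl$origin[2] - 0.5 & c < cl$origin[2] + cl$size[2] - 0.5)
    }
    inside
  }
  pts <- list()
  # background region: rejection sampling from the full window
  n_bg <- rpois(1, bg_integral)
  if (n_bg > 0) {
    acc_r <- numeric(0); acc_c <- numeric(0)
    while (length(acc_r) < n_bg) {
      m <- max(16, 2 * (n_bg - length(acc_r)))
      r <- runif(m, 0.5, H + 0.5); c <- runif(m, 0.5, W + 0.5)
      keep <- !in_any_cluster(r, c)
      acc_r <- c(acc_r, r[keep]); acc_c <- c(acc_c, c[keep])
    }
    pts[[length(pts) + 1]] <- cbind(acc_r[seq_len(n_bg)], acc_c[seq_len(n_bg)])
  }
  for (k in seq_along(field$clusters)) {
    cl <- field$clusters[[k]]
    n_k <- rpois(1, field$lambda_bg * mults[k] * areas[k])
    if (n_k > 0) {
      r <- runif(n_k, cl$origin[1] - 0.5, cl$origin[1] + cl$size[1] - 0.5)
      c <- runif(n_k, cl$origin[2] - 0.5, cl$origin[2] + cl$size[2] - 0.5)
      pts[[length(pts) + 1]] <- cbind(r, c)
    }
  }
  if (length(pts) == 0) return(out)
  res <- do.call(rbind, pts)
  colnames(res) <- c("row", "col")
  res
}

#' Rasterise disks around seeds
#'
#' Draws a radius for every seed from the radius model and marks a pixel as
#' foreground if its centre lies within distance `radius` of any seed
#' (pixel-centre-in-disk rule). Disks crossing the image border are clipped;
#' overlapping disks are merged (Boolean union).
#'
#' @param seeds two-column `(row, col)` matrix of seed coordinates.
#' @param model a [radius_model()].
#' @param shape image shape `(H, W)`.
#' @param radii optional fixed radii (one per seed), bypassing the model.
#' @return integer matrix with values 0/1.
#' @export
render_disks <- function(seeds, model, shape, radii = NULL) {
  H <- shape[1]; W <- shape[2]
  img <- matrix(0L, H, W)
  n <- nrow(seeds)
  if (is.null(n) || n == 0) return(img)
  if (is.null(radii)) radii <- sample_radii(n, model)
  stopifnot(length(radii) == n)
  for (k in seq_len(n)) {
    rho <- radii[k]
    if (rho <= 0) next
    sr <- seeds[k, 1]; sc <- seeds[k, 2]
    r0 <- max(1L, ceiling(sr - rho)); r1 <- min(H, floor(sr + rho))
    c0 <- max(1L, ceiling(sc - rho)); c1 <- min(W, floor(sc + rho))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - sr)^2, (cc - sc)^2, "+")
    sub <- img[rr, cc, drop = FALSE]
    sub[d2 <= rho^2] <- 1L
    img[rr, cc] <- sub
  }
  img
}

#' Simulation configuration
#'
#' Bundles the parameters of one simulation experiment: image shape, radius
#' model, basal expected seed count, cluster layout of the exacerbated group,
#' group size and RNG seed. Defaults are the benchmark conditions: 2560 x
#' 2560 px images, disk radii Gaussian with mean 7 px and sd 2 px, four
#' quadrant clusters at multipliers 20/10/5/2.5, and 10 images per group.
#'
#' @param image_shape `(H, W)` in pixels.
#' @param radius_model a [radius_model()].
#' @param basal_expected_count expected background seed count over the image
#'   (40, 80 or 160 in the benchmark experiments).
#' @param clusters cluster layout of the exacerbated group; default
#'   [default_clusters()] for `image_shape`.
#' @param n_per_group images per group (>= 2 for inference; 0 allowed and
#'   yields empty cohorts with a warning).
#' @param seed RNG seed for [simulate_cohort()]; `NULL` uses the current RNG
#'   state.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(image_shape = c(2560, 2560),
                       radius_model = markload::radius_model(),
                       basal_expected_count = 40,
                       clusters = default_clusters(image_shape),
                       n_per_group = 10,
                       seed = NULL) {
  stopifnot(basal_expected_count > 0, n_per_group >= 0)
  structure(list(image_shape = image_shape, radius_model = radius_model,
                 basal_expected_count = basal_expected_count,
                 clusters = clusters, n_per_group = n_per_group, seed = seed),
            class = "sim_config")
}

#' Simulate a two-group cohort
#'
#' Generates `n_per_group` independent Boolean-Poisson realisations for the
#' control group (homogeneous field) and for the exacerbated group (field
#' with the configured clusters). With a fixed `seed` the output is
#' bit-identical across calls; per-image sub-stream seeds are derived
#' deterministically from the cohort seed.
#'
#' @param config a [sim_config()].
#' @return list with elements `control` and `exacerbated` (lists of 0/1
#'   integer matrices), `fields` (the two intensity fields) and `image_seeds`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_per_group == 0)
    warning("n_per_group is 0: returning an empty cohort")
  field_ctrl <- build_intensity_field(config$image_shape,
                                      config$basal_expected_count)
  field_exac <- build_intensity_field(config$image_shape,
                                      config$basal_expected_count,
                                      config$clusters)
  gen <- function() {
    n <- config$n_per_group
    seeds_img <- if (n > 0) substream_seeds(2 * n) else integer(0)
    draw <- function(field, s) {
      withr::with_seed(s, {
        pts <- sample_seeds(field)
        render_disks(pts, config$radius_model, config$image_shape)
      })
    }
    ctrl <- lapply(seq_len(n), function(i) draw(field_ctrl, seeds_img[i]))
    exac <- lapply(seq_len(n), function(i) draw(field_exac, seeds_img[n + i]))
    list(control = ctrl, exacerbated = exac, image_seeds = seeds_img)
  }
  res <- if (is.null(config$seed)) gen() else withr::with_seed(config$seed, gen())
  res$fields <- list(control = field_ctrl, exacerbated = field_exac)
  res
}

#' True marker load (coverage probability) of the Boolean model
#'
#' The probability that a pixel is covered by at least one disk,
#' `mu(x) = 1 - exp(-integral of lambda(y) P(R >= |x - y|) dy)`. For a
#' homogeneous field with per-pixel intensity `lambda` this is
#' `1 - exp(-lambda * pi * E[R^2])`. The integral is evaluated as a lattice
#' convolution of the intensity grid with the radius survival function,
#' normalised so the homogeneous interior matches the closed form exactly;
#' zero padding reflects the absence of seeds outside the image (the
#' renderer's border clipping).
#'
#' @param field an [build_intensity_field()] object.
#' @param model a [radius_model()].
#' @return numeric matrix of coverage probabilities in `[0, 1]`.
#' @export
true_marker_load <- function(field, model) {
  stopifnot(inherits(field, "intensity_field"), inherits(model, "radius_model"))
  H <- field$shape[1]; W <- field$shape[2]
  if (field$total_expected == 0) return(matrix(0, H, W))
  rad <- ceiling(model$mean_radius + max(5 * model$sd_radius, 1))
  off <- -rad:rad
  kern <- radius_survival(model, sqrt(outer(off^2, off^2, "+")))
  # normalise lattice mass to the continuous mass pi * E[R^2]
  kern <- kern * (pi * radius_mean_square(model) / sum(kern))
  A <- conv2_fft(intensity_grid(field), kern)
  pmin(pmax(1 - exp(-A), 0), 1)
}

# Zero-padded linear convolution via FFT; k must have odd dimensions and the
# output is aligned to x's grid (kernel centred).
conv2_fft <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  kh <- nrow(k); kw <- ncol(k)
  ph <- next_good_size(H + kh - 1L)
  pw <- next_good_size(W + kw - 1L)
  X <- matrix(0, ph, pw); X[1:H, 1:W] <- x
  K <- matrix(0, ph, pw); K[1:kh, 1:kw] <- k
  Y <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / (ph * pw)
  r0 <- (kh + 1L) %/% 2L
  c0 <- (kw + 1L) %/% 2L
  Y[r0:(r0 + H - 1L), c0:(c0 + W - 1L)]
}

#' Mean squared error of an estimated map against the true load
#'
#' The full-resolution truth is aggregated to the estimate's resolution by
#' window averaging before squared differences are taken.
#'
#' @param estimate a [parametric_map] or a numeric matrix at map resolution.
#' @param truth full-resolution true-load matrix, or a matrix already at map
#'   resolution.
#' @param bin_window aggregation window; taken from `estimate` when it is a
#'   `parametric_map`.
#' @return scalar mean squared error.
#' @export
mse_to_truth <- function(estimate, truth, bin_window = NULL) {
  if (inherits(estimate, "parametric_map")) {
    bin_window <- bin_window %||% estimate$bin_window
    est <- estimate$grid
  } else est <- estimate
  if (!identical(dim(est), dim(truth))) {
    if (is.null(bin_window))
      stop("bin_window needed to aggregate the truth to map resolution")
    truth <- bin_image(truth, bin_window)$grid
  }
  if (!identical(dim(est), dim(truth)))
    stop("estimate and aggregated truth have different shapes")
  mean((est - truth)^2)
}
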