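# Parametric map generation: binning, Voronoi tessellation and Gaussian
# smoothing estimators of the local marker load, plus out-of-bag bootstrap
# selection of the Gaussian kernel standard deviation.

new_parametric_map <- function(grid, bin_window, estimator, sigma = NULL,
                               source_id = NULL) {
  structure(list(grid = grid, bin_window = bin_window, estimator = estimator,
                 sigma = sigma, source_id = source_id),
            class = "parametric_map")
}

#' @export
as.matrix.parametric_map <- function(x, ...) x$grid

#' @export
print.parametric_map <- function(x, ...) {
  cat("<parametric_map> ", paste(dim(x$grid), collapse = " x "),
      " (", x$estimator,
      if (!is.null(x$sigma)) sprintf(", sigma = %.3g", x$sigma) else "",
      ", window ", paste(x$bin_window, collapse = "x"), ")\n", sep = "")
  invisible(x)
}

#' Window binning
#'
#' Reduces resolution by averaging non-overlapping windows. Boundary windows
#' smaller than `bin_window` average over their actual voxel count, so no
#' tissue is discarded when the window does not divide the image shape.
#' `NA` voxels (e.g. outside a mask) are excluded from the window mean.
#'
#' @param image 2D matrix or 3D array.
#' @param bin_window window size `(h, w)` or `(h, w, d)` in voxels; a scalar
#'   is recycled.
#' @return a [parametric_map] with grid shape `ceiling(dim(image) /
#'   bin_window)`.
#' @examples
#' as.matrix(bin_image(matrix(c(1, 0, 0, 0), 2, 2), c(2, 2)))  # 0.25
#' @export
bin_image <- function(image, bin_window = c(18, 18)) {
  d <- img_dim(image)
  if (length(bin_window) == 1) bin_window <- rep(bin_window, length(d))
  if (length(bin_window) != length(d))
    stop("bin_window must match the image dimensionality")
  bin_window <- as.integer(bin_window)
  if (any(bin_window < 1)) stop("bin window dimensions must be positive")
  if (any(bin_window > d)) stop("bin window larger than the image")
  agg_rows <- function(m, b) {
    # m: matrix aggregated along rows in blocks of b (NA-aware mean numerator
    # and denominator returned separately)
    g <- (seq_len(nrow(m)) - 1L) %/% b + 1L
    if (anyNA(m)) {
      na <- is.na(m)
      m[na] <- 0
      num <- rowsum(m, g, reorder = TRUE)
      den <- rowsum((!na) * 1, g, reorder = TRUE)
    } else {
      num <- rowsum(m, g, reorder = TRUE)
      den <- matrix(tabulate(g), nrow(num), ncol(m))
    }
    list(num = num, den = den)
  }
  if (length(d) == 2) {
    a <- agg_rows(image, bin_window[1])
    num <- t(rowsum(t(a$num), (seq_len(d[2]) - 1L) %/% bin_window[2] + 1L))
    den <- t(rowsum(t(a$den), (seq_len(d[2]) - 1L) %/% bin_window[2] + 1L))
    grid <- num / den
    grid[den == 0] <- NA_real_
  } else if (length(d) == 3) {
    nb <- ceiling(d / bin_window)
    num <- array(0, nb); den <- array(0, nb)
    gz <- (seq_len(d[3]) - 1L) %/% bin_window[3] + 1L
    for (z in seq_len(d[3])) {
      a <- agg_rows(image[, , z], bin_window[1])
      g2 <- (seq_len(d[2]) - 1L) %/% bin_window[2] + 1L
      num[, , gz[z]] <- num[, , gz[z]] + t(rowsum(t(a$num), g2))
      den[, , gz[z]] <- den[, , gz[z]] + t(rowsum(t(a$den), g2))
    }
    grid <- num / den
    grid[den == 0] <- NA_real_
  } else stop("only 2D and 3D images are supported")
  dimnames(grid) <- NULL
  new_parametric_map(grid, bin_window, "binning")
}

#' Gaussian kernel smoothing
#'
#' Convolution with a unit-sum truncated Gaussian kernel (separable, zero
#' padding). With a mask, the smoothed image is renormalised by the smoothed
#' mask so values remain unbiased near mask borders; voxels outside the mask
#' are returned as `NA`.
#'
#' @param image 2D matrix or 3D array.
#' @param sigma kernel standard deviation in voxels; scalar, or one value per
#'   axis for anisotropic smoothing (0 along an axis disables smoothing on
#'   that axis in 3D).
#' @param mask optional logical array of the same shape.
#' @param truncate kernel support half-width in units of sigma.
#' @return numeric array of the same shape as `image`.
#' @export
gaussian_smooth <- function(image, sigma, mask = NULL, truncate = 3) {
  d <- img_dim(image)
  stopifnot(all(sigma >= 0), any(sigma > 0))
  run <- function(x) {
    if (length(d) == 2) {
      s <- if (length(sigma) == 1) c(sigma, sigma) else sigma
      cpp_sep_gauss2d(x, s[1], s[2], truncate)
    } else {
      s <- if (length(sigma) == 1) rep(sigma, 3) else sigma
      array(cpp_sep_gauss3d(as.numeric(x), as.integer(d), as.numeric(s),
                            truncate), d)
    }
  }
  storage.mode(image) <- "double"
  if (is.null(mask)) return(run(image))
  m <- array(as.numeric(mask), d)
  out <- run(image * m) / run(m)
  out[m == 0] <- NA_real_
  out
}

#' Voronoi tessellation load estimator
#'
#' Connected foreground components are reduced to their centroids; the plane
#' is partitioned into the Voronoi cells of the centroids, and every voxel of
#' a cell is assigned load = component voxel count / cell voxel count.
#' An image with no foreground yields an all-zero map; a single object yields
#' one cell spanning the whole image. Loads are capped at 1.
#'
#' @param image binary 2D matrix.
#' @param connectivity component connectivity, 4 or 8.
#' @return numeric matrix of local load estimates.
#' @export
voronoi_load <- function(image, connectivity = 8) {
  d <- img_dim(image)
  if (length(d) != 2) stop("the Voronoi estimator is defined for 2D images")
  storage.mode(image) <- "integer"
  lab <- cpp_label2d(image, as.integer(connectivity))
  K <- max(lab)
  if (K == 0) return(matrix(0, d[1], d[2]))
  st <- cpp_label_stats(lab, K)
  sizes <- st[, 1]
  cr <- st[, 2] / sizes
  cc <- st[, 3] / sizes
  # merge components whose centroids coincide exactly (shared cell)
  key <- paste(cr, cc)
  if (anyDuplicated(key)) {
    grp <- match(key, key)
    sizes <- as.vector(rowsum(sizes, grp)[as.character(sort(unique(grp))), ])
    keep <- sort(unique(grp))
    cr <- cr[keep]; cc <- cc[keep]
  }
  cell <- cpp_nearest_site(cr, cc, d[1], d[2])
  cell_sizes <- tabulate(cell, nbins = length(cr))
  load <- sizes / cell_sizes
  matrix(pmin(load[cell], 1), d[1], d[2])
}

#' Parametric map estimation
#'
#' Converts one high-resolution binary image into a low-resolution marker
#' load map: `"binning"` averages windows of the raw image,
#' `"voronoi_binning"` applies [voronoi_load()] then binning, and
#' `"gaussian_binning"` applies [gaussian_smooth()] then binning (computed by
#' an exact sparse shortcut for unmasked binary 2D images).
#'
#' @param image binary 2D matrix or 3D array.
#' @param estimator one of `"binning"`, `"voronoi_binning"`,
#'   `"gaussian_binning"`.
#' @param sigma Gaussian kernel sd in voxels (required for
#'   `"gaussian_binning"`).
#' @param bin_window binning window, see [bin_image()].
#' @param mask optional logical array.
#' @param source_id identifier recorded in the map's provenance.
#' @param truncate Gaussian kernel support half-width in sigmas.
#' @return a [parametric_map].
#' @export
estimate_map <- function(image,
                         estimator = c("binning", "voronoi_binning",
                                       "gaussian_binning"),
                         sigma = NULL, bin_window = c(18, 18), mask = NULL,
                         source_id = NULL, truncate = 3) {
  estimator <- match.arg(estimator)
  d <- img_dim(image)
  if (length(bin_window) == 1) bin_window <- rep(bin_window, length(d))
  pm <- switch(estimator,
    binning = bin_image(if (is.null(mask)) image else
      replace(array(as.numeric(image), d), !mask, NA_real_), bin_window),
    voronoi_binning = bin_image(voronoi_load(image), bin_window),
    gaussian_binning = {
      if (is.null(sigma)) stop("sigma is required for gaussian_binning")
      if (is.null(mask) && length(d) == 2 && length(sigma) == 1 &&
          is_binary_image(image)) {
        fg <- fg_coords(image)
        grid <- cpp_gauss_binned_sparse(fg$r, fg$c, d[1], d[2], sigma,
                                        truncate, bin_window[1], bin_window[2])
        new_parametric_map(grid, bin_window, "gaussian_binning")
      } else {
        bin_image(gaussian_smooth(image, sigma, mask, truncate), bin_window)
      }
    })
  pm$estimator <- estimator
  pm$sigma <- sigma
  pm$source_id <- source_id
  pm
}

#' Out-of-bag bootstrap error of the smoothed-map sample mean
#'
#' Draws `n_bootstrap` bootstrap samples of individuals with replacement.
#' For each individual j, the voxel-mean squared difference between the
#' bootstrap sample mean of smoothed images and j's raw binary image is
#' averaged over the samples that do not contain j, then over individuals.
#' Individuals contained in every sample are skipped (with the divisor
#' reduced accordingly); if no individual has an out-of-bag sample an error
#' is raised.
#'
#' @param images list of binary images (identical shapes).
#' @param sigma Gaussian kernel sd in voxels.
#' @param n_bootstrap number of bootstrap samples.
#' @param mask optional logical array; voxels outside the mask are excluded
#'   from the voxel mean.
#' @param stride evaluate the voxel mean on a regular subgrid with this
#'   stride (1 = every voxel, as defined; larger values subsample for speed).
#' @param boot_samples optional integer matrix (`n_bootstrap` rows, one
#'   column per individual) of pre-specified bootstrap index draws, e.g. the
#'   exhaustive enumeration for small cohorts.
#' @param truncate Gaussian kernel support half-width in sigmas.
#' @return scalar bootstrap error.
#' @export
bootstrap_error <- function(images, sigma, n_bootstrap = 500, mask = NULL,
                            stride = 1, boot_samples = NULL, truncate = 3) {
  T_n <- length(images)
  stopifnot(T_n >= 2, sigma > 0)
  d <- img_dim(images[[1]])
  for (im in images) if (!identical(img_dim(im), d))
    stop("all images must share the same shape")
  if (is.null(boot_samples)) {
    stopifnot(n_bootstrap >= 1)
    boot_samples <- matrix(sample.int(T_n, n_bootstrap * T_n, replace = TRUE),
                           nrow = n_bootstrap)
  } else {
    boot_samples <- as.matrix(boot_samples)
    stopifnot(all(boot_samples >= 1), all(boot_samples <= T_n))
  }
  B <- nrow(boot_samples)
  off <- (stride + 1L) %/% 2L
  eval_grids <- smoothed_eval_values(images, sigma, mask, stride, off, truncate)
  Smat <- eval_grids$S   # nvox_eval x T (smoothed)
  Mmat <- eval_grids$M   # nvox_eval x T (raw)
  nv <- nrow(Smat)
  A <- crossprod(Smat) / nv
  Bm <- crossprod(Smat, Mmat) / nv
  m2 <- colMeans(Mmat^2)
  Cnt <- matrix(0L, T_n, B)
  for (b in seq_len(B))
    Cnt[, b] <- tabulate(boot_samples[b, ], nbins = T_n)
  Cnt <- matrix(as.numeric(Cnt), T_n, B)
  q_b <- colSums((A %*% Cnt) * Cnt) / T_n^2          # mean(mu_b^2) per sample
  c_bj <- t(Cnt) %*% Bm / T_n                         # B x T: mean(mu_b * M_j)
  errs <- numeric(0)
  for (j in seq_len(T_n)) {
    oob <- which(Cnt[j, ] == 0)
    if (length(oob) == 0) next
    errs <- c(errs, mean(q_b[oob] - 2 * c_bj[oob, j] + m2[j]))
  }
  if (length(errs) == 0)
    stop("no out-of-bag samples: every individual appears in every bootstrap sample")
  mean(errs)
}

# Smoothed and raw image values on the evaluation subgrid, as columns.
smoothed_eval_values <- function(images, sigma, mask, stride, off, truncate) {
  d <- img_dim(images[[1]])
  T_n <- length(images)
  use_sparse <- is.null(mask) && length(d) == 2 &&
    all(vapply(images, function(im)
      inherits(im, "sparse_binary_image") || is_binary_image(im), logical(1)))
  if (use_sparse) {
    nr <- (d[1] - off) %/% stride + 1L
    nc <- (d[2] - off) %/% stride + 1L
    S <- matrix(0, nr * nc, T_n)
    M <- matrix(0, nr * nc, T_n)
    for (k in seq_len(T_n)) {
      sp <- as_sparse_binary(images[[k]])
      S[, k] <- cpp_gauss_strided_sparse(sp$r, sp$c, d[1], d[2], sigma,
                                         truncate, stride, off)
      on_grid <- (sp$r - off) %% stride == 0L & (sp$c - off) %% stride == 0L &
        sp$r >= off & sp$c >= off
      lin <- (sp$r[on_grid] - off) %/% stride + 1L +
        ((sp$c[on_grid] - off) %/% stride) * nr
      M[lin, k] <- 1
    }
  } else {
    idx_list <- lapply(d, function(n) seq.int(off, n, by = stride))
    sel <- as.matrix(expand.grid(idx_list))
    keep <- if (is.null(mask)) rep(TRUE, nrow(sel)) else mask[sel] != 0
    sel <- sel[keep, , drop = FALSE]
    S <- matrix(0, nrow(sel), T_n)
    M <- matrix(0, nrow(sel), T_n)
    for (k in seq_len(T_n)) {
      sm <- gaussian_smooth(images[[k]], sigma, mask, truncate)
      S[, k] <- sm[sel]
      M[, k] <- as.numeric(images[[k]][sel])
    }
  }
  list(S = S, M = M)
}

#' Gaussian kernel selection by bootstrap error minimisation
#'
#' Computes the bootstrap error curve of [bootstrap_error()] for each
#' experimental group separately and selects the kernel standard deviation
#' minimising the mean curve across groups; ties are broken toward the
#' smaller sigma. Within a group the same bootstrap draws are reused across
#' candidate sigmas (common random numbers).
#'
#' @param groups named list of image lists, one per experimental group.
#' @param sigmas increasing vector of candidate kernel sds (voxels), e.g.
#'   [sigma_grid()].
#' @param n_bootstrap bootstrap samples per group.
#' @param mask,stride,truncate passed to [bootstrap_error()].
#' @return an object of class `bootstrap_error_curve` with elements `sigmas`,
#'   `errors` (matrix, one column per group), `mean_error`, `selected_sigma`
#'   and `n_bootstrap`.
#' @export
select_kernel <- function(groups, sigmas = sigma_grid(), n_bootstrap = 500,
                          mask = NULL, stride = 1, truncate = 3) {
  stopifnot(length(groups) >= 1, length(sigmas) >= 2)
  sigmas <- sort(sigmas)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  errors <- matrix(NA_real_, length(sigmas), length(groups),
                   dimnames = list(NULL, names(groups)))
  for (g in seq_along(groups)) {
    imgs <- groups[[g]]
    T_n <- length(imgs)
    d <- img_dim(imgs[[1]])
    if (is.null(mask) && length(d) == 2 &&
        all(vapply(imgs, function(im) inherits(im, "sparse_binary_image") ||
                     is_binary_image(im), logical(1))))
      imgs <- lapply(imgs, as_sparse_binary)   # scan each image only once
    draws <- matrix(sample.int(T_n, n_bootstrap * T_n, replace = TRUE),
                    nrow = n_bootstrap)
    for (s in seq_along(sigmas)) {
      errors[s, g] <- bootstrap_error(imgs, sigmas[s], mask = mask,
                                      stride = stride, boot_samples = draws,
                                      truncate = truncate)
    }
  }
  mean_error <- rowMeans(errors)
  structure(list(sigmas = sigmas, errors = errors, mean_error = mean_error,
                 selected_sigma = sigmas[which.min(mean_error)],
                 n_bootstrap = n_bootstrap),
            class = "bootstrap_error_curve")
}

#' @export
print.bootstrap_error_curve <- function(x, ...) {
  cat("<bootstrap_error_curve> ", length(x$sigmas), " candidate sigmas, ",
      ncol(x$errors), " group(s), B = ", x$n_bootstrap, "\n", sep = "")
  cat("selected sigma:", format(x$selected_sigma, digits = 4), "voxels\n")
  invisible(x)
}

#' True-error curve of the Gaussian estimator
#'
#' Mean squared error between the group-mean gaussian-binned map and the
#' aggregated true load, per candidate sigma. Used to validate bootstrap
#' kernel selection on simulated cohorts where the truth is known.
#'
#' @param images list of binary images (one group).
#' @param truth full-resolution true-load matrix.
#' @param sigmas candidate kernel sds.
#' @param bin_window binning window.
#' @param truncate kernel support half-width in sigmas.
#' @return numeric vector of true errors, one per sigma.
#' @export
true_error_curve <- function(images, truth, sigmas, bin_window = c(18, 18),
                             truncate = 3) {
  truth_map <- bin_image(truth, bin_window)$grid
  vapply(sigmas, function(s) {
    maps <- lapply(images, estimate_map, estimator = "gaussian_binning",
                   sigma = s, bin_window = bin_window, truncate = truncate)
    mse_to_truth(Reduce(`+`, lapply(maps, as.matrix)) / length(maps),
                 truth_map)
  }, numeric(1))
}
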