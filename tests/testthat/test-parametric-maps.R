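# Map estimators: binning, Gaussian smoothing, Voronoi tessellation, and the
# bootstrap error / kernel selection machinery.

test_that("binning averages windows, handles partial windows and conserves the mean", {
  expect_equal(as.matrix(bin_image(matrix(c(1, 0, 0, 0), 2, 2), c(2, 2))),
               matrix(0.25, 1, 1))
  ones <- matrix(1, 20, 20)
  expect_true(all(as.matrix(bin_image(ones, c(7, 7))) == 1))

  # 2560 = 142 * 18 + 4: 143 bins, last row/col from 4-voxel-wide windows
  x <- matrix(rnorm(2560 * 40), 2560, 40)
  b <- bin_image(x, c(18, 18))
  expect_identical(dim(b$grid), c(143L, 3L))
  expect_equal(b$grid[143, 1], mean(x[2557:2560, 1:18]))

  # exact mean conservation when the window divides the shape
  y <- matrix(rnorm(36 * 54), 36, 54)
  expect_equal(mean(as.matrix(bin_image(y, c(18, 18)))), mean(y))
  # weighted conservation otherwise
  bz <- bin_image(x, c(18, 18))
  w <- outer(c(rep(18, 142), 4), c(rep(18, 2), 4))
  expect_equal(sum(bz$grid * w) / sum(w), mean(x), tolerance = 1e-12)

  expect_error(bin_image(matrix(0, 4, 4), c(5, 5)), "larger")
  # 3D binning with an 18x18x1-style window
  v <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  b3 <- bin_image(v, c(6, 6, 1))
  expect_identical(dim(b3$grid), c(2L, 2L, 3L))
  expect_equal(b3$grid[1, 1, 2], mean(v[1:6, 1:6, 2]))
})

test_that("gaussian smoothing equals brute-force convolution and conserves mass", {
  withr::local_seed(5)
  x <- matrix(0, 9, 9); x[5, 5] <- 1
  expect_lt(max(abs(gaussian_smooth(x, 1) - brute_gauss(x, 1))), 1e-10)
  for (sg in c(0.7, 1.6, 2.3)) {
    y <- matrix(runif(11 * 13), 11, 13)
    expect_lt(max(abs(gaussian_smooth(y, sg) - brute_gauss(y, sg))), 1e-10)
  }
  # interior point mass is conserved
  z <- matrix(0, 41, 41); z[21, 21] <- 1
  expect_equal(sum(gaussian_smooth(z, 3)), 1, tolerance = 1e-8)
  # constant image stays ~1 in the interior
  expect_equal(gaussian_smooth(matrix(1, 31, 31), 2)[16, 16], 1,
               tolerance = 1e-12)
  # 3D separable smoothing agrees with smoothing each slice when sigma_z = 0
  v <- array(runif(9 * 9 * 3), c(9, 9, 3))
  s3 <- gaussian_smooth(v, c(1.2, 1.2, 0))
  for (k in 1:3)
    expect_equal(s3[, , k], gaussian_smooth(v[, , k], 1.2), tolerance = 1e-12)
})

test_that("mask-renormalised smoothing is unbiased near mask borders", {
  x <- matrix(1, 30, 30)
  mask <- matrix(FALSE, 30, 30); mask[1:30, 1:15] <- TRUE
  s <- gaussian_smooth(x, 3, mask = mask)
  expect_true(all(abs(s[, 1:15] - 1) < 1e-10))
  expect_true(all(is.na(s[, 16:30])))
})

test_that("voronoi load matches nearest-centroid partition oracles", {
  expect_true(all(voronoi_load(matrix(0L, 40, 40)) == 0))
  # a single object: one cell spanning the whole image
  img <- render_disks(matrix(c(60, 60), 1, 2), radius_model(), c(200, 200),
                      radii = 7)
  v <- voronoi_load(img)
  expect_equal(unique(as.vector(v)), 149 / 200^2)
  # two equal disks in the left/right halves -> two half-plane cells
  img2 <- render_disks(rbind(c(50, 25), c(50, 75)), radius_model(),
                       c(100, 100), radii = c(5, 5))
  v2 <- voronoi_load(img2)
  area <- sum(img2) / 2
  expect_equal(unique(as.vector(v2[, 1:49])), area / (100 * 50))
  expect_equal(unique(as.vector(v2[, 52:100])), area / (100 * 50))
  # partition agrees with the brute-force assignment away from tie lines
  withr::local_seed(8)
  for (rep in 1:5) {
    H <- 17; W <- 23
    sr <- runif(6, 1, H); sc <- runif(6, 1, W)
    fast <- markload:::cpp_nearest_site(sr, sc, H, W)
    slow <- brute_nearest(sr, sc, H, W)
    d2 <- function(i, j, s) (i - sr[s])^2 + (j - sc[s])^2
    for (i in seq_len(H)) for (j in seq_len(W))
      expect_equal(d2(i, j, fast[i, j]), d2(i, j, slow[i, j]), tolerance = 1e-12)
  }
})

test_that("estimate_map composes the estimator pipelines", {
  withr::local_seed(6)
  x <- rand_binary(90, 90, 0.05)
  expect_equal(estimate_map(x, "binning")$grid, bin_image(x, c(18, 18))$grid)
  expect_equal(estimate_map(x, "voronoi_binning")$grid,
               bin_image(voronoi_load(x), c(18, 18))$grid)
  # the sparse shortcut equals smooth-then-bin exactly
  m1 <- estimate_map(x, "gaussian_binning", sigma = 4)
  m2 <- bin_image(gaussian_smooth(x, 4), c(18, 18))
  expect_lt(max(abs(m1$grid - m2$grid)), 1e-12)
  # sigma -> 0 converges to plain binning
  m0 <- estimate_map(x, "gaussian_binning", sigma = 0.1)
  expect_lt(max(abs(m0$grid - estimate_map(x, "binning")$grid)), 1e-6)
  expect_error(estimate_map(x, "gaussian_binning"), "sigma")
  # all estimators stay within [0, 1]
  for (est in c("binning", "voronoi_binning", "gaussian_binning")) {
    g <- estimate_map(x, est, sigma = 3)$grid
    expect_true(all(g >= 0 & g <= 1))
  }
})

test_that("bootstrap error matches exhaustive enumeration and plug-in cases", {
  # all-zero images: zero error at any sigma
  zero <- list(matrix(0L, 8, 8), matrix(0L, 8, 8), matrix(0L, 8, 8))
  expect_equal(bootstrap_error(zero, sigma = 2, n_bootstrap = 30), 0)

  # T = 2 one-voxel images {0, 1}, enumerated over all 4 bootstrap samples:
  # C_{-1} = {(2,2)} with error (1-0)^2 = 1; C_{-2} = {(1,1)} with (0-1)^2 = 1
  imgs <- list(matrix(0, 1, 1), matrix(1, 1, 1))
  all_samples <- as.matrix(expand.grid(1:2, 1:2))
  expect_equal(bootstrap_error(imgs, sigma = 1e-3, boot_samples = all_samples),
               1)

  # identical non-constant images: pure smoothing bias, no variance term
  withr::local_seed(10)
  x <- rand_binary(30, 30, 0.2)
  expect_equal(bootstrap_error(list(x, x, x), sigma = 2, n_bootstrap = 40),
               mean((gaussian_smooth(x, 2) - x)^2))

  # every individual in every sample -> no out-of-bag error
  expect_error(bootstrap_error(imgs, sigma = 1,
                               boot_samples = matrix(c(1, 2), 1, 2)),
               "out-of-bag")

  # the strided sparse evaluation grid equals dense smoothing subsampled
  y <- rand_binary(40, 52, 0.1)
  fg <- markload:::fg_coords(y)
  for (stride in c(1L, 3L)) {
    off <- (stride + 1L) %/% 2L
    S <- markload:::cpp_gauss_strided_sparse(fg$r, fg$c, 40L, 52L, 2.5, 3,
                                             stride, off)
    D <- gaussian_smooth(y, 2.5)[seq(off, 40, stride), seq(off, 52, stride)]
    expect_lt(max(abs(S - D)), 1e-12)
  }
})

test_that("bootstrap error is reproducible across seeds within MC error", {
  withr::local_seed(11)
  imgs <- replicate(6, rand_binary(60, 60, 0.08), simplify = FALSE)
  e1 <- bootstrap_error(imgs, sigma = 3, n_bootstrap = 2000)
  e2 <- bootstrap_error(imgs, sigma = 3, n_bootstrap = 2000)
  expect_lt(abs(e1 - e2) / e1, 0.05)
})

test_that("kernel selection minimises the mean group curve with low-sigma ties", {
  const <- replicate(3, matrix(0L, 12, 12), simplify = FALSE)
  withr::local_seed(12)
  curve <- select_kernel(list(a = const), sigmas = c(1, 2, 4),
                         n_bootstrap = 30)
  expect_true(all(curve$errors >= 0))
  expect_equal(max(curve$mean_error), 0)  # identical constant images
  expect_equal(curve$selected_sigma, 1)   # tie broken toward the smaller sigma
  expect_identical(dim(curve$errors), c(3L, 1L))
})
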