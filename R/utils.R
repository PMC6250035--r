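# Internal helpers shared across modules.

# Image dimensions treating a matrix as 2D and an array as 3D.
img_dim <- function(x) {
  if (inherits(x, "sparse_binary_image")) return(x$dim)
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array image", call. = FALSE)
  d
}

# Compact coordinate representation of a 2D binary image; avoids rescanning
# large images when the same cohort is smoothed at many kernel widths.
as_sparse_binary <- function(image) {
  if (inherits(image, "sparse_binary_image")) return(image)
  fg <- fg_coords(image)
  structure(list(r = fg$r, c = fg$c, dim = dim(image)),
            class = "sparse_binary_image")
}

is_binary_image <- function(x) {
  v <- as.vector(x)
  all(v == 0 | v == 1)
}

# Foreground coordinates (row, col) of a 2D binary image.
fg_coords <- function(x) {
  idx <- which(x != 0)
  H <- nrow(x)
  list(r = ((idx - 1L) %% H) + 1L, c = ((idx - 1L) %/% H) + 1L)
}

# Smallest 7-smooth integer >= n (efficient FFT length).
next_good_size <- function(n) {
  is_smooth <- function(m) {
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    m == 1L
  }
  m <- as.integer(n)
  while (!is_smooth(m)) m <- m + 1L
  m
}

# Geometric grid of candidate Gaussian kernel standard deviations (voxels).
#' Candidate kernel grid
#'
#' Geometric grid of candidate Gaussian kernel standard deviations, in
#' voxels, for [select_kernel()].
#'
#' @param from,to smallest and largest candidate sd (voxels).
#' @param n number of candidates.
#' @return numeric vector of length `n`, increasing.
#' @export
sigma_grid <- function(from = 2, to = 64, n = 10) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}

# Draw independent sub-stream seeds (31-bit) from the current RNG.
substream_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
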