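# Independent brute-force oracles used to check the optimised implementations.

# O(n^2) direct convolution with a unit-sum truncated Gaussian, zero padding.
brute_gauss <- function(x, sigma, truncate = 3) {
  rad <- max(1, ceiling(truncate * sigma))
  taps <- exp(-0.5 * (-rad:rad)^2 / sigma^2)
  taps <- taps / sum(taps)
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (di in -rad:rad) for (dj in -rad:rad) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + taps[di + rad + 1] * taps[dj + rad + 1] * x[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Recursive flood fill connected-component labelling (4- or 8-connectivity).
flood_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 4) cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
        else as.matrix(expand.grid(-1:1, -1:1))[-5, ]
  k <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] > 0) next
    k <- k + 1L
    stack <- list(c(i, j)); lab[i, j] <- k
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (q in seq_len(nrow(nb))) {
        ii <- p[1] + nb[q, 1]; jj <- p[2] + nb[q, 2]
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            mask[ii, jj] != 0 && lab[ii, jj] == 0L) {
          lab[ii, jj] <- k
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Same partition of foreground pixels into components?
same_partition <- function(l1, l2) {
  f <- which(l1 > 0)
  if (!identical(which(l2 > 0), f)) return(FALSE)
  identical(as.integer(match(l1[f], unique(l1[f]))),
            as.integer(match(l2[f], unique(l2[f]))))
}

# Brute-force nearest-centroid assignment (index of nearest site).
brute_nearest <- function(site_r, site_c, H, W) {
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    d2 <- (i - site_r)^2 + (j - site_c)^2
    out[i, j] <- which.min(d2)
  }
  out
}

# Lattice disk pixel count by enumeration.
brute_disk_pixels <- function(centre, radius, H, W) {
  co <- expand.grid(r = seq_len(H), c = seq_len(W))
  sum((co$r - centre[1])^2 + (co$c - centre[2])^2 <= radius^2)
}

rand_binary <- function(H, W, p = 0.3) {
  matrix((runif(H * W) < p) * 1L, H, W)
}
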