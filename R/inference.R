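# Voxel-wise group comparison of parametric maps, cluster extraction,
# permutation cluster-mass correction and F1 evaluation against ground truth.

map_grids <- function(maps) {
  lapply(maps, function(m) if (inherits(m, "parametric_map")) m$grid else m)
}

# Pooled (or Welch) two-sample t from per-group moments; returns list(t, p).
t_from_moments <- function(ma, va, na, mb, vb, nb, var_equal = TRUE) {
  if (var_equal) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se2a <- va / na; se2b <- vb / nb
    se <- sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
    df[!is.finite(df)] <- na + nb - 2
  }
  tt <- (ma - mb) / se
  zero <- se == 0
  equal <- zero & (ma == mb)
  tt[equal] <- 0
  tt[zero & !equal] <- sign(ma - mb)[zero & !equal] * Inf
  p <- 2 * pt(-abs(tt), df)
  p[equal] <- 1
  list(t = tt, p = p, df = df)
}

#' Voxel-wise two-sample t-test map
#'
#' Computes, at every voxel, the two-tailed two-sample Student t statistic
#' (pooled variance by default, `df = n_a + n_b - 2`) comparing the marker
#' load between two groups of maps. Voxels with zero pooled variance and
#' equal means get `t = 0`, `p = 1`.
#'
#' @param maps_a,maps_b lists of [parametric_map]s or numeric arrays, one per
#'   individual, all with the same shape; at least 2 per group.
#' @param var_equal pooled variance (classical Student) if `TRUE`, Welch
#'   otherwise.
#' @return an object of class `stat_map` with elements `t`, `p` (arrays),
#'   `df` and `group_sizes`.
#' @examples
#' a <- lapply(c(1, 2, 3), function(v) matrix(v, 1, 1))
#' b <- lapply(c(4, 5, 6), function(v) matrix(v, 1, 1))
#' s <- tstat_map(a, b)
#' c(s$t, s$p)  # -3.674, 0.0213
#' @export
tstat_map <- function(maps_a, maps_b, var_equal = TRUE) {
  ga <- map_grids(maps_a); gb <- map_grids(maps_b)
  na <- length(ga); nb <- length(gb)
  stopifnot(na >= 2, nb >= 2)
  d <- img_dim(ga[[1]])
  for (g in c(ga, gb)) if (!identical(img_dim(g), d))
    stop("all maps must share the same shape")
  Xa <- matrix(vapply(ga, as.numeric, numeric(prod(d))), nrow = prod(d))
  Xb <- matrix(vapply(gb, as.numeric, numeric(prod(d))), nrow = prod(d))
  ma <- rowMeans(Xa); mb <- rowMeans(Xb)
  va <- rowSums((Xa - ma)^2) / (na - 1)
  vb <- rowSums((Xb - mb)^2) / (nb - 1)
  res <- t_from_moments(ma, va, na, mb, vb, nb, var_equal)
  structure(list(t = array(res$t, d), p = array(res$p, d),
                 df = if (var_equal) na + nb - 2 else array(res$df, d),
                 group_sizes = c(na, nb), var_equal = var_equal),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> ", paste(dim(x$t), collapse = " x "),
      ", groups ", paste(x$group_sizes, collapse = " vs "),
      ", df = ", if (length(x$df) == 1) x$df else "per-voxel (Welch)",
      "\n", sep = "")
  invisible(x)
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("<permutation_null> ", x$n_perm, " permutations, alpha = ", x$alpha,
      ", mass threshold = ", format(x$threshold, digits = 4), "\n", sep = "")
  invisible(x)
}

default_connectivity <- function(d) if (length(d) == 2) 8L else 26L

label_components <- function(mask, connectivity) {
  d <- img_dim(mask)
  storage.mode(mask) <- "integer"
  if (length(d) == 2) {
    cpp_label2d(mask, as.integer(connectivity))
  } else {
    array(cpp_label3d(as.integer(mask), as.integer(d),
                      as.integer(connectivity)), d)
  }
}

#' Extract suprathreshold clusters
#'
#' Thresholds the p-value map at `alpha` and partitions suprathreshold
#' voxels into connected components, separately for positive and negative t
#' (adjacent voxels of opposite sign never join). Cluster mass is the sum of
#' `|t|` over member voxels.
#'
#' @param stat_map a [tstat_map()] result.
#' @param alpha cluster-forming threshold on the voxel p-values.
#' @param connectivity 4 or 8 (2D), 6 or 26 (3D); default 8 / 26.
#' @return list of clusters, each a list with `voxels` (linear indices),
#'   `sign`, `mass`, `size`; ordered by decreasing mass.
#' @export
extract_clusters <- function(stat_map, alpha = 0.05, connectivity = NULL) {
  d <- img_dim(stat_map$t)
  connectivity <- connectivity %||% default_connectivity(d)
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- array((stat_map$p < alpha) & (sign(stat_map$t) == sgn), d)
    mask[is.na(mask)] <- FALSE
    lab <- label_components(mask, connectivity)
    K <- max(lab)
    if (K == 0) next
    for (k in seq_len(K)) {
      vox <- which(lab == k)
      out[[length(out) + 1]] <- list(voxels = vox, sign = sgn,
                                     mass = sum(abs(stat_map$t[vox])),
                                     size = length(vox))
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "mass"), decreasing = TRUE)]
}

#' Cluster report table
#'
#' @param clusters list of clusters from [extract_clusters()] or
#'   [significant_clusters()].
#' @param dim map dimensions, for centroid/bounding-box coordinates.
#' @return data frame with one row per cluster.
#' @export
cluster_table <- function(clusters, dim) {
  if (length(clusters) == 0)
    return(data.frame(cluster = integer(0), sign = integer(0),
                      size = integer(0), mass = numeric(0),
                      corrected_p = numeric(0)))
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    co <- arrayInd(cl$voxels, dim)
    data.frame(cluster = i, sign = cl$sign, size = cl$size, mass = cl$mass,
               corrected_p = cl$corrected_p %||% NA_real_,
               centroid = paste(round(colMeans(co), 2), collapse = ";"),
               bbox = paste(apply(co, 2, function(v)
                 paste0(min(v), "-", max(v))), collapse = ";"))
  })
  do.call(rbind, rows)
}

#' Permutation null distribution of the maximum cluster mass
#'
#' Re-runs the voxel-wise t-test and cluster extraction under `n_perm`
#' random relabelings of the individuals (group sizes preserved) and records
#' the maximum cluster mass of each permutation (0 when no suprathreshold
#' cluster forms). The observed labelling is not included in the null set.
#' If fewer distinct relabelings exist than requested, all distinct
#' relabelings (except the observed one) are enumerated instead.
#'
#' @param maps list of all individuals' maps (both groups).
#' @param labels group labels, a vector of length `length(maps)` with two
#'   levels; the first level is group A.
#' @param n_perm number of permutations.
#' @param alpha_cluster_forming cluster-forming p threshold.
#' @param connectivity see [extract_clusters()].
#' @param var_equal see [tstat_map()].
#' @return an object of class `permutation_null` with `max_masses`, `alpha`,
#'   `n_perm` and `threshold` (the mass that an observed cluster must exceed
#'   for corrected p < alpha).
#' @export
permutation_null <- function(maps, labels, n_perm = 100, alpha = 0.05,
                             alpha_cluster_forming = 0.05,
                             connectivity = NULL, var_equal = TRUE) {
  grids <- map_grids(maps)
  n <- length(grids)
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2, length(labels) == n, n_perm >= 20)
  d <- img_dim(grids[[1]])
  connectivity <- connectivity %||% default_connectivity(d)
  na <- sum(labels == levels(labels)[1])
  nb <- n - na
  V <- matrix(vapply(grids, as.numeric, numeric(prod(d))), nrow = prod(d))
  V2 <- V^2
  obs_a <- which(labels == levels(labels)[1])
  n_distinct <- choose(n, na)
  if (n_perm >= n_distinct - 1) {
    sets <- utils::combn(n, na, simplify = FALSE)
    sets <- Filter(function(s) !identical(sort(s), sort(obs_a)), sets)
  } else {
    sets <- replicate(n_perm, sample.int(n, na), simplify = FALSE)
  }
  csum <- rowSums(V); csum2 <- rowSums(V2)
  max_masses <- vapply(sets, function(ia) {
    sa <- rowSums(V[, ia, drop = FALSE])
    sa2 <- rowSums(V2[, ia, drop = FALSE])
    ma <- sa / na; mb <- (csum - sa) / nb
    va <- (sa2 - na * ma^2) / (na - 1)
    vb <- ((csum2 - sa2) - nb * mb^2) / (nb - 1)
    va[va < 0] <- 0; vb[vb < 0] <- 0
    res <- t_from_moments(ma, va, na, mb, vb, nb, var_equal)
    sm <- structure(list(t = array(res$t, d), p = array(res$p, d)),
                    class = "stat_map")
    cl <- extract_clusters(sm, alpha_cluster_forming, connectivity)
    if (length(cl) == 0) 0 else max(vapply(cl, `[[`, numeric(1), "mass"))
  }, numeric(1))
  B <- length(max_masses)
  m_allow <- floor(alpha * (1 + B) - 1 + 1e-12)
  thr <- if (m_allow < 0) Inf else sort(max_masses,
                                        decreasing = TRUE)[m_allow + 1]
  structure(list(max_masses = max_masses, alpha = alpha, n_perm = B,
                 threshold = thr,
                 alpha_cluster_forming = alpha_cluster_forming,
                 connectivity = connectivity),
            class = "permutation_null")
}

#' Build a permutation null from precomputed maximum masses
#'
#' @param max_masses numeric vector of null maximum cluster masses.
#' @param alpha significance level.
#' @return a `permutation_null` object.
#' @export
as_permutation_null <- function(max_masses, alpha = 0.05) {
  B <- length(max_masses)
  m_allow <- floor(alpha * (1 + B) - 1 + 1e-12)
  thr <- if (m_allow < 0) Inf else sort(max_masses,
                                        decreasing = TRUE)[m_allow + 1]
  structure(list(max_masses = max_masses, alpha = alpha, n_perm = B,
                 threshold = thr),
            class = "permutation_null")
}

#' Corrected p-value of an observed cluster mass
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, which cannot reach zero
#' with a finite number of permutations.
#'
#' @param mass observed cluster mass (vectorised).
#' @param null a [permutation_null()] object.
#' @return corrected p-values.
#' @export
corrected_p <- function(mass, null) {
  vapply(mass, function(m) (1 + sum(null$max_masses >= m)) / (1 + null$n_perm),
         numeric(1))
}

#' Family-wise-error-corrected clusters
#'
#' Annotates every cluster with its permutation-corrected p-value and
#' retains those with corrected p below the null's alpha.
#'
#' @param clusters list from [extract_clusters()].
#' @param null a [permutation_null()] built with the same cluster-forming
#'   settings.
#' @return filtered cluster list, each element annotated with `corrected_p`.
#' @export
significant_clusters <- function(clusters, null) {
  if (length(clusters) == 0) return(clusters)
  ps <- corrected_p(vapply(clusters, `[[`, numeric(1), "mass"), null)
  clusters <- Map(function(cl, p) { cl$corrected_p <- p; cl }, clusters, ps)
  Filter(function(cl) cl$corrected_p < null$alpha, clusters)
}

#' Voxel-wise F1 detection score
#'
#' `F1 = 2 TP / (2 TP + FP + FN)` between a detected voxel mask and the true
#' cluster mask at map resolution. Voxels detected in the opposite direction
#' of the planted effect can be supplied separately and count as false
#' positives.
#'
#' @param detected logical array of voxels detected in the effect direction.
#' @param truth logical array of true cluster voxels (same shape).
#' @param detected_opposite optional logical array of opposite-direction
#'   detections (counted as FP).
#' @param empty_value value returned when detection and truth are both empty.
#' @return scalar F1 in `[0, 1]`.
#' @export
f1_detection <- function(detected, truth, detected_opposite = NULL,
                         empty_value = 1) {
  stopifnot(identical(img_dim(detected), img_dim(truth)))
  det <- detected != 0; tru <- truth != 0
  tp <- sum(det & tru)
  fp <- sum(det & !tru)
  if (!is.null(detected_opposite)) fp <- fp + sum(detected_opposite != 0)
  fn <- sum(tru & !det)
  if (tp + fp + fn == 0) return(empty_value)
  2 * tp / (2 * tp + fp + fn)
}
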