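# Post-hoc within-cluster object statistics: counts and sizes of connected
# marker objects (e.g. plaques) inside significant clusters, compared
# between groups.

#' Label marker objects
#'
#' Connected-component labelling of the foreground of a binary image or
#' volume. In `"planewise"` mode (the default) components are computed
#' independently within each slice (third array dimension), matching markers
#' defined per coronal section; `"volumetric"` mode uses 3D connectivity.
#'
#' @param volume binary 2D matrix or 3D array with slices along the third
#'   dimension.
#' @param mode `"planewise"` or `"volumetric"`.
#' @param connectivity in-plane connectivity 4/8 (planewise) or volumetric
#'   6/26; defaults 8 and 26.
#' @return integer array of object labels (`0` = background) with attributes
#'   `n_objects` and `mode`.
#' @export
label_objects <- function(volume, mode = c("planewise", "volumetric"),
                          connectivity = NULL) {
  mode <- match.arg(mode)
  d <- img_dim(volume)
  if (length(d) == 2) {
    lab <- label_components(volume, connectivity %||% 8L)
    return(structure(lab, n_objects = max(lab), mode = mode))
  }
  if (length(d) != 3) stop("only 2D and 3D inputs are supported")
  if (mode == "volumetric") {
    lab <- label_components(volume, connectivity %||% 26L)
    return(structure(lab, n_objects = max(lab), mode = mode))
  }
  conn <- connectivity %||% 8L
  lab <- array(0L, d)
  offset <- 0L
  for (z in seq_len(d[3])) {
    lz <- label_components(volume[, , z], conn)
    nz <- max(lz)
    lz[lz > 0] <- lz[lz > 0] + offset
    lab[, , z] <- lz
    offset <- offset + nz
  }
  structure(lab, n_objects = offset, mode = mode)
}

#' Objects within clusters
#'
#' Tabulates the labelled marker objects of one individual and assigns each
#' to a cluster according to a membership rule evaluated against a cluster
#' mask at image resolution: `"centroid"` (default) assigns an object to the
#' cluster containing its centroid voxel; `"any_overlap"` to the cluster with
#' which it shares most voxels (at least one); `"majority"` requires more
#' than half of the object's voxels in a single cluster. Objects matching no
#' cluster are dropped.
#'
#' @param labeled output of [label_objects()] (or an integer label array).
#' @param cluster_mask integer array at image resolution with cluster ids
#'   (0 = background), or a logical array for a single cluster; see
#'   [upsample_mask()] to bring a map-resolution mask to image resolution.
#' @param rule membership rule.
#' @param id,group identifiers recorded in the output rows.
#' @return data frame with columns `individual`, `group`, `cluster`,
#'   `object`, `size` and centroid coordinates.
#' @export
objects_in_cluster <- function(labeled, cluster_mask,
                               rule = c("centroid", "any_overlap", "majority"),
                               id = NA, group = NA) {
  rule <- match.arg(rule)
  d <- img_dim(labeled)
  stopifnot(identical(d, img_dim(cluster_mask)))
  cm <- cluster_mask
  if (is.logical(cm)) cm <- cm * 1L
  storage.mode(cm) <- "integer"
  fg <- which(labeled > 0)
  empty <- data.frame(individual = character(0), group = character(0),
                      cluster = integer(0), object = integer(0),
                      size = integer(0), centroid_r = numeric(0),
                      centroid_c = numeric(0), centroid_s = numeric(0))
  if (length(fg) == 0) return(empty)
  labs <- labeled[fg]
  K <- max(labs)
  sizes <- tabulate(labs, nbins = K)
  co <- arrayInd(fg, d)
  cent <- apply(co, 2, function(v) rowsum(as.numeric(v), labs)[, 1]) / sizes
  cent <- matrix(cent, nrow = K)
  assign_cluster <- switch(rule,
    centroid = {
      ci <- round(cent)
      ci[, 1] <- pmin(pmax(ci[, 1], 1), d[1])
      ci[, 2] <- pmin(pmax(ci[, 2], 1), d[2])
      if (length(d) == 3) ci[, 3] <- pmin(pmax(ci[, 3], 1), d[3])
      lin <- ci[, 1] + (ci[, 2] - 1) * d[1]
      if (length(d) == 3) lin <- lin + (ci[, 3] - 1) * prod(d[1:2])
      cm[lin]
    },
    {
      # overlap counts per (object, cluster)
      cl_at <- cm[fg]
      res <- integer(K)
      incl <- cl_at > 0
      if (any(incl)) {
        tab <- table(labs[incl], cl_at[incl])
        objs <- as.integer(rownames(tab))
        best <- apply(tab, 1, which.max)
        ov <- tab[cbind(seq_len(nrow(tab)), best)]
        cl_id <- as.integer(colnames(tab))[best]
        ok <- if (rule == "majority") ov > sizes[objs] / 2 else ov >= 1
        res[objs[ok]] <- cl_id[ok]
      }
      res
    })
  keep <- which(assign_cluster > 0)
  if (length(keep) == 0) return(empty)
  data.frame(individual = rep(as.character(id), length(keep)),
             group = rep(as.character(group), length(keep)),
             cluster = as.integer(assign_cluster[keep]),
             object = keep,
             size = as.integer(sizes[keep]),
             centroid_r = cent[keep, 1],
             centroid_c = cent[keep, 2],
             centroid_s = if (length(d) == 3) cent[keep, 3] else NA_real_)
}

#' Upsample a map-resolution mask to image resolution
#'
#' Nearest-neighbour expansion: every image voxel receives the value of the
#' bin it belongs to (the exact inverse of the binning partition).
#'
#' @param mask matrix/array at map resolution.
#' @param bin_window binning window used to create the map.
#' @param out_shape image shape; defaults to `dim(mask) * bin_window`.
#' @return array of shape `out_shape`.
#' @export
upsample_mask <- function(mask, bin_window, out_shape = NULL) {
  d <- img_dim(mask)
  if (length(bin_window) == 1) bin_window <- rep(bin_window, length(d))
  out_shape <- out_shape %||% (d * bin_window)
  idx <- lapply(seq_along(d), function(ax) {
    pmin((seq_len(out_shape[ax]) - 1L) %/% bin_window[ax] + 1L, d[ax])
  })
  if (length(d) == 2) mask[idx[[1]], idx[[2]]]
  else mask[idx[[1]], idx[[2]], idx[[3]]]
}

#' Compare per-individual object counts between groups
#'
#' Pooled-variance two-tailed two-sample t-test on per-individual object
#' counts, with the percent change of group means.
#'
#' @param counts_a,counts_b numeric vectors of per-individual counts
#'   (at least 2 each); group A is the reference for the percent change.
#' @param var_equal pooled (default) or Welch variance.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b` and
#'   `percent_change` (`100 * (mean_b - mean_a) / mean_a`; `NaN` with a
#'   warning when `mean_a` is zero).
#' @export
compare_counts <- function(counts_a, counts_b, var_equal = TRUE) {
  stopifnot(length(counts_a) >= 2, length(counts_b) >= 2)
  na <- length(counts_a); nb <- length(counts_b)
  res <- t_from_moments(mean(counts_a), stats::var(counts_a), na,
                        mean(counts_b), stats::var(counts_b), nb, var_equal)
  ma <- mean(counts_a); mb <- mean(counts_b)
  pc <- if (ma == 0) {
    warning("reference group mean is zero: percent change undefined")
    NaN
  } else 100 * (mb - ma) / ma
  list(t = res$t, p = res$p, df = res$df, mean_a = ma, mean_b = mb,
       percent_change = pc)
}

#' Export the object size table
#'
#' Writes a tidy CSV (individual, group, cluster, object, size, centroids)
#' consumable by mixed-model packages for downstream size modelling.
#'
#' @param object_table data frame from [objects_in_cluster()] (possibly
#'   row-bound over individuals).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_size_table <- function(object_table, path) {
  if (nrow(object_table) == 0) stop("object table is empty")
  write.csv(format_numeric_df(object_table), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
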