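# End-to-end simulation benchmark: cohorts -> maps (with kernel selection)
# -> voxel-wise tests -> true error and F1 per estimator.

#' True-cluster mask at map resolution
#'
#' A map voxel is "true" iff more than half of its source voxels lie inside
#' a planted cluster.
#'
#' @param field the exacerbated-group [build_intensity_field()].
#' @param bin_window binning window.
#' @return logical matrix at map resolution.
#' @export
truth_mask <- function(field, bin_window = c(18, 18)) {
  bin_image(cluster_indicator(field), bin_window)$grid > 0.5
}

#' Simulation benchmark of the map estimators
#'
#' For each basal expected seed count, simulates replicate two-group cohorts
#' from the Boolean-Poisson model, builds parametric maps with each
#' estimator (selecting the Gaussian kernel per replicate by bootstrap error
#' minimisation over both groups), runs the voxel-wise two-tailed t-test at
#' the cluster-forming threshold, and records the true error (MSE between
#' the exacerbated-group mean map and the aggregated true load) and the
#' voxel-wise F1 score against the true cluster mask. Detections in the
#' direction opposite to the planted effect count as false positives.
#'
#' @param basal_counts basal expected seed counts, one experiment each.
#' @param n_replicates replicate cohorts per experiment.
#' @param shape image shape in pixels.
#' @param n_per_group images per group.
#' @param estimators subset of `"binning"`, `"voronoi_binning"`,
#'   `"gaussian_binning"`.
#' @param bin_window binning window.
#' @param sigmas candidate kernel sds for the Gaussian estimator.
#' @param n_bootstrap bootstrap samples for kernel selection.
#' @param stride evaluation stride for the bootstrap error (see
#'   [bootstrap_error()]).
#' @param alpha voxel-wise threshold for cluster detection.
#' @param radius_model disk radius model.
#' @param clusters cluster layout for the exacerbated group; default
#'   [default_clusters()] for `shape`.
#' @param seed RNG seed.
#' @param verbose print progress.
#' @return data frame with columns `basal`, `replicate`, `method`, `sigma`,
#'   `true_error`, `f1`.
#' @export
run_benchmark <- function(basal_counts = c(40, 80, 160),
                          n_replicates = 1,
                          shape = c(2560, 2560),
                          n_per_group = 10,
                          estimators = c("binning", "voronoi_binning",
                                         "gaussian_binning"),
                          bin_window = c(18, 18),
                          sigmas = sigma_grid(),
                          n_bootstrap = 500,
                          stride = 1,
                          alpha = 0.05,
                          radius_model = markload::radius_model(),
                          clusters = NULL,
                          seed = NULL,
                          verbose = FALSE) {
  if (!is.null(seed)) withr::local_seed(seed)
  clusters <- clusters %||% default_clusters(shape)
  rows <- list()
  for (basal in basal_counts) {
    field_exac <- build_intensity_field(shape, basal, clusters)
    truth <- true_marker_load(field_exac, radius_model)
    truth_map <- bin_image(truth, bin_window)$grid
    tmask <- truth_mask(field_exac, bin_window)
    cohort_seeds <- substream_seeds(n_replicates)
    for (rep_i in seq_len(n_replicates)) {
      if (verbose)
        message(sprintf("basal %g, replicate %d", basal, rep_i))
      cfg <- sim_config(image_shape = shape, radius_model = radius_model,
                        basal_expected_count = basal, clusters = clusters,
                        n_per_group = n_per_group,
                        seed = cohort_seeds[rep_i])
      cohort <- simulate_cohort(cfg)
      sigma_sel <- NA_real_
      if ("gaussian_binning" %in% estimators) {
        curve <- select_kernel(list(control = cohort$control,
                                    exacerbated = cohort$exacerbated),
                               sigmas = sigmas, n_bootstrap = n_bootstrap,
                               stride = stride)
        sigma_sel <- curve$selected_sigma
      }
      for (est in estimators) {
        sg <- if (est == "gaussian_binning") sigma_sel else NULL
        make_maps <- function(imgs) lapply(imgs, estimate_map, estimator = est,
                                           sigma = sg, bin_window = bin_window)
        maps_c <- make_maps(cohort$control)
        maps_e <- make_maps(cohort$exacerbated)
        mean_e <- Reduce(`+`, lapply(maps_e, as.matrix)) / length(maps_e)
        err <- mse_to_truth(mean_e, truth_map)
        sm <- tstat_map(maps_e, maps_c)        # planted direction: t > 0
        det_pos <- sm$p < alpha & sm$t > 0
        det_neg <- sm$p < alpha & sm$t < 0
        f1 <- f1_detection(det_pos, tmask, det_neg)
        rows[[length(rows) + 1]] <-
          data.frame(basal = basal, replicate = rep_i, method = est,
                     sigma = if (est == "gaussian_binning") sigma_sel else NA_real_,
                     true_error = err, f1 = f1)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("markload_benchmark", "data.frame")
  out
}

#' Benchmark summary averaged over replicates
#'
#' @param object a [run_benchmark()] result.
#' @param ... unused.
#' @return data frame with mean `true_error` and `f1` per basal count and
#'   method.
#' @export
summary.markload_benchmark <- function(object, ...) {
  agg <- aggregate(cbind(true_error, f1) ~ basal + method,
                   data = as.data.frame(object), FUN = mean)
  agg[order(agg$basal, agg$method), ]
}
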