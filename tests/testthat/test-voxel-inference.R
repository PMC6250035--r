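# Voxel-wise t-maps, cluster extraction, permutation cluster-mass inference
# and F1 scoring.

maps_from_matrix <- function(M, d) {
  lapply(seq_len(ncol(M)), function(j) array(M[, j], d))
}

test_that("t-map matches the closed form and a reference implementation", {
  a <- lapply(c(1, 2, 3), function(v) matrix(v, 1, 1))
  b <- lapply(c(4, 5, 6), function(v) matrix(v, 1, 1))
  s <- tstat_map(a, b)
  expect_equal(s$t[1, 1], -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(s$t[1, 1], 3), -3.674)
  expect_equal(s$p[1, 1], 0.0213, tolerance = 1e-3)
  expect_equal(s$df, 4)
  # antisymmetry under group swap
  s2 <- tstat_map(b, a)
  expect_equal(s2$t, -s$t)
  expect_equal(s2$p, s$p)
  # identical groups: t = 0, p = 1
  s0 <- tstat_map(a, a)
  expect_equal(s0$t[1, 1], 0)
  expect_equal(s0$p[1, 1], 1)

  withr::local_seed(21)
  d <- c(5, 4)
  Xa <- matrix(rnorm(prod(d) * 4), ncol = 4)
  Xb <- matrix(rnorm(prod(d) * 6, sd = 2), ncol = 6)
  for (ve in c(TRUE, FALSE)) {
    sm <- tstat_map(maps_from_matrix(Xa, d), maps_from_matrix(Xb, d),
                    var_equal = ve)
    for (v in seq_len(prod(d))) {
      ref <- t.test(Xa[v, ], Xb[v, ], var.equal = ve)
      expect_lt(abs(sm$t[v] - unname(ref$statistic)), 1e-10)
      expect_lt(abs(sm$p[v] - ref$p.value), 1e-10)
    }
  }
})

test_that("cluster extraction equals flood fill and separates signs", {
  mk_stat <- function(t, p) structure(list(t = t, p = p), class = "stat_map")
  # no suprathreshold voxels
  expect_length(extract_clusters(mk_stat(matrix(0, 3, 3), matrix(1, 3, 3))), 0)
  # opposite signs sharing an edge stay separate
  t <- matrix(0, 2, 2); t[1, 1] <- 3; t[1, 2] <- -3
  p <- matrix(1, 2, 2); p[1, 1:2] <- 0.01
  cl <- extract_clusters(mk_stat(t, p), 0.05)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, `[[`, numeric(1), "sign"), c(1, -1))
  # adjacent suprathreshold voxels sum their |t| into the mass
  t2 <- matrix(0, 3, 3); t2[2, 2] <- 2.5; t2[2, 3] <- 3.1
  p2 <- matrix(1, 3, 3); p2[2, 2:3] <- 0.01
  cl2 <- extract_clusters(mk_stat(t2, p2), 0.05)
  expect_length(cl2, 1)
  expect_equal(cl2[[1]]$mass, 5.6)

  # random toy maps against the flood-fill oracle, both connectivities
  withr::local_seed(22)
  for (rep in 1:20) {
    H <- sample(3:8, 1); W <- sample(3:8, 1)
    tv <- matrix(rnorm(H * W), H, W)
    pv <- matrix(runif(H * W), H, W)
    for (conn in c(4, 8)) {
      cl <- extract_clusters(mk_stat(tv, pv), 0.3, connectivity = conn)
      # reconstruct the partition per sign from the oracle
      n_oracle <- 0L
      for (sgn in c(1, -1)) {
        mask <- (pv < 0.3 & sign(tv) == sgn) * 1L
        lab <- flood_label(mask, conn)
        n_oracle <- n_oracle + max(lab)
        if (max(lab) > 0) {
          oracle_masses <- sort(vapply(seq_len(max(lab)), function(k)
            sum(abs(tv[lab == k])), numeric(1)))
          got <- sort(vapply(Filter(function(cl) cl$sign == sgn, cl),
                             `[[`, numeric(1), "mass"))
          expect_equal(got, oracle_masses)
        }
      }
      expect_length(cl, n_oracle)
    }
  }
})

test_that("component labelling matches flood fill in 2D and 3D", {
  withr::local_seed(23)
  for (rep in 1:10) {
    m <- rand_binary(7, 7, 0.45)
    for (conn in c(4L, 8L))
      expect_true(same_partition(markload:::cpp_label2d(m, conn),
                                 flood_label(m, conn)))
  }
  # 3D: two voxels touching diagonally across slices
  v <- array(0L, c(3, 3, 2)); v[1, 1, 1] <- 1L; v[2, 2, 2] <- 1L
  l26 <- markload:::label_components(v, 26)
  l6 <- markload:::label_components(v, 6)
  expect_equal(max(l26), 1)
  expect_equal(max(l6), 2)
})

test_that("corrected p-values follow the +1 rank convention", {
  null <- as_permutation_null(1:100, alpha = 0.05)
  expect_equal(corrected_p(200, null), 1 / 101)
  expect_equal(corrected_p(0.5, null), 1)        # below every null mass
  expect_equal(corrected_p(99.5, null), 2 / 101)
  expect_equal(null$threshold, 96)               # must exceed the 5th largest
  clusters <- list(list(voxels = 1L, sign = 1, mass = 200, size = 1),
                   list(voxels = 2L, sign = -1, mass = 50, size = 1))
  kept <- significant_clusters(clusters, null)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$corrected_p, 1 / 101)
  expect_length(significant_clusters(list(), null), 0)
  # alpha = 1 retains everything
  expect_length(significant_clusters(clusters,
                                     as_permutation_null(1:100, alpha = 1)), 2)
})

test_that("permutation null enumerates small designs and stays exchangeable", {
  withr::local_seed(24)
  d <- c(4, 4)
  maps <- maps_from_matrix(matrix(rnorm(16 * 6), ncol = 6), d)
  labels <- rep(c("a", "b"), each = 3)
  null <- permutation_null(maps, labels, n_perm = 100)
  expect_equal(null$n_perm, choose(6, 3) - 1)    # observed labelling excluded
  null2 <- permutation_null(maps, labels, n_perm = 100)
  expect_equal(null$max_masses, null2$max_masses) # enumeration is deterministic
  expect_true(all(null$max_masses >= 0))
})

test_that("planted clusters are recovered and only where planted", {
  withr::local_seed(25)
  shape <- c(360, 360)
  clusters <- list(cluster_spec(c(60, 60), c(90, 90), 25))
  cfg <- sim_config(image_shape = shape, basal_expected_count = 30,
                    clusters = clusters, n_per_group = 8,
                    seed = 555)
  co <- simulate_cohort(cfg)
  maps <- lapply(c(co$exacerbated, co$control), estimate_map,
                 estimator = "gaussian_binning", sigma = 8,
                 bin_window = c(18, 18))
  sm <- tstat_map(maps[1:8], maps[9:16])
  cl <- extract_clusters(sm, 0.05)
  null <- permutation_null(maps, rep(c("e", "c"), each = 8), n_perm = 60)
  sig <- significant_clusters(cl, null)
  expect_gte(length(sig), 1)
  tmask <- truth_mask(co$fields$exacerbated, c(18, 18))
  # every significant positive cluster overlaps the planted region
  for (s in Filter(function(x) x$sign > 0, sig))
    expect_gt(sum(tmask[s$voxels]), 0)
  expect_length(Filter(function(x) x$sign < 0, sig), 0)
})

test_that("F1 follows 2TP / (2TP + FP + FN)", {
  # perfect detection
  m <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(f1_detection(m, m), 1)
  # TP = 5, FP = 3, FN = 2 -> 2/3
  det <- matrix(FALSE, 2, 5); tru <- matrix(FALSE, 2, 5)
  det[1:8] <- TRUE; tru[c(1:5, 9:10)] <- TRUE
  expect_equal(f1_detection(det, tru), 2 * 5 / (2 * 5 + 3 + 2))
  # empty-vs-empty convention
  e <- matrix(FALSE, 2, 2)
  expect_equal(f1_detection(e, e), 1)
  expect_equal(f1_detection(e, e, empty_value = 0), 0)
  # opposite-direction detections count as false positives
  opp <- matrix(FALSE, 2, 5); opp[9] <- TRUE
  expect_equal(f1_detection(det, tru, detected_opposite = opp),
               2 * 5 / (2 * 5 + 4 + 2))
  # enumerated 2x2 masks against the direct formula
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  for (i in seq_len(nrow(combos))) for (j in seq_len(nrow(combos))) {
    dm <- matrix(unlist(combos[i, ]), 2, 2)
    tm <- matrix(unlist(combos[j, ]), 2, 2)
    tp <- sum(dm & tm); fp <- sum(dm & !tm); fn <- sum(tm & !dm)
    want <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
    expect_equal(f1_detection(dm, tm), want)
  }
})
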