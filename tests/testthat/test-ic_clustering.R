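test_that("ERP is the trial mean with the expected noise scaling", {
  set.seed(1)
  tr <- sin(seq(0, 2 * pi, length.out = 100))
  same <- matrix(tr, 100, 8)
  expect_equal(compute_erp(same), tr)
  expect_equal(compute_erp(matrix(tr, 100, 1)), tr)
  noise <- matrix(rnorm(100 * 1000), 100, 1000)
  # standard-error scaling: ERP amplitude ~ single trial / sqrt(N)
  expect_lt(abs(sd(compute_erp(noise)) * sqrt(1000) - 1), 0.15)
})

test_that("ERSP is baseline-relative and localizes a late burst", {
  set.seed(2)
  fs <- 128; Tn <- 256
  stat <- matrix(rnorm(Tn * 40), Tn, 40)
  er <- compute_ersp(stat, fs, window_len = 64, step = 16)
  expect_lt(max(abs(er$ersp)), 3)          # stationary: ~0 dB everywhere
  # 10 Hz burst in the second half of the epoch
  burst <- stat
  tsec <- seq_len(Tn) / fs
  burst[tsec > 1, ] <- burst[tsec > 1, ] + 4 * sin(2 * pi * 10 * tsec[tsec > 1])
  pre <- which(cortconn:::stft_power_phase(burst, fs, 64, 16)$times < 0.9)
  eb <- compute_ersp(burst, fs, window_len = 64, step = 16,
                     baseline_windows = pre)
  late <- eb$ersp[, eb$times > 1.3, drop = FALSE]
  peak <- which(late == max(late), arr.ind = TRUE)
  expect_lt(abs(eb$freqs[peak[1]] - 10), 3)
  # doubling the amplitude in a band adds about 6 dB
  dbl <- stat + 8 * sin(2 * pi * 20 * tsec)
  dbl2 <- stat + 16 * sin(2 * pi * 20 * tsec)
  p1 <- cortconn:::stft_power_phase(dbl, fs, 64, 16)
  p2 <- cortconn:::stft_power_phase(dbl2, fs, 64, 16)
  fi <- which.min(abs(p1$freqs - 20))
  gain_db <- mean(10 * log10(p2$power[fi, ] / p1$power[fi, ]))
  expect_lt(abs(gain_db - 6), 1)
  expect_error(compute_ersp(stat, fs, 64, 16, baseline_windows = integer()),
               "baseline")
})

test_that("ITC is 1 for identical trials, small for random phases, and
          bounded", {
  set.seed(3)
  fs <- 128
  tr <- sin(2 * pi * 10 * seq_len(256) / fs)
  same <- matrix(tr, 256, 20)
  it <- compute_itc(same, fs, 64, 16)
  expect_equal(max(it$itc), 1, tolerance = 1e-9)
  expect_equal(min(it$itc), 1, tolerance = 1e-9)
  rnd <- sapply(1:500, function(i)
    sin(2 * pi * 10 * seq_len(256) / fs + runif(1, 0, 2 * pi)))
  ir <- compute_itc(rnd, fs, 64, 16)
  fi <- which.min(abs(ir$freqs - 10))
  # Rayleigh: expected resultant of 500 random phasors ~ sqrt(pi)/2/sqrt(500)
  expect_lt(ir$itc[fi, 1], 4 / sqrt(500))
  all_itc <- compute_itc(matrix(rnorm(256 * 10), 256, 10), fs, 64, 16)$itc
  expect_true(all(all_itc >= 0 & all_itc <= 1 + 1e-12))
  expect_error(compute_itc(matrix(tr, 256, 1), fs, 64, 16), "2 trials")
})

make_fake_ics <- function(n, C = 16, Tn = 128, N = 6, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    list(subject = sprintf("s%02d", (i - 1) %/% 4 + 1), component = i,
         scalp_map = rnorm(C),
         activations = matrix(rnorm(Tn * N), Tn, N),
         dipole_xyz = rnorm(3, sd = 0.04), fs = 128))
}

test_that("feature vectors have the requested dimension and are
          deterministic", {
  ics <- make_fake_ics(24)
  fv <- build_feature_vectors(ics, pca_dims = 10)
  expect_equal(dim(fv$reduced), c(24L, 10L))
  fv2 <- build_feature_vectors(ics, pca_dims = 10)
  expect_identical(fv$reduced, fv2$reduced)
  # duplicated IC yields identical reduced vectors
  ics_dup <- c(ics, ics[3])
  fvd <- build_feature_vectors(ics_dup, pca_dims = 10)
  expect_equal(fvd$reduced[25, ], fvd$reduced[3, ], tolerance = 1e-8)
  expect_error(build_feature_vectors(ics[1:8], pca_dims = 10),
               "pca_dims")
})

test_that("kept-component variance matches a direct eigendecomposition", {
  set.seed(4)
  mat <- matrix(rnorm(40 * 12), 40, 12) %*% diag(c(8:1, rep(0.2, 4)))
  red <- cortconn:::pca_reduce(mat, 5)
  ev <- eigen(cov(mat), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(unname(apply(red$scores, 2, var)), ev[1:5],
               tolerance = 1e-8)
})

test_that("K-means recovers separated blobs and behaves at the edges", {
  set.seed(5)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(60 * 2, sd = 0.5), 60, 2), 2, centers[k, ], "+")))
  truth <- rep(1:3, each = 60)
  cl <- kmeans_cluster(x, K = 3, seed = 1)
  # perfect agreement up to label permutation
  tab <- table(cl$assignments, truth)
  expect_equal(sum(apply(tab, 1, max)), 180)
  one <- kmeans_cluster(x, K = 1, seed = 1)
  expect_equal(as.vector(one$centroids), colMeans(x), tolerance = 1e-10)
  expect_error(kmeans_cluster(x, K = 0), "positive")
  expect_error(kmeans_cluster(x[1:2, ], K = 3), "at least K")
})

test_that("cluster centroids map to regions, with bilateral spans getting
          two labels", {
  specs <- default_roi_specs()
  rad <- 0.082
  # cluster 1 at the L_Par seed; cluster 2 split across both occipital seeds
  seed_lpar <- specs[[3]]$seeds[1, ] * rad
  seed_locc <- specs[[1]]$seeds[1, ] * rad
  seed_rocc <- specs[[2]]$seeds[1, ] * rad
  dip <- rbind(
    matrix(rep(seed_lpar, 6), ncol = 3, byrow = TRUE),
    matrix(rep(seed_locc, 3), ncol = 3, byrow = TRUE),
    matrix(rep(seed_rocc, 3), ncol = 3, byrow = TRUE))
  cl <- structure(list(assignments = rep(1:2, each = 6),
                       centroids = matrix(0, 2, 10),
                       centroid_xyz = rbind(seed_lpar,
                                            (seed_locc + seed_rocc) / 2),
                       dipole_xyz = dip),
                  class = "cluster_result")
  lab <- assign_rois(cl, specs)
  expect_equal(lab$cluster1, "L_Par")
  expect_setequal(lab$cluster2, c("L_Occ", "R_Occ"))
  # midline SMA cluster: merged spec gives a single label
  sma <- specs[[8]]$seeds[1, ] * rad
  cl2 <- structure(list(assignments = rep(1, 4),
                        centroids = matrix(0, 1, 10),
                        centroid_xyz = matrix(sma, 1),
                        dipole_xyz = matrix(rep(sma, 4), ncol = 3,
                                            byrow = TRUE)),
                   class = "cluster_result")
  expect_equal(assign_rois(cl2, specs)$cluster1, "SMA")
  # centroid far outside the head: warning, nearest assignment
  cl3 <- cl2
  cl3$centroid_xyz <- matrix(sma * 4, 1)
  expect_warning(assign_rois(cl3, specs), "outside")
})

test_that("clustering the synthetic nine-source cohort recovers all nine
          region labels", {
  hm <- test_head_model()
  nets <- default_truth_networks()
  coh <- generate_cohort(3, nets, hm, jitter = 0.05, seed = 21,
                         n_control = 8, n_test = 8, T_s = 1)
  # ICs stand in for localized sources: scalp map = lead-field column of
  # the generating gridpoint, dipole at the true vertex
  ics <- list()
  for (s in seq_along(coh)) {
    gp <- coh[[s]]$gridpoints
    for (m in seq_along(gp)) {
      ics[[length(ics) + 1]] <- list(
        subject = sprintf("s%d", s), component = m,
        scalp_map = hm$K[, gp[m]],
        activations = coh[[s]]$true_sources[m, , 1:6],
        dipole_xyz = hm$mesh$vertices[gp[m], ], fs = 128)
    }
  }
  fv <- build_feature_vectors(ics, pca_dims = 10)
  cl <- kmeans_cluster(fv, K = 14, seed = 2)
  labels <- unique(unlist(assign_rois(cl, default_roi_specs())))
  expect_setequal(intersect(labels, names(hm$roi_map)), names(hm$roi_map))
})
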