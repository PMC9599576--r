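test_that("kmeans_pp separates blobs and handles n = k", {
  blobs <- make_blobs(40, rbind(c(0, 0), c(30, 30)), sd = 0.4, seed = 11)
  fit <- kmeans_pp(blobs$X, 2, seed = 1)
  expect_equal(length(unique(fit$labels[blobs$labels == 1])), 1L)
  expect_equal(length(unique(fit$labels[blobs$labels == 2])), 1L)
  expect_false(fit$labels[1] == fit$labels[80])

  X <- matrix(rnorm(12), 4, 3)
  fit2 <- kmeans_pp(X, 4, seed = 1)
  expect_equal(sort(fit2$labels), 1:4)
  expect_equal(fit2$inertia, 0)

  expect_error(kmeans_pp(X, 5, seed = 1), "k <= n")
})

test_that("kmeans_pp beats a random-label baseline and Lloyd descends", {
  set.seed(12)
  X <- matrix(rnorm(120 * 5), 120, 5)
  fit <- kmeans_pp(X, 3, seed = 2)
  # baseline oracle: random labels, centers at class means
  base_inertia <- replicate(20, {
    lab <- sample(1:3, 120, replace = TRUE)
    sum(vapply(1:3, function(j) {
      m <- colMeans(X[lab == j, , drop = FALSE])
      sum(sweep(X[lab == j, , drop = FALSE], 2, m)^2)
    }, numeric(1)))
  })
  expect_lt(fit$inertia, min(base_inertia))
  expect_true(all(diff(fit$inertia_path) <= 1e-9))
})

test_that("silhouette matches the worked 1-D example exactly", {
  X <- matrix(c(0, 1, 5, 6), ncol = 1)
  sil <- silhouette_score(X, c(1, 1, 2, 2))
  # hand computation: s = (9/11, 7/9, 7/9, 9/11), SC = 79/99
  expect_equal(sil$s, c(9 / 11, 7 / 9, 7 / 9, 9 / 11), tolerance = 1e-12)
  expect_equal(sil$sc, 79 / 99, tolerance = 1e-12)
  expect_equal(sil$n, 4L)
})

test_that("silhouette edge cases: coincident clusters, random labels", {
  X <- rbind(matrix(0, 5, 2), matrix(10, 5, 2))
  expect_equal(silhouette_score(X, rep(1:2, each = 5))$sc, 1)

  set.seed(13)
  X2 <- matrix(rnorm(2 * 400), ncol = 2)
  sc <- silhouette_score(X2, sample(1:2, 400, TRUE))$sc
  expect_lt(abs(sc), 0.05)

  expect_error(silhouette_score(X2, rep(1, 400)), "single cluster")
})

test_that("silhouette equals the brute-force oracle to 1e-12 (n <= 50)", {
  skip_if_not_installed("cluster")
  set.seed(14)
  for (i in 1:8) {
    n <- sample(10:50, 1)
    k <- sample(2:4, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    labels <- sample(seq_len(k), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    sil <- silhouette_score(X, labels)
    expect_equal(sil$sc, silhouette_oracle(X, labels), tolerance = 1e-12)
    # second, independent implementation: cluster::silhouette
    if (all(table(labels) > 1)) {
      cs <- cluster::silhouette(labels, stats::dist(X))
      expect_equal(sil$sc, mean(cs[, "sil_width"]), tolerance = 1e-12)
    }
  }
})

test_that("singleton clusters contribute zero by convention", {
  X <- matrix(c(0, 0.5, 9, 20), ncol = 1)
  sil <- silhouette_score(X, c(1, 1, 2, 3))
  expect_equal(sil$s[4], 0)
  expect_equal(sil$sc, silhouette_oracle(X, c(1, 1, 2, 3)),
               tolerance = 1e-12)
})

test_that("select_k_by_silhouette finds the planted cluster count", {
  two <- make_blobs(40, rbind(c(0, 0), c(25, 25)), sd = 0.6, seed = 15)
  expect_equal(select_k_by_silhouette(two$X, 2, 5, seed = 1)$best_k, 2L)

  three <- make_blobs(30, rbind(c(0, 0), c(25, 0), c(0, 25)), sd = 0.6,
                      seed = 16)
  expect_equal(select_k_by_silhouette(three$X, 2, 5, seed = 1)$best_k, 3L)

  sel <- select_k_by_silhouette(two$X, k_min = 1, k_max = 3, seed = 1)
  expect_equal(min(sel$k_evaluated), 2L)   # k = 1 excluded, logged
  expect_match(sel$note, "undefined")
})

test_that("rf importance pinpoints a single informative feature", {
  set.seed(17)
  X <- matrix(rnorm(300 * 40), 300, 40)
  labels <- ifelse(X[, 23] > 0, "a", "b")
  imp <- rf_importance(X, labels, n_trees = 150, seed = 1)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  expect_equal(which.max(imp$importance), 23L)
  expect_gt(sum(imp$importance[22:24]), 0.5)

  # determinism under a fixed seed
  imp2 <- rf_importance(X, labels, n_trees = 150, seed = 1)
  expect_identical(imp$importance, imp2$importance)

  expect_error(rf_importance(X, rep("a", 300)), "2 classes")
})

test_that("rf importance is flat when labels are independent of X", {
  set.seed(18)
  X <- matrix(rnorm(250 * 50), 250, 50)
  labels <- sample(c("a", "b"), 250, TRUE)    # permutation baseline
  imp <- rf_importance(X, labels, n_trees = 200, seed = 2)
  expect_lt(max(imp$importance), 5 * mean(imp$importance))
})

test_that("smoothing preserves constants and interior spike mass", {
  wn <- seq(700, 900, by = 1)
  prof <- structure(list(wavenumbers = wn,
                         importance = rep(1 / length(wn), length(wn)),
                         smoothed = NULL),
                    class = "importance_profile")
  sm <- smooth_importance(prof, 15)
  expect_equal(sm$smoothed, prof$importance)

  spike <- rep(0, length(wn)); spike[100] <- 0.7
  prof$importance <- spike
  sm2 <- smooth_importance(prof, 15)
  expect_equal(sum(sm2$smoothed), 0.7, tolerance = 1e-12)
  # plateau of width 2*hw+1 = 15 bins at height mass/15
  expect_equal(sm2$smoothed[100], 0.7 / 15)
  expect_equal(sm2$smoothed[93], 0.7 / 15)
  expect_equal(sm2$smoothed[107], 0.7 / 15)
  expect_equal(sm2$smoothed[108], 0)

  # two spikes separated by more than the window stay distinct maxima
  spike2 <- rep(0, length(wn)); spike2[c(50, 150)] <- 1
  prof$importance <- spike2
  y <- smooth_importance(prof, 15)$smoothed
  lm_idx <- which(y >= c(-Inf, y[-length(y)]) & y > c(y[-1], -Inf))
  expect_equal(sum(y[lm_idx] > 0), 2L)

  expect_error(smooth_importance(prof, 0.1), "below the grid spacing")
})

test_that("top_bands returns separated maxima nearest 782 and 1655", {
  wn <- as.numeric(default_grid())
  imp <- rep(1e-6, length(wn))
  i782 <- which.min(abs(wn - 782))
  i1655 <- which.min(abs(wn - 1655))
  imp[i782] <- 0.4; imp[i1655] <- 0.6
  prof <- structure(list(wavenumbers = wn, importance = imp / sum(imp),
                         smoothed = NULL), class = "importance_profile")
  got <- sort(top_bands(prof, 2, 50))
  expect_equal(got, sort(c(wn[i782], wn[i1655])), tolerance = 1e-9)

  # monotone profile: the boundary point is the single maximum
  prof2 <- structure(list(wavenumbers = wn,
                          importance = seq_along(wn) / sum(seq_along(wn)),
                          smoothed = NULL), class = "importance_profile")
  expect_equal(top_bands(prof2, 1, 50), wn[length(wn)])

  # two equal maxima within min_separation: requesting 2 errors
  imp3 <- rep(1e-6, length(wn))
  imp3[c(i782, i782 + 20L)] <- 0.5
  prof3 <- structure(list(wavenumbers = wn, importance = imp3,
                          smoothed = imp3), class = "importance_profile")
  expect_length(top_bands(prof3, 1, 50), 1L)
  expect_error(top_bands(prof3, 2, 50), "separated local maxima")
})

test_that("band features track region composition in a noise-free scan", {
  cfg <- noise_free_config(
    layout = data.frame(region = c("nucleus", "cytoplasm"),
                        length_um = c(5, 5)))
  scan <- simulate_line_scan(cfg)
  feats <- extract_band_features(scan, c(782, 1655), 5)
  expect_equal(dim(feats), c(10L, 2L))
  nuc <- scan$meta$truth_region == "nucleus"
  expect_gt(min(feats[nuc, 1]), max(feats[!nuc, 1]))   # 782: nucleus high
  expect_gt(min(feats[!nuc, 2]), max(feats[nuc, 2]))   # 1655: cytoplasm
  expect_error(extract_band_features(scan, 2000, 5), "outside")
})

test_that("classify_regions labels, intensities and invariances", {
  set.seed(19)
  n <- 40
  # nucleic-rich: high col 1, low col 2; protein-rich: the reverse
  f <- rbind(cbind(rnorm(n, 10, .4), rnorm(n, 2, .4)),
             cbind(rnorm(n, 2, .4), rnorm(n, 10, .4)))
  res <- classify_regions(f, protein_col = 2, seed = 1)
  expect_equal(res$call, rep(c("nucleic_acid_rich", "protein_rich"),
                             each = n))
  expect_true(all(res$intensity >= 0 & res$intensity <= 1))
  expect_gt(res$sc, 0)

  # spectrum at a cluster centre scores 1; the farthest member scores 0
  for (cl in 1:2) {
    members <- which(res$clusters$labels == cl)
    expect_equal(min(res$clusters$dist_to_center[members]),
                 res$clusters$dist_to_center[
                   members[which.max(res$intensity[members])]])
    expect_equal(min(res$intensity[members]), 0)
  }

  # far_strong flips the intensity convention
  res2 <- classify_regions(f, protein_col = 2, seed = 1,
                           intensity_direction = "far_strong")
  expect_equal(res2$intensity, 1 - res$intensity)

  # ordering invariance (well-separated case): calls permute with rows
  perm <- sample(nrow(f))
  res3 <- classify_regions(f[perm, ], protein_col = 2, seed = 1)
  expect_equal(res3$call, res$call[perm])

  expect_error(classify_regions(cbind(rep(1, 10), rnorm(10))),
               "degenerate")
  expect_error(classify_regions(matrix(rnorm(30), 10, 3)), "two band")
})
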