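# helper: build a circular ellipse_spec of radius r (as confidence_ellipse
# would produce for an isotropic cloud at the given level)
make_circle <- function(center, r, level = 0.95) {
  q <- stats::qchisq(level, 2)
  structure(list(center = center, semi_axes = c(r, r), angle = 0,
                 level = level, cov = diag(2) * r^2 / q, q = q),
            class = "ellipse_spec")
}

test_that("PCA handles rank-1, isotropic and degenerate inputs", {
  set.seed(1)
  t <- rnorm(40)
  X <- outer(t, c(1, 2, 3))            # data on a line
  p <- fit_pca(X, 2)
  expect_equal(p$explained[1], 1, tolerance = 1e-10)

  Z <- matrix(rnorm(2 * 20000), ncol = 2)
  expect_equal(fit_pca(Z, 2)$explained, c(0.5, 0.5), tolerance = 0.03)

  expect_error(fit_pca(matrix(1, 10, 4), 2), "constant")
  expect_error(fit_pca(matrix(rnorm(12), 3, 4), 3), "n_components")
})

test_that("PCA loadings are orthonormal and reconstruction is exact", {
  set.seed(2)
  X <- matrix(rnorm(30 * 8), 30, 8)
  p <- fit_pca(X, 8)   # full rank in features
  G <- crossprod(p$loadings)
  expect_lt(max(abs(G - diag(8))), 1e-8)
  recon <- p$scores %*% t(p$loadings)
  centered <- sweep(X, 2, p$center)
  expect_lt(max(abs(recon - centered)), 1e-8)
  expect_true(all(diff(p$explained) <= 1e-12))
  # sign convention: largest-magnitude entry of each loading is positive
  for (j in 1:8) {
    v <- p$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("confidence ellipse matches the chi-square quantile oracle", {
  set.seed(3)
  Z <- matrix(rnorm(2 * 200000), ncol = 2)
  e <- confidence_ellipse(Z, 0.95)
  r <- sqrt(stats::qchisq(0.95, 2))    # 2.4477 for a standard normal
  expect_equal(unname(e$semi_axes), c(r, r), tolerance = 0.02)

  sml <- matrix(rnorm(2 * 50), ncol = 2)
  e1 <- confidence_ellipse(sml, 0.9)
  e2 <- confidence_ellipse(3.7 * sml, 0.9)
  expect_equal(e2$semi_axes, 3.7 * e1$semi_axes, tolerance = 1e-10)

  expect_error(confidence_ellipse(matrix(rnorm(4), 2, 2)), "3 points")
  expect_error(confidence_ellipse(cbind(1:10, 2 * (1:10))), "singular")
  expect_error(confidence_ellipse(matrix(rnorm(20), 10, 2), level = 1.2),
               "level")
})

test_that("ellipse coverage approaches the nominal level", {
  set.seed(4)
  train <- matrix(rnorm(2 * 5000), ncol = 2) %*% chol(rbind(c(2, .6),
                                                            c(.6, 1)))
  test <- matrix(rnorm(2 * 50000), ncol = 2) %*% chol(rbind(c(2, .6),
                                                            c(.6, 1)))
  e <- confidence_ellipse(train, 0.95)
  expect_equal(mean(ellipse_contains(e, test)), 0.95, tolerance = 0.01)
})

test_that("ellipse overlap test covers the canonical cases", {
  a <- make_circle(c(0, 0), 1)
  expect_true(ellipses_overlap(a, a))                       # identical
  expect_false(ellipses_overlap(a, make_circle(c(10, 0), 1)))
  expect_true(ellipses_overlap(a, make_circle(c(1.5, 0), 1)))  # d < r1+r2
  # nested: one fully inside the other
  expect_true(ellipses_overlap(a, make_circle(c(0, 0), 0.2)))
})

test_that("quadrant rule assigns constructed loadings correctly", {
  mk <- function(l1, l2) {
    structure(list(loadings = cbind(PC1 = l1, PC2 = l2),
                   wavenumbers = c(800, 900, 1000)),
              class = "pca_result")
  }
  # one dominant wavenumber at (+0.9, -0.8): a 2D key band
  kb <- key_bands_from_loadings(mk(c(0.9, .1, .1), c(-0.8, .1, .1)), 0.5)
  expect_equal(kb$model[kb$wavenumber == 800], "2D")
  # quadrant 1 stays unassigned
  kb2 <- key_bands_from_loadings(mk(c(0.9, .1, .1), c(0.9, .1, .1)), 0.5)
  expect_true(is.na(kb2$model[kb2$wavenumber == 800]))
  # quadrant 2 is a 3D key band
  kb3 <- key_bands_from_loadings(mk(c(-0.9, .1, .1), c(0.8, .1, .1)), 0.5)
  expect_equal(kb3$model[kb3$wavenumber == 800], "3D")
})

test_that("quadrant rule recovers every planted band on engineered data", {
  set <- make_engineered_pair(n_per = 150, seed = 7)
  pca <- orient_pca_to_labels(fit_pca(set, 2))
  kb <- key_bands_from_loadings(pca, 0.5)
  found <- function(model, b)
    any(!is.na(kb$model) & kb$model == model & abs(kb$wavenumber - b) < 6)
  for (b in c(1628, 1377, 1096, 794)) expect_true(found("2D", b))
  for (b in c(1662, 1246, 851, 1002)) expect_true(found("3D", b))
  # includes the planted 3D-only amide I band at 1662
  expect_true(found("3D", 1662))
})

test_that("stated-world pair recovers one class cleanly, never crosses", {
  pair <- simulate_model_pair(generator_config(seed = 3), 200, 200)
  merged <- bind_spectra(pair$set_2d, pair$set_3d)
  pca <- orient_pca_to_labels(fit_pca(merged, 2))
  kb <- key_bands_from_loadings(pca, 0.5)
  near <- function(w, bands) any(abs(w - bands) < 6)
  b2 <- c(1628, 1377, 1096, 794)
  b3 <- c(1662, 1246, 851, 1002)
  for (b in b2)
    expect_true(any(!is.na(kb$model) & kb$model == "2D" &
                      abs(kb$wavenumber - b) < 6))
  # no planted band is ever assigned to the wrong class
  for (i in seq_len(nrow(kb))) {
    if (is.na(kb$model[i])) next
    if (kb$model[i] == "2D") expect_false(near(kb$wavenumber[i], b3))
    if (kb$model[i] == "3D") expect_false(near(kb$wavenumber[i], b2))
  }
})

test_that("knn_rms_distance matches hand values and the metric axioms", {
  expect_equal(knn_rms_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(knn_rms_distance(c(0, 0), c(0.4, 0.3)), sqrt(0.125))
  set.seed(5)
  for (i in 1:25) {
    p <- rnorm(2); q <- rnorm(2); r <- rnorm(2)
    expect_equal(knn_rms_distance(p, q), knn_rms_distance(q, p))
    expect_gte(knn_rms_distance(p, q), 0)
    expect_lte(knn_rms_distance(p, r),
               knn_rms_distance(p, q) + knn_rms_distance(q, r) + 1e-12)
  }
})

test_that("knn_fit_score is 1 for separated classes, 0.5 at chance", {
  blobs <- make_blobs(100, rbind(c(0, 0), c(20, 20)), sd = 0.5, seed = 6)
  labs <- c("2D", "3D")[blobs$labels]
  expect_equal(knn_fit_score(blobs$X, labs, k = 11, seed = 1)$score, 1)

  set.seed(7)
  X <- matrix(rnorm(2 * 1000), ncol = 2)   # identical class distributions
  labs2 <- rep(c("2D", "3D"), each = 500)
  expect_equal(knn_fit_score(X, labs2, k = 11, seed = 1)$score, 0.5,
               tolerance = 0.12)
})

test_that("k equal to the training size degenerates to the majority vote", {
  set.seed(8)
  X <- matrix(rnorm(2 * 100), ncol = 2)
  labs <- rep(c("A", "B"), times = c(60, 40))
  n_train <- 48 + 32        # stratified 80%
  res <- knn_fit_score(X, labs, k = n_train, train_fraction = 0.8,
                       seed = 3)
  expect_true(all(res$predicted == "A"))      # majority class of training
  expect_equal(res$score, mean(res$truth == "A"))
  expect_equal(res$score, 12 / 20)            # test split is 12 A / 8 B
  expect_error(knn_fit_score(X, labs, k = n_train + 1, seed = 1),
               "exceeds training size")
})
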