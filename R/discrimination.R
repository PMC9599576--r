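# Stage 1 of the pipeline: PCA of labeled 2D/3D spectra, 95% confidence
# ellipses in PC1/PC2 score space, quadrant-rule key-band extraction from
# the loadings, and a KNN validation score on the score coordinates.

#' Principal component analysis of a spectrum set
#'
#' Mean-centred PCA via singular value decomposition (equivalent to an
#' eigen-decomposition of the covariance matrix). Loadings are orthonormal
#' weight vectors over wavenumbers; scores are the projections of each
#' centred spectrum; explained proportions are eigenvalues over total
#' variance, in non-increasing order. Sign convention: each loading vector
#' is flipped so that its largest-magnitude entry is positive, making the
#' decomposition deterministic.
#'
#' @param set a [spectrum_set()] or a plain numeric matrix
#'   (rows = spectra).
#' @param n_components number of components to retain
#'   (`2 <= n_components < n_spectra`).
#' @return an object of class `pca_result`: `center` (mean spectrum),
#'   `loadings` (p x k), `scores` (n x k), `explained` (length-k
#'   proportions), `wavenumbers` (if available) and `labels` (if available).
#' @export
fit_pca <- function(set, n_components = 2L) {
  if (inherits(set, "spectrum_set")) {
    X <- set$intensities
    wn <- as.numeric(set$grid)
    labels <- set$meta$model_label
  } else {
    X <- as.matrix(set)
    wn <- NULL
    labels <- NULL
  }
  n <- nrow(X)
  n_components <- as.integer(n_components)
  if (!(n > n_components && n_components >= 2L))
    stop("need n_spectra > n_components >= 2 (got n = ", n,
         ", n_components = ", n_components, ")", call. = FALSE)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  total_var <- sum(Xc^2) / (n - 1L)
  if (total_var <= .Machine$double.eps * max(1, mean(abs(X))))
    stop("constant input matrix: PCA undefined", call. = FALSE)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  eig <- sv$d^2 / (n - 1L)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1L))
  loadings <- sweep(sv$v, 2L, flip, `*`)
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(n_components)],
                                n_components), 2L, flip, `*`)
  colnames(loadings) <- colnames(scores) <-
    paste0("PC", seq_len(n_components))
  structure(list(center = center,
                 loadings = loadings,
                 scores = scores,
                 explained = eig[seq_len(n_components)] / total_var,
                 total_variance = total_var,
                 wavenumbers = wn,
                 labels = labels),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d spectra, %d components; explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' Orient PC1/PC2 by the class means
#'
#' PCA loading signs are arbitrary; the quadrant rule that assigns key
#' bands to a culture model is stated relative to the score-space
#' orientation in which the 2D class projects into the fourth quadrant
#' (PC1 > 0, PC2 < 0) and the 3D class into the second. This helper flips
#' PC1 so the 2D class mean exceeds the 3D class mean on PC1, and PC2 the
#' other way round. Scores and loadings are flipped together, so the
#' decomposition is unchanged up to sign.
#'
#' @param pca a [fit_pca()] result carrying `labels` (or pass `labels`).
#' @param labels optional label vector overriding `pca$labels`.
#' @return the re-oriented `pca_result`.
#' @export
orient_pca_to_labels <- function(pca, labels = pca$labels) {
  stopifnot(inherits(pca, "pca_result"))
  if (is.null(labels)) stop("labels required to orient the PCA",
                            call. = FALSE)
  m2 <- colMeans(pca$scores[labels == "2D", 1:2, drop = FALSE])
  m3 <- colMeans(pca$scores[labels == "3D", 1:2, drop = FALSE])
  flip <- c(if (m2[1L] >= m3[1L]) 1 else -1,
            if (m2[2L] <= m3[2L]) 1 else -1)
  pca$scores[, 1:2] <- sweep(pca$scores[, 1:2, drop = FALSE], 2L, flip, `*`)
  pca$loadings[, 1:2] <- sweep(pca$loadings[, 1:2, drop = FALSE], 2L,
                               flip, `*`)
  pca
}

#' Confidence ellipse of a 2-D score cloud
#'
#' Fits a bivariate-normal confidence ellipse from the sample mean and
#' covariance of the PC1/PC2 points: semi-axes are
#' `sqrt(eigenvalue * q)` with `q` the chi-square quantile at `level` with
#' 2 degrees of freedom.
#'
#' @param scores numeric matrix (or data.frame) with >= 3 rows and exactly
#'   2 columns.
#' @param level confidence level in (0, 1); 0.95 by default.
#' @return an object of class `ellipse_spec`: `center`, `semi_axes`,
#'   `angle` (radians), `level`, plus the fitted `cov` and quantile `q`
#'   used by the containment test.
#' @export
confidence_ellipse <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  if (nrow(scores) < 3L)
    stop("need at least 3 points to fit an ellipse", call. = FALSE)
  if (!(level > 0 && level < 1))
    stop("confidence level must lie in (0, 1)", call. = FALSE)
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(abs(e$values), 1))
    stop("singular covariance: score cloud is degenerate", call. = FALSE)
  q <- stats::qchisq(level, df = 2L)
  structure(list(center = ctr,
                 semi_axes = sqrt(e$values * q),
                 angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
                 level = level,
                 cov = S,
                 q = q),
            class = "ellipse_spec")
}

#' Test which points fall inside a confidence ellipse
#' @param ellipse an [confidence_ellipse()] result.
#' @param points n x 2 matrix of score coordinates.
#' @param margin numerical containment margin added to the quantile.
#' @return logical vector.
#' @export
ellipse_contains <- function(ellipse, points, margin = 0) {
  points <- matrix(as.numeric(points), ncol = 2L)
  stats::mahalanobis(points, ellipse$center, ellipse$cov) <=
    ellipse$q + margin
}

#' Boundary points of an ellipse
#' @param ellipse an `ellipse_spec`.
#' @param n number of boundary samples.
#' @return n x 2 matrix.
#' @export
ellipse_boundary <- function(ellipse, n = 720L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  a <- ellipse$semi_axes[1L]
  b <- ellipse$semi_axes[2L]
  phi <- ellipse$angle
  x <- a * cos(t)
  y <- b * sin(t)
  cbind(ellipse$center[1L] + x * cos(phi) - y * sin(phi),
        ellipse$center[2L] + x * sin(phi) + y * cos(phi))
}

#' Do two confidence ellipses overlap?
#'
#' TRUE iff the ellipse interiors intersect. Decided by dense boundary
#' sampling (default 720 points each) plus mutual centre-containment checks
#' (which also catches one ellipse nested inside the other).
#'
#' @param a,b `ellipse_spec` objects.
#' @param n_boundary boundary samples per ellipse.
#' @param margin containment tolerance.
#' @return logical.
#' @export
ellipses_overlap <- function(a, b, n_boundary = 720L, margin = 1e-9) {
  if (any(ellipse_contains(b, ellipse_boundary(a, n_boundary), margin)))
    return(TRUE)
  if (any(ellipse_contains(a, ellipse_boundary(b, n_boundary), margin)))
    return(TRUE)
  # nested cases: one centre inside the other ellipse
  ellipse_contains(b, matrix(a$center, 1L), margin) ||
    ellipse_contains(a, matrix(b$center, 1L), margin)
}

#' Key discriminating bands from PCA loadings
#'
#' Applies the quadrant rule to the PC1/PC2 loading vectors: wavenumbers
#' whose loadings are large on both components are assigned to the 2D model
#' when (PC1 > 0, PC2 < 0) and to the 3D model when (PC1 < 0, PC2 > 0);
#' large-loading wavenumbers in the other two quadrants are reported
#' unassigned. "Large" means `|loading| >= magnitude_threshold * max
#' |loading|` on that component.
#'
#' @param pca a [fit_pca()] result with >= 2 components.
#' @param magnitude_threshold fraction of the per-component maximum
#'   absolute loading (default 0.5).
#' @return data.frame of class `key_band_report` with columns `wavenumber`,
#'   `pc1`, `pc2`, `model` ("2D", "3D" or NA).
#' @export
key_bands_from_loadings <- function(pca, magnitude_threshold = 0.5) {
  stopifnot(inherits(pca, "pca_result"), ncol(pca$loadings) >= 2L)
  l1 <- pca$loadings[, 1L]
  l2 <- pca$loadings[, 2L]
  sel <- abs(l1) >= magnitude_threshold * max(abs(l1)) &
         abs(l2) >= magnitude_threshold * max(abs(l2))
  wn <- if (is.null(pca$wavenumbers)) seq_along(l1) else pca$wavenumbers
  model <- rep(NA_character_, sum(sel))
  p1 <- l1[sel]
  p2 <- l2[sel]
  model[p1 > 0 & p2 < 0] <- "2D"
  model[p1 < 0 & p2 > 0] <- "3D"
  out <- data.frame(wavenumber = wn[sel], pc1 = p1, pc2 = p2,
                    model = model, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("key_band_report", class(out))
  out
}

#' Root-mean-square distance between two score pairs
#'
#' `sqrt(((p1 - q1)^2 + (p2 - q2)^2) / 2)`: the RMS of the coordinate-wise
#' differences of the PC1/PC2 score pairs, used as the KNN distance.
#'
#' @param p,q numeric length-2 vectors of (PC1, PC2) coordinates.
#' @return non-negative distance.
#' @export
knn_rms_distance <- function(p, q) {
  stopifnot(length(p) == 2L, length(q) == 2L,
            all(is.finite(p)), all(is.finite(q)))
  sqrt(sum((p - q)^2) / 2)
}

.knn_vote <- function(d, train_labels, k) {
  ord <- order(d)
  nn <- ord[seq_len(k)]
  votes <- table(train_labels[nn])
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) return(top)
  # tie: nearer neighbour's label among the tied labels, then lexicographic
  for (i in nn) if (train_labels[i] %in% top) return(train_labels[i])
  sort(top)[1L]
}

#' KNN validation score on PC score coordinates
#'
#' Stratified seeded split of the labeled (PC1, PC2) points into training
#' and test sets; each test point is classified by majority vote among its
#' `k` nearest training points under [knn_rms_distance()]; the score is the
#' fraction of test points whose prediction matches the true label.
#'
#' @param scores n x 2 matrix of (PC1, PC2) coordinates.
#' @param labels class label per row (two or more classes).
#' @param k neighbour count (default 11; must not exceed training size).
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.8).
#' @param seed integer seed for the split.
#' @return object of class `knn_score`: `score` in \[0, 1\], `k`,
#'   `n_train`, `n_test`, `predicted`, `truth`, `test_idx`.
#' @export
knn_fit_score <- function(scores, labels, k = 11L, train_fraction = 0.8,
                          seed = 1L) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels), !anyNA(labels))
  n <- nrow(scores)
  train_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(n), labels), function(idx) {
      n_tr <- max(1L, round(train_fraction * length(idx)))
      sample(idx, min(n_tr, length(idx) - 1L))
    }), use.names = FALSE)
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(unique(labels[train_idx])) < 2L)
    stop("training split does not contain both classes", call. = FALSE)
  if (k > length(train_idx))
    stop("k = ", k, " exceeds training size ", length(train_idx),
         call. = FALSE)
  tr <- scores[train_idx, , drop = FALSE]
  trl <- labels[train_idx]
  pred <- vapply(test_idx, function(i) {
    d <- sqrt(((scores[i, 1L] - tr[, 1L])^2 +
               (scores[i, 2L] - tr[, 2L])^2) / 2)
    .knn_vote(d, trl, k)
  }, character(1L))
  structure(list(score = mean(pred == labels[test_idx]),
                 k = k, n_train = length(train_idx),
                 n_test = length(test_idx),
                 predicted = pred, truth = labels[test_idx],
                 test_idx = test_idx),
            class = "knn_score")
}

#' @export
print.knn_score <- function(x, ...) {
  cat(sprintf("<knn_score> %.4f (k = %d, %d train / %d test)\n",
              x$score, x$k, x$n_train, x$n_test))
  invisible(x)
}
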