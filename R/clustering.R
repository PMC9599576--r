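# Stage 2 of the pipeline: K-means++ clustering of the spectra,
# silhouette-based cluster-count selection, random-forest feature
# importance over wavenumbers, top-band selection, and the final two-band
# re-clustering that calls each scan position protein-rich or
# nucleic-acid-rich.

.sq_dists <- function(X, centers) {
  # n x k matrix of squared Euclidean distances
  d2 <- outer(rowSums(X^2), rowSums(centers^2), `+`) -
    2 * X %*% t(centers)
  d2[d2 < 0] <- 0
  d2
}

.kmeanspp_seed_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  d2 <- .sq_dists(X, centers[1L, , drop = FALSE])[, 1L]
  for (j in seq_len(k - 1L)) {
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1L)        # all points coincide with a center
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[j + 1L, ] <- X[pick, ]
    d2 <- pmin(d2, .sq_dists(X, centers[j + 1L, , drop = FALSE])[, 1L])
  }
  centers
}

.lloyd <- function(X, centers, max_iter, tol) {
  inertia_path <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- .sq_dists(X, centers)
    labels <- max.col(-d2, ties.method = "first")
    inertia_path <- c(inertia_path, sum(d2[cbind(seq_len(nrow(X)), labels)]))
    new_centers <- centers
    for (j in seq_len(nrow(centers))) {
      members <- labels == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(X[members, , drop = FALSE])
      } else {
        # re-seed an empty cluster at the point farthest from its center
        far <- which.max(d2[cbind(seq_len(nrow(X)), labels)])
        new_centers[j, ] <- X[far, ]
      }
    }
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- .sq_dists(X, centers)
  labels <- max.col(-d2, ties.method = "first")
  dist_own <- sqrt(d2[cbind(seq_len(nrow(X)), labels)])
  list(labels = labels, centers = centers,
       inertia = sum(dist_own^2), dist_to_center = dist_own,
       inertia_path = inertia_path, iterations = length(inertia_path))
}

#' K-means++ clustering
#'
#' K-means with probabilistic (++) seeding of the initial centres
#' proportional to squared distance from the centres chosen so far,
#' followed by Lloyd iterations to convergence; the best of `n_init`
#' restarts by within-cluster sum of squares is returned. Fully seeded and
#' deterministic.
#'
#' @param X numeric feature matrix (rows = observations) or a
#'   [spectrum_set()].
#' @param k number of clusters (`2 <= k <= n`... `n = k` gives one point
#'   per cluster).
#' @param seed integer seed.
#' @param n_init number of restarts (default 10).
#' @param max_iter Lloyd iteration cap (default 300).
#' @param tol centre-shift convergence tolerance (default 1e-6).
#' @return object of class `cluster_result`: `labels`, `centers`,
#'   `inertia`, `dist_to_center`, `inertia_path` (of the winning restart),
#'   `k`.
#' @export
kmeans_pp <- function(X, k, seed = 1L, n_init = 10L, max_iter = 300L,
                      tol = 1e-6) {
  if (inherits(X, "spectrum_set")) X <- X$intensities
  X <- as.matrix(X)
  k <- as.integer(k)
  if (k < 1L || nrow(X) < k)
    stop("need 1 <= k <= n (got k = ", k, ", n = ", nrow(X), ")",
         call. = FALSE)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      fit <- .lloyd(X, .kmeanspp_seed_centers(X, k), max_iter, tol)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  best$k <- k
  class(best) <- "cluster_result"
  best
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, n = %d, inertia = %.4g\n",
              x$k, length(x$labels), x$inertia))
  invisible(x)
}

#' Silhouette coefficient
#'
#' For each sample, `a_i` is its mean distance to the other samples of its
#' own cluster and `b_i` the smallest mean distance to the samples of any
#' other cluster; the per-sample silhouette is `(b_i - a_i) / max(a_i,
#' b_i)` and the silhouette coefficient SC is the mean over all N samples.
#' Samples in singleton clusters contribute 0. Euclidean distances.
#'
#' @param X numeric feature matrix or [spectrum_set()].
#' @param labels cluster label per row (>= 2 distinct values).
#' @return object of class `silhouette_result`: `sc`, `n`, and per-sample
#'   `a`, `b`, `s`.
#' @export
silhouette_score <- function(X, labels) {
  if (inherits(X, "spectrum_set")) X <- X$intensities
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("silhouette undefined for a single cluster", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  groups <- split(seq_len(n), labels)
  sizes <- lengths(groups)
  # n x K matrix of summed distances from each sample to each cluster
  sums <- vapply(groups, function(idx)
    rowSums(D[, idx, drop = FALSE]), numeric(n))
  a <- b <- s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[own]] == 1L) {
      a[i] <- 0; s[i] <- 0
      b[i] <- min(sums[i, names(groups) != own] /
                    sizes[names(groups) != own])
      next
    }
    a[i] <- sums[i, own] / (sizes[[own]] - 1L)
    b[i] <- min(sums[i, names(groups) != own] /
                  sizes[names(groups) != own])
    # coincident points: a = b = 0 reads as "no structure", s = 0
    s[i] <- if (max(a[i], b[i]) == 0) 0 else
      (b[i] - a[i]) / max(a[i], b[i])
  }
  structure(list(sc = mean(s), n = n, a = a, b = b, s = s),
            class = "silhouette_result")
}

#' Select the cluster count by silhouette
#'
#' Runs [kmeans_pp()] for each candidate `k` and returns the `k`
#' maximising the silhouette coefficient; ties go to the smaller `k`.
#' `k = 1` is excluded (the silhouette is undefined there); a `k_min`
#' below 2 is accepted and silently raised, with a note in the result.
#'
#' @param X numeric feature matrix or [spectrum_set()].
#' @param k_min,k_max candidate range (default 2..5).
#' @param seed integer seed shared by all candidate fits.
#' @param ... passed to [kmeans_pp()].
#' @return object of class `k_selection`: `best_k`, `silhouettes` (named
#'   by k), `k_evaluated`, `note`.
#' @export
select_k_by_silhouette <- function(X, k_min = 2L, k_max = 5L, seed = 1L,
                                   ...) {
  if (inherits(X, "spectrum_set")) X <- X$intensities
  X <- as.matrix(X)
  note <- NULL
  if (k_min < 2L) {
    note <- "k = 1 excluded: silhouette undefined for a single cluster"
    k_min <- 2L
  }
  ks <- seq.int(max(2L, k_min), k_max)
  stopifnot(length(ks) >= 1L, max(ks) <= nrow(X) - 1L)
  sc <- vapply(ks, function(k) {
    fit <- kmeans_pp(X, k, seed = seed, ...)
    silhouette_score(X, fit$labels)$sc
  }, numeric(1L))
  names(sc) <- ks
  structure(list(best_k = ks[which.max(sc)], silhouettes = sc,
                 k_evaluated = ks, note = note),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection> best k =", x$best_k, "\n")
  print(round(x$silhouettes, 4))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Random-forest feature importance over wavenumbers
#'
#' Trains a random-forest classifier (bootstrap CART trees, Gini
#' impurity, `sqrt(p)` candidate features per split) on the spectra with
#' the given (cluster) labels and returns the per-wavenumber
#' mean-decrease-in-impurity importances, normalised to sum 1.
#'
#' @param X numeric spectra matrix or [spectrum_set()].
#' @param labels class label per row (>= 2 classes).
#' @param n_trees number of trees (default 500).
#' @param mtry candidate features per split; default `floor(sqrt(p))`.
#' @param min_node minimum node size to attempt a split (default 1, i.e.
#'   trees grown to purity).
#' @param seed integer seed.
#' @return object of class `importance_profile`: `wavenumbers`,
#'   `importance` (sums to 1), `smoothed` (NULL until
#'   [smooth_importance()]), and the hyperparameters used.
#' @export
rf_importance <- function(X, labels, n_trees = 500L, mtry = NULL,
                          min_node = 1L, seed = 1L) {
  wn <- NULL
  if (inherits(X, "spectrum_set")) {
    wn <- as.numeric(X$grid)
    X <- X$intensities
  }
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(X))
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("random forest needs at least 2 classes", call. = FALSE)
  y <- match(labels, classes) - 1L
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  imp <- .rf_importance_cpp(X, y, length(classes), as.integer(n_trees),
                            as.integer(mtry), as.integer(min_node),
                            as.integer(seed))
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  if (is.null(wn)) wn <- seq_len(ncol(X))
  structure(list(wavenumbers = wn, importance = imp, smoothed = NULL,
                 n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 min_node = as.integer(min_node), seed = as.integer(seed)),
            class = "importance_profile")
}

#' Smooth an importance profile
#'
#' Centred moving average (boxcar) over a window of the stated width in
#' cm^-1 (the window shrinks symmetrically at the grid edges). A constant
#' profile is left unchanged and an interior spike of mass m becomes a
#' plateau of the same total mass.
#'
#' @param profile an [rf_importance()] result.
#' @param window smoothing window width in cm^-1 (default 15; must be at
#'   least the grid spacing).
#' @return the profile with `smoothed` filled in.
#' @export
smooth_importance <- function(profile, window = 15) {
  wn <- profile$wavenumbers
  spacing <- stats::median(diff(wn))
  if (window < spacing)
    stop("smoothing window ", window, " cm^-1 is below the grid spacing ",
         signif(spacing, 4), call. = FALSE)
  hw <- max(1L, floor(window / spacing / 2))
  x <- profile$importance
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - hw, 1L)
  hi <- pmin(seq_len(n) + hw, n)
  profile$smoothed <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  profile$window <- window
  profile
}

#' Top important bands
#'
#' Returns the wavenumbers of the `n_bands` highest local maxima of the
#' smoothed importance curve, greedily chosen so that any two reported
#' bands are at least `min_separation` cm^-1 apart (so the shoulders of a
#' single band are not reported twice). Boundary maxima count.
#'
#' @param profile an [rf_importance()] result (smoothed automatically with
#'   the default window if [smooth_importance()] has not been called).
#' @param n_bands number of bands to report.
#' @param min_separation minimal pairwise separation in cm^-1 (default 50).
#' @return numeric wavenumbers in decreasing order of importance.
#' @export
top_bands <- function(profile, n_bands = 2L, min_separation = 50) {
  stopifnot(n_bands >= 1L)
  if (is.null(profile$smoothed)) profile <- smooth_importance(profile)
  y <- profile$smoothed
  wn <- profile$wavenumbers
  # run-length compression so a plateau (e.g. a boxcar-smoothed spike)
  # counts as one maximum located at its centre
  r <- rle(signif(y, 10))   # quantized: cumsum round-off must not split runs
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  is_max <- vapply(seq_len(nr), function(j) {
    (j == 1L || r$values[j] > r$values[j - 1L]) &&
      (j == nr || r$values[j] > r$values[j + 1L])
  }, logical(1L))
  cand <- floor((starts[is_max] + ends[is_max]) / 2)
  cand <- cand[order(y[cand], decreasing = TRUE)]
  picked <- numeric(0)
  for (i in cand) {
    if (all(abs(wn[i] - picked) >= min_separation))
      picked <- c(picked, wn[i])
    if (length(picked) == n_bands) break
  }
  if (length(picked) < n_bands)
    stop("only ", length(picked), " separated local maxima found, ",
         n_bands, " requested", call. = FALSE)
  picked
}

#' Band-area feature matrix
#'
#' For every spectrum, the trapezoidal band area over `center +/-
#' halfwidth` for each requested band: the low-dimensional input of the
#' final clustering stage.
#'
#' @param set a [spectrum_set()].
#' @param bands numeric band centres in cm^-1 (must lie inside the grid).
#' @param halfwidth integration half width in cm^-1 (default 5).
#' @return numeric matrix (n_spectra x n_bands) with bands as column names.
#' @export
extract_band_features <- function(set, bands, halfwidth = 5) {
  rng <- range(as.numeric(set$grid))
  if (any(bands < rng[1L] | bands > rng[2L]))
    stop("band centre outside the wavenumber grid", call. = FALSE)
  out <- vapply(bands, function(b) band_areas(set, b, halfwidth),
                numeric(n_spectra(set)))
  out <- matrix(out, nrow = n_spectra(set))
  colnames(out) <- format(bands, trim = TRUE)
  out
}

#' Two-band molecular classification of spectra
#'
#' Standardises the two band features (zero mean, unit variance per band),
#' clusters them with K-means++ at k = 2, labels the cluster whose centre
#' has the larger protein-band coordinate "protein_rich" and the other
#' "nucleic_acid_rich", and attaches a per-spectrum normalised intensity
#' `1 - d_i / max_cluster(d)` (the spectrum at the cluster centre scores 1,
#' the farthest member 0; set `intensity_direction = "far_strong"` to flip
#' the convention) together with the silhouette coefficient of the
#' partition.
#'
#' @param features n x 2 matrix from [extract_band_features()].
#' @param protein_col which column holds the protein-marker band
#'   (default 2).
#' @param seed integer seed for K-means++.
#' @param intensity_direction `"center_strong"` (default) or
#'   `"far_strong"`.
#' @return object of class `region_call_result`: `call`
#'   (protein_rich/nucleic_acid_rich per spectrum), `intensity` in
#'   \[0, 1\], `sc`, `silhouette`, `clusters` (the [kmeans_pp()] result on
#'   standardised features), `protein_col`.
#' @export
classify_regions <- function(features, protein_col = 2L, seed = 1L,
                             intensity_direction = c("center_strong",
                                                     "far_strong")) {
  intensity_direction <- match.arg(intensity_direction)
  features <- as.matrix(features)
  if (ncol(features) != 2L)
    stop("exactly two band features are required", call. = FALSE)
  if (nrow(features) < 4L)
    stop("too few spectra to cluster", call. = FALSE)
  sds <- apply(features, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate features: band ", which(sds == 0)[1L],
         " is constant across spectra", call. = FALSE)
  Z <- scale(features)
  fit <- kmeans_pp(Z, 2L, seed = seed)
  protein_cluster <- which.max(fit$centers[, protein_col])
  call <- ifelse(fit$labels == protein_cluster,
                 "protein_rich", "nucleic_acid_rich")
  intensity <- numeric(nrow(Z))
  for (j in 1:2) {
    members <- fit$labels == j
    dmax <- max(fit$dist_to_center[members])
    intensity[members] <- if (dmax == 0) 1 else
      1 - fit$dist_to_center[members] / dmax
  }
  if (intensity_direction == "far_strong") intensity <- 1 - intensity
  sil <- silhouette_score(Z, fit$labels)
  structure(list(call = call, intensity = intensity, sc = sil$sc,
                 silhouette = sil, clusters = fit,
                 protein_col = protein_col,
                 intensity_direction = intensity_direction),
            class = "region_call_result")
}
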