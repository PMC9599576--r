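# Shared fixtures and independent oracles. Everything here is built in
# code at test time; no binary fixtures.

# small spectrum set on an arbitrary grid with full metadata
make_tiny_set <- function(n = 3L, grid = c(717, 720.5, 725, 731, 740)) {
  set.seed(42)
  spectrum_set(grid,
               matrix(round(runif(n * length(grid), 0, 10), 3), nrow = n),
               position_um = seq_len(n) - 1,
               model_label = rep("2D", n),
               truth_region = rep(c("nucleus", "cytoplasm", "ecm"),
                                  length.out = n))
}

# quiet generator: no noise, no hot-spot variation, no baseline
noise_free_config <- function(...) {
  generator_config(hotspot_cv = 0, noise_sd = 0, baseline_scale = 0, ...)
}

# independent silhouette oracle: literal transcription of the formula,
# one pairwise loop, no shared code with silhouette_score()
silhouette_oracle <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (length(same) == 0L) { s[i] <- 0; next }
    a_i <- mean(vapply(same, function(j) d(i, j), numeric(1L)))
    b_i <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      others <- which(labels == cl)
      mean(vapply(others, function(j) d(i, j), numeric(1L)))
    }, numeric(1L)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

# analytic mixture oracle for the generator's clean signal
clean_region_signature <- function(config, region) {
  grid <- seq(config$grid_lo, config$grid_hi, length.out = config$grid_n)
  w <- config$weights[[region]]
  sig <- numeric(length(grid))
  for (comp in names(w)) {
    b <- config$library$shared[config$library$shared$component == comp, ]
    if (nrow(b) == 0L) next
    for (r in seq_len(nrow(b))) {
      g <- b$fwhm[r] / 2
      sig <- sig + w[[comp]] * b$amplitude[r] * g^2 /
        ((grid - b$center[r])^2 + g^2)
    }
  }
  sig
}

# well-separated Gaussian blobs in `dim` dimensions
make_blobs <- function(n_per, centers, sd = 0.5, dim = 2L, seed = 99L) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
    matrix(rnorm(n_per * dim, sd = sd), n_per, dim) +
      matrix(centers[j, ], n_per, dim, byrow = TRUE)
  }))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# engineered two-latent-factor model pair for the quadrant-rule recovery
# benchmark: class separation is split across two orthogonal spectral
# directions whose signs at the planted band positions realise the
# (PC1 > 0, PC2 < 0) / (PC1 < 0, PC2 > 0) structure of the score plot.
make_engineered_pair <- function(n_per = 150L, seed = 7L) {
  lib <- default_band_library()
  grid <- default_grid()
  wn <- as.numeric(grid)
  e2 <- component_signature(lib$model_specific[["2D"]], grid)
  e3 <- component_signature(lib$model_specific[["3D"]], grid)
  d <- e2 / sqrt(sum(e2^2)) - e3 / sqrt(sum(e3^2))
  # both factors carry the band pattern (+d and -d); a shared smooth
  # carrier bump in the band-free 1530 cm^-1 region absorbs the
  # orthogonality constraint without touching the band positions
  # spread over several band-free regions so its peak stays below the
  # band loadings after normalisation
  carrier <- exp(-((wn - 745) / 15)^2) + exp(-((wn - 930) / 25)^2) +
    exp(-((wn - 1175) / 25)^2) + exp(-((wn - 1540) / 25)^2) +
    exp(-((wn - 1760) / 30)^2)
  beta <- sqrt(sum(d^2) / sum(carrier^2))
  gamma <- (sum(d^2) + beta * sum(d * carrier)) /
    (sum(d * carrier) + beta * sum(carrier^2))
  v1 <- d + beta * carrier
  v2 <- -d + gamma * carrier
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- v2 / sqrt(sum(v2^2))
  base <- component_signature(lib$shared, grid)
  set.seed(seed)
  # latent geometry: class means (+1, -1) / (-1, +1); the u-factor's
  # within-class spread dominates so the PCA rotation angle stays small
  # enough that the class means land in quadrants 4 and 2
  mk <- function(mu_u, mu_v, n) {
    u <- rnorm(n, mu_u, 0.8)
    v <- rnorm(n, mu_v, 0.4)
    t(vapply(seq_len(n), function(i)
      base + 5 * u[i] * v1 + 2.5 * v[i] * v2 +
        rnorm(length(base), sd = 0.01),
      numeric(length(base))))
  }
  X <- rbind(mk(+1, -1, n_per), mk(-1, +1, n_per))
  spectrum_set(grid, X - min(X),
               model_label = rep(c("2D", "3D"), each = n_per))
}
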