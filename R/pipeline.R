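# End-to-end orchestration: crop to the acquisition window, run the
# discrimination stage (PCA -> ellipses -> key bands -> KNN) or the
# region-mapping stage (k selection -> forest importance -> top bands ->
# two-band clustering), attach micrometre positions, and score against the
# generator's ground truth.

#' Pipeline configuration
#'
#' Every numeric default left open by the analysis design is collected
#' here and echoed into the run reports, so a run is auditable from its
#' artifacts alone.
#'
#' @param window_lo,window_hi analysis window in cm^-1 (717-1827).
#' @param n_components PCA components retained (default 2).
#' @param knn_k KNN neighbour count (default 11).
#' @param train_fraction training share of the KNN split (default 0.8).
#' @param ellipse_level confidence-ellipse level (default 0.95).
#' @param loading_threshold key-band loading threshold, as a fraction of
#'   the per-component maximum absolute loading (default 0.5).
#' @param k_min,k_max candidate cluster counts (default 2..5).
#' @param n_trees random-forest size (default 500).
#' @param smoothing_window importance smoothing window, cm^-1 (default 15).
#' @param min_separation minimal separation of reported bands, cm^-1
#'   (default 50).
#' @param band_halfwidth band-area integration half width, cm^-1
#'   (default 5).
#' @param seed integer seed used by every stochastic stage.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_lo = 717, window_hi = 1827,
                            n_components = 2L, knn_k = 11L,
                            train_fraction = 0.8, ellipse_level = 0.95,
                            loading_threshold = 0.5,
                            k_min = 2L, k_max = 5L, n_trees = 500L,
                            smoothing_window = 15, min_separation = 50,
                            band_halfwidth = 5, seed = 1L) {
  stopifnot(window_lo < window_hi, n_components >= 2L, knn_k >= 1L,
            train_fraction > 0, train_fraction < 1,
            ellipse_level > 0, ellipse_level < 1,
            loading_threshold > 0, loading_threshold <= 1,
            k_max >= max(2L, k_min), n_trees >= 1L,
            band_halfwidth > 0)
  structure(list(window_lo = window_lo, window_hi = window_hi,
                 n_components = as.integer(n_components),
                 knn_k = as.integer(knn_k),
                 train_fraction = train_fraction,
                 ellipse_level = ellipse_level,
                 loading_threshold = loading_threshold,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_trees = as.integer(n_trees),
                 smoothing_window = smoothing_window,
                 min_separation = min_separation,
                 band_halfwidth = band_halfwidth,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# canonical marker positions used to orient the two-band clustering
.protein_marker <- 1655   # amide I
.nucleic_marker <- 782    # O-P-O stretching

#' Discrimination stage: PCA + ellipses + key bands + KNN
#'
#' Crops both labeled sets to the analysis window (resampling the second
#' onto the first's grid if they differ), merges them, fits a PCA, fits a
#' confidence ellipse per model in PC1/PC2 score space, tests whether the
#' ellipses overlap, extracts key bands by the quadrant rule, and computes
#' the KNN validation score.
#'
#' @param cfg a [pipeline_config()].
#' @param set_2d,set_3d labeled [spectrum_set()]s (model_label set).
#' @param out_dir optional directory; when given, scores/key-band CSVs and
#'   a JSON report are written there.
#' @return a list of class `discrimination_report`: `pca`, `ellipses`,
#'   `overlap`, `key_bands`, `knn`, `config`.
#' @export
run_discrimination <- function(cfg, set_2d, set_3d, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  set_2d <- crop_window(set_2d, cfg$window_lo, cfg$window_hi)
  set_3d <- crop_window(set_3d, cfg$window_lo, cfg$window_hi)
  if (length(set_2d$grid) != length(set_3d$grid) ||
      any(abs(as.numeric(set_2d$grid) - as.numeric(set_3d$grid)) > 1e-9))
    set_3d <- resample_to_grid(set_3d, set_2d$grid)
  merged <- bind_spectra(set_2d, set_3d)
  labels <- merged$meta$model_label
  if (anyNA(labels)) stop("all spectra must carry a model label",
                          call. = FALSE)
  pca <- orient_pca_to_labels(fit_pca(merged, cfg$n_components), labels)
  sc2 <- pca$scores[labels == "2D", 1:2, drop = FALSE]
  sc3 <- pca$scores[labels == "3D", 1:2, drop = FALSE]
  ellipses <- list("2D" = confidence_ellipse(sc2, cfg$ellipse_level),
                   "3D" = confidence_ellipse(sc3, cfg$ellipse_level))
  overlap <- ellipses_overlap(ellipses[["2D"]], ellipses[["3D"]])
  key_bands <- key_bands_from_loadings(pca, cfg$loading_threshold)
  knn <- knn_fit_score(pca$scores[, 1:2], labels, k = cfg$knn_k,
                       train_fraction = cfg$train_fraction, seed = cfg$seed)
  report <- structure(list(pca = pca, ellipses = ellipses,
                           overlap = overlap, key_bands = key_bands,
                           knn = knn, config = cfg),
                      class = "discrimination_report")
  if (!is.null(out_dir)) .write_discrimination_artifacts(report, out_dir)
  report
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("<discrimination_report>\n")
  cat(sprintf("  explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$pca$explained),
                    collapse = ", ")))
  cat("  ellipses overlap:", x$overlap, "\n")
  cat(sprintf("  KNN score: %.4f (k = %d, %d test spectra)\n",
              x$knn$score, x$knn$k, x$knn$n_test))
  cat("  key bands: 2D:",
      paste(round(x$key_bands$wavenumber[
        !is.na(x$key_bands$model) & x$key_bands$model == "2D"]),
        collapse = ", "),
      "| 3D:",
      paste(round(x$key_bands$wavenumber[
        !is.na(x$key_bands$model) & x$key_bands$model == "3D"]),
        collapse = ", "), "\n")
  invisible(x)
}

.ellipse_to_list <- function(e) {
  list(center = as.numeric(e$center), semi_axes = as.numeric(e$semi_axes),
       angle = e$angle, level = e$level)
}

.write_discrimination_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- data.frame(report$pca$scores,
                   model_label = report$pca$labels)
  utils::write.csv(sc, file.path(out_dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(report$key_bands, file.path(out_dir, "key_bands.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(schema = "wirespec/discrimination/1",
         config = unclass(report$config),
         explained = report$pca$explained,
         ellipses = lapply(report$ellipses, .ellipse_to_list),
         overlap = report$overlap,
         knn_score = report$knn$score,
         knn_k = report$knn$k,
         n_test = report$knn$n_test),
    file.path(out_dir, "discrimination.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Region-mapping stage: forest-guided two-band clustering
#'
#' Crops the scan to the analysis window, selects the cluster count by
#' silhouette on the full spectra, trains a random forest on the selected
#' cluster labels to rank wavenumber importance, smooths the importance
#' curve, picks the two top bands, extracts the two band-area features,
#' and clusters them at k = 2 into protein-rich and nucleic-acid-rich
#' calls at each micrometre position. The chosen band nearest the amide I
#' marker (1655 cm^-1) is taken as the protein axis.
#'
#' @param cfg a [pipeline_config()].
#' @param scan a [spectrum_set()] with positions (>= 10 spectra).
#' @param out_dir optional artifact directory.
#' @return a list of class `region_map`: `map` (data.frame with
#'   position_um, call, intensity, truth_region), `bands` (the two chosen
#'   wavenumbers, protein band first), `k_selection`, `importance`, `sc`,
#'   `calls` (the [classify_regions()] result), `config`.
#' @export
run_region_mapping <- function(cfg, scan, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (n_spectra(scan) < 10L)
    stop("need at least 10 spectra for a stable region map", call. = FALSE)
  scan <- crop_window(scan, cfg$window_lo, cfg$window_hi)
  ksel <- select_k_by_silhouette(scan, cfg$k_min, cfg$k_max,
                                 seed = cfg$seed)
  base_fit <- kmeans_pp(scan$intensities, ksel$best_k, seed = cfg$seed)
  imp <- rf_importance(scan, base_fit$labels, n_trees = cfg$n_trees,
                       seed = cfg$seed)
  imp <- smooth_importance(imp, cfg$smoothing_window)
  bands <- top_bands(imp, n_bands = 2L,
                     min_separation = cfg$min_separation)
  # orient: the band nearer the amide I marker is the protein axis
  protein_band <- bands[which.min(abs(bands - .protein_marker))]
  nucleic_band <- bands[which.max(abs(bands - .protein_marker))]
  ordered_bands <- c(nucleic_band, protein_band)
  features <- extract_band_features(scan, ordered_bands,
                                    cfg$band_halfwidth)
  calls <- classify_regions(features, protein_col = 2L, seed = cfg$seed)
  map <- data.frame(position_um = scan$meta$position_um,
                    call = calls$call,
                    intensity = calls$intensity,
                    truth_region = scan$meta$truth_region,
                    stringsAsFactors = FALSE)
  report <- structure(list(map = map,
                           bands = c(protein = protein_band,
                                     nucleic = nucleic_band),
                           k_selection = ksel, importance = imp,
                           sc = calls$sc, calls = calls, config = cfg),
                      class = "region_map")
  if (!is.null(out_dir)) .write_region_artifacts(report, out_dir)
  report
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map>\n")
  cat("  selected k:", x$k_selection$best_k, "\n")
  cat(sprintf("  bands: protein %.1f cm^-1, nucleic acid %.1f cm^-1\n",
              x$bands["protein"], x$bands["nucleic"]))
  cat(sprintf("  silhouette of two-band clustering: %.4f\n", x$sc))
  cat("  calls:", paste(names(table(x$map$call)), table(x$map$call),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

.write_region_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$map, file.path(out_dir, "region_map.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(wavenumber = report$importance$wavenumbers,
                              importance = report$importance$importance,
                              smoothed = report$importance$smoothed),
                   file.path(out_dir, "importance.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(schema = "wirespec/region-map/1",
         config = unclass(report$config),
         best_k = report$k_selection$best_k,
         silhouettes_by_k = as.list(report$k_selection$silhouettes),
         bands = as.list(report$bands),
         silhouette_two_band = report$sc),
    file.path(out_dir, "region_map.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Score a region map against generator ground truth
#'
#' Maps the generator's truth regions onto the two molecular classes
#' (nucleus -> nucleic_acid_rich; cytoplasm and ECM -> protein_rich) and
#' reports the confusion counts, per-class recall and overall accuracy.
#'
#' @param map a `region_map` (or its `map` data.frame) with `truth_region`
#'   present.
#' @return list of class `truth_score`: `accuracy`, `recall` (named by
#'   class), `confusion` (table), `n`.
#' @export
score_against_truth <- function(map) {
  if (inherits(map, "region_map")) map <- map$map
  if (anyNA(map$truth_region))
    stop("truth_region is required to score a region map", call. = FALSE)
  truth <- ifelse(map$truth_region == "nucleus",
                  "nucleic_acid_rich", "protein_rich")
  confusion <- table(truth = truth, call = map$call)
  classes <- sort(unique(truth))
  recall <- vapply(classes, function(cl)
    mean(map$call[truth == cl] == cl), numeric(1L))
  structure(list(accuracy = mean(map$call == truth),
                 recall = recall, confusion = confusion,
                 n = nrow(map)),
            class = "truth_score")
}

#' @export
print.truth_score <- function(x, ...) {
  cat(sprintf("<truth_score> accuracy %.3f on %d positions\n",
              x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}
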