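#' Wavenumber grid constructor
#'
#' A wavenumber grid is the shared Raman-shift axis (cm^-1) on which every
#' spectrum of a [spectrum_set()] is sampled. Values must be strictly
#' increasing, positive and of length at least 2.
#'
#' @param values numeric vector of wavenumbers in cm^-1.
#' @return a numeric vector of class `wavenumber_grid`.
#' @export
wavenumber_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a wavenumber grid needs at least 2 points", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("wavenumber grid contains non-finite values", call. = FALSE)
  if (any(values <= 0))
    stop("wavenumbers must be positive", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  structure(values, class = "wavenumber_grid")
}

#' Default acquisition grid
#'
#' The default Raman window spans 717 to 1827 cm^-1 sampled at 1015 equally
#' spaced points, matching the acquisition window of the instrument this
#' package emulates.
#'
#' @param lo,hi window limits in cm^-1.
#' @param n number of grid points.
#' @return a [wavenumber_grid()].
#' @export
default_grid <- function(lo = 717, hi = 1827, n = 1015L) {
  wavenumber_grid(seq(lo, hi, length.out = n))
}

.region_levels <- c("nucleus", "cytoplasm", "ecm")
.model_levels <- c("2D", "3D")

#' Spectrum set constructor
#'
#' Container for a set of spectra on a shared wavenumber grid with
#' per-spectrum metadata: position along the wire (micrometres), culture-model
#' label ("2D"/"3D" or NA) and an optional ground-truth region label
#' ("nucleus", "cytoplasm" or "ecm") used by the synthetic generator.
#'
#' @param grid a [wavenumber_grid()] or numeric vector coercible to one.
#' @param intensities numeric matrix, one row per spectrum, one column per
#'   grid point.
#' @param position_um optional numeric vector of positions (non-decreasing).
#' @param model_label optional character vector ("2D"/"3D"/NA).
#' @param truth_region optional character vector of region labels.
#' @return an object of class `spectrum_set` with fields `grid`,
#'   `intensities` and `meta` (a data.frame).
#' @export
spectrum_set <- function(grid, intensities, position_um = NULL,
                         model_label = NULL, truth_region = NULL) {
  if (!inherits(grid, "wavenumber_grid")) grid <- wavenumber_grid(grid)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- nrow(intensities)
  if (ncol(intensities) != length(grid))
    stop("intensity matrix has ", ncol(intensities),
         " columns but grid has ", length(grid), " points", call. = FALSE)
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("intensities contain missing or non-finite values", call. = FALSE)
  chk <- function(x, len, what) {
    if (is.null(x)) return(rep(NA, len))
    if (length(x) != len)
      stop(what, " must have one entry per spectrum", call. = FALSE)
    x
  }
  position_um <- as.numeric(chk(position_um, n, "position_um"))
  if (!all(is.na(position_um)) && any(diff(position_um[!is.na(position_um)]) < 0))
    stop("positions must be non-decreasing along the scan", call. = FALSE)
  model_label <- as.character(chk(model_label, n, "model_label"))
  if (!all(is.na(model_label) | model_label %in% .model_levels))
    stop("model_label must be one of ", paste(.model_levels, collapse = ", "),
         call. = FALSE)
  truth_region <- as.character(chk(truth_region, n, "truth_region"))
  if (!all(is.na(truth_region) | truth_region %in% .region_levels))
    stop("truth_region must be one of ",
         paste(.region_levels, collapse = ", "), call. = FALSE)
  dimnames(intensities) <- NULL
  structure(list(
    grid = grid,
    intensities = intensities,
    meta = data.frame(position_um = position_um,
                      model_label = model_label,
                      truth_region = truth_region,
                      stringsAsFactors = FALSE)
  ), class = "spectrum_set")
}

#' Number of spectra in a set
#' @param set a [spectrum_set()].
#' @return integer count.
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' @export
print.spectrum_set <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<spectrum_set> %d spectra x %d wavenumbers [%.1f, %.1f] cm^-1\n",
              n_spectra(x), length(g), min(g), max(g)))
  lab <- x$meta$model_label
  if (!all(is.na(lab)))
    cat("  model labels:", paste(names(table(lab)), table(lab),
                                 sep = "=", collapse = ", "), "\n")
  reg <- x$meta$truth_region
  if (!all(is.na(reg)))
    cat("  truth regions:", paste(names(table(reg)), table(reg),
                                  sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset rows of a spectrum set
#' @param set a [spectrum_set()].
#' @param i row index.
#' @return a [spectrum_set()] with the selected spectra.
#' @export
subset_spectra <- function(set, i) {
  spectrum_set(set$grid, set$intensities[i, , drop = FALSE],
               position_um = set$meta$position_um[i],
               model_label = set$meta$model_label[i],
               truth_region = set$meta$truth_region[i])
}

#' Row-bind two spectrum sets on an identical grid
#'
#' Positions are kept only when their concatenation is still
#' non-decreasing (i.e. the two sets are consecutive pieces of one scan);
#' otherwise they are dropped, since positions from different wires are
#' not comparable.
#'
#' @param a,b spectrum sets sharing the same grid.
#' @return combined [spectrum_set()].
#' @export
bind_spectra <- function(a, b) {
  if (length(a$grid) != length(b$grid) ||
      any(abs(as.numeric(a$grid) - as.numeric(b$grid)) > 1e-9))
    stop("spectrum sets are not on the same grid", call. = FALSE)
  pos <- c(a$meta$position_um, b$meta$position_um)
  ok <- !anyNA(pos) && all(diff(pos) >= 0)
  spectrum_set(a$grid, rbind(a$intensities, b$intensities),
               position_um = if (ok) pos else NULL,
               model_label = c(a$meta$model_label, b$meta$model_label),
               truth_region = c(a$meta$truth_region, b$meta$truth_region))
}

.meta_cols <- c("position_um", "model_label", "truth_region")

#' Write a spectrum set to CSV
#'
#' One fixed dialect: comma separator, "." decimal mark, UTF-8, mandatory
#' header. The three reserved metadata columns (`position_um`, `model_label`,
#' `truth_region`) precede the intensity columns, whose headers are the
#' wavenumbers. Numbers are written with 17 significant digits so the
#' read/write round trip is lossless.
#'
#' @param set a [spectrum_set()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_spectra_csv <- function(set, path) {
  num <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- ""
    out
  }
  header <- paste(c(.meta_cols, num(as.numeric(set$grid))), collapse = ",")
  lab <- set$meta$model_label
  reg <- set$meta$truth_region
  lab[is.na(lab)] <- ""
  reg[is.na(reg)] <- ""
  body <- character(n_spectra(set))
  for (i in seq_len(n_spectra(set))) {
    body[i] <- paste(c(num(set$meta$position_um[i]), lab[i], reg[i],
                       num(set$intensities[i, ])), collapse = ",")
  }
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a spectrum set from CSV
#'
#' Inverse of [write_spectra_csv()]. The header row must start with the
#' reserved metadata columns followed by strictly increasing numeric
#' wavenumbers; all data rows must have the header's field count.
#'
#' @param path input file path.
#' @return a [spectrum_set()].
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("CSV has no data rows", call. = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  header <- fields[[1L]]
  n_meta <- sum(.meta_cols %in% header[seq_len(min(3L, length(header)))])
  if (!identical(header[seq_len(n_meta)], .meta_cols[seq_len(n_meta)]))
    stop("reserved metadata columns must precede intensity columns",
         call. = FALSE)
  wn <- suppressWarnings(as.numeric(header[-seq_len(n_meta)]))
  if (anyNA(wn)) stop("non-numeric wavenumber in header", call. = FALSE)
  if (any(diff(wn) <= 0))
    stop("wavenumber header is not strictly increasing", call. = FALSE)
  rows <- fields[-1L]
  nf <- lengths(rows)
  if (any(nf != length(header)))
    stop("ragged CSV: row(s) ", paste(which(nf != length(header)),
                                      collapse = ", "),
         " do not match the header field count", call. = FALSE)
  m <- do.call(rbind, rows)
  blank2na <- function(x) { x[x == ""] <- NA; x }
  meta <- list(position_um = NULL, model_label = NULL, truth_region = NULL)
  for (j in seq_len(n_meta)) meta[[.meta_cols[j]]] <- blank2na(m[, j])
  intens <- matrix(as.numeric(m[, -seq_len(n_meta), drop = FALSE]),
                   nrow = nrow(m))
  if (anyNA(intens)) stop("non-numeric or missing intensity value",
                          call. = FALSE)
  spectrum_set(wavenumber_grid(wn), intens,
               position_um = if (is.null(meta$position_um)) NULL else
                 as.numeric(meta$position_um),
               model_label = meta$model_label,
               truth_region = meta$truth_region)
}

#' Crop a spectrum set to a wavenumber window
#'
#' Retains grid columns with `lo <= nu <= hi` (closed interval on both ends).
#' Metadata is unchanged. On the default grid, cropping to \[717, 1827\]
#' keeps all 1015 features.
#'
#' @param set a [spectrum_set()].
#' @param lo,hi window limits in cm^-1, `lo < hi`.
#' @return cropped [spectrum_set()].
#' @export
crop_window <- function(set, lo = 717, hi = 1827) {
  if (!(lo < hi)) stop("crop window requires lo < hi", call. = FALSE)
  keep <- as.numeric(set$grid) >= lo & as.numeric(set$grid) <= hi
  if (sum(keep) < 2L)
    stop("crop window [", lo, ", ", hi, "] retains fewer than 2 grid points",
         call. = FALSE)
  spectrum_set(wavenumber_grid(as.numeric(set$grid)[keep]),
               set$intensities[, keep, drop = FALSE],
               position_um = set$meta$position_um,
               model_label = set$meta$model_label,
               truth_region = set$meta$truth_region)
}

#' Resample a spectrum set onto a target grid
#'
#' Linear interpolation of every spectrum onto `grid`. The target grid must
#' lie inside the source range; extrapolation is refused.
#'
#' @param set a [spectrum_set()].
#' @param grid target [wavenumber_grid()].
#' @return resampled [spectrum_set()].
#' @export
resample_to_grid <- function(set, grid) {
  if (!inherits(grid, "wavenumber_grid")) grid <- wavenumber_grid(grid)
  src <- as.numeric(set$grid)
  tgt <- as.numeric(grid)
  if (min(tgt) < min(src) || max(tgt) > max(src))
    stop("target grid [", min(tgt), ", ", max(tgt),
         "] extends beyond the source range [", min(src), ", ", max(src),
         "]",
         call. = FALSE)
  if (length(tgt) == length(src) && all(abs(tgt - src) < 1e-12))
    return(set)
  out <- t(apply(set$intensities, 1L,
                 function(y) stats::approx(src, y, xout = tgt)$y))
  if (n_spectra(set) == 1L) out <- matrix(out, nrow = 1L)
  spectrum_set(grid, out,
               position_um = set$meta$position_um,
               model_label = set$meta$model_label,
               truth_region = set$meta$truth_region)
}
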