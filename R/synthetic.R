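# Synthetic SERS line-scan generator. Spectra are sums of Lorentzian bands
# from a curated band library (amide I ~1655 and the nucleic-acid O-P-O
# band ~782 are the dominant markers), mixed with region-dependent component
# weights, scaled by a per-spectrum log-normal hot-spot factor, and degraded
# by a polynomial baseline and additive Gaussian noise.

#' Evaluate an expression with a temporary RNG seed
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

.components <- c("lipid", "protein", "nucleic_acid", "amino_acid",
                 "phospholipid")

#' Raman band definition
#'
#' @param center band centre in cm^-1.
#' @param component molecular component, one of `"lipid"`, `"protein"`,
#'   `"nucleic_acid"`, `"amino_acid"`, `"phospholipid"`.
#' @param amplitude peak amplitude (relative intensity, >= 0).
#' @param fwhm full width at half maximum in cm^-1 (> 0). 12 cm^-1 is a
#'   typical condensed-phase Raman line width.
#' @return a one-row data.frame describing the band.
#' @export
band <- function(center, component, amplitude = 1, fwhm = 12) {
  stopifnot(fwhm > 0, amplitude >= 0)
  component <- match.arg(component, .components)
  data.frame(center = center, fwhm = fwhm, amplitude = amplitude,
             component = component, stringsAsFactors = FALSE)
}

#' Default band library
#'
#' The shared list holds the strong bands seen in both culture models
#' (amide I ~1655, nucleic-acid O-P-O ~782, lipid CH2 ~1449, ...). The
#' model-specific lists hold the discriminating bands: the 3D (spheroid)
#' model adds protein-associated bands at 851, 1002, 1246 and 1662 cm^-1
#' attributed to extracellular-matrix proteins, while the 2D (monolayer)
#' model adds lipid/phospholipid/nucleic-acid bands at 794, 1096, 1377 and
#' 1628 cm^-1. Amplitudes are generator free parameters: the two marker
#' bands (782, 1655) carry the largest amplitude, the remaining bands are
#' moderate.
#'
#' @return a list of class `band_library` with elements `shared` (data.frame
#'   of bands) and `model_specific` (named list with `"2D"` and `"3D"`
#'   band data.frames).
#' @export
default_band_library <- function() {
  shared <- rbind(
    band(1782, "lipid",        0.30),
    band(1655, "protein",      1.00),
    band(1449, "lipid",        0.60),
    band(1320, "lipid",        0.40, fwhm = 30),  # broad 1306-1339 envelope
    band(1128, "protein",      0.35),
    band(1097, "phospholipid", 0.40),
    band(1003, "amino_acid",   0.50),
    band(937,  "protein",      0.30),
    band(782,  "nucleic_acid", 1.00)
  )
  spec2d <- rbind(
    band(1628, "lipid",        0.50),
    band(1377, "lipid",        0.50),
    band(1096, "phospholipid", 0.50),
    band(794,  "nucleic_acid", 0.50)
  )
  spec3d <- rbind(
    band(1662, "protein",      0.70),
    band(1448, "lipid",        0.50),
    band(1336, "nucleic_acid", 0.50),
    band(1246, "protein",      0.50),
    band(1002, "amino_acid",   0.50),
    band(851,  "amino_acid",   0.50)
  )
  lib <- list(shared = shared,
              model_specific = list("2D" = spec2d, "3D" = spec3d))
  class(lib) <- "band_library"
  validate_band_library(lib)
  lib
}

#' Validate a band library
#'
#' Checks the structural invariants: positive widths, known components, the
#' shared list containing the two marker bands (782 and ~1655 cm^-1) and the
#' 3D-specific list containing the four protein-associated bands at 851,
#' 1002, 1246 and 1662 cm^-1.
#'
#' @param lib a `band_library`.
#' @return `lib`, invisibly, or an error.
#' @export
validate_band_library <- function(lib) {
  all_bands <- rbind(lib$shared, lib$model_specific[["2D"]],
                     lib$model_specific[["3D"]])
  stopifnot(all(all_bands$fwhm > 0), all(all_bands$amplitude >= 0),
            all(all_bands$component %in% .components))
  if (!all(c(782) %in% lib$shared$center) ||
      !any(abs(lib$shared$center - 1655) <= 5))
    stop("shared band list must contain 782 and ~1655 cm^-1", call. = FALSE)
  if (!all(c(851, 1002, 1246, 1662) %in% lib$model_specific[["3D"]]$center))
    stop("3D-specific list must contain bands at 851, 1002, 1246, 1662",
         call. = FALSE)
  invisible(lib)
}

#' Sum-of-Lorentzians component signature
#'
#' Evaluates `sum_b amplitude_b * gamma_b^2 / ((nu - center_b)^2 + gamma_b^2)`
#' with `gamma = fwhm / 2` on the grid; a band's value at its centre is its
#' amplitude and at `center +/- fwhm/2` exactly half of it.
#'
#' @param bands a data.frame of bands (rows from [band()]), possibly empty.
#' @param grid a [wavenumber_grid()] or numeric vector.
#' @return numeric vector of intensities on the grid (all >= 0).
#' @export
component_signature <- function(bands, grid) {
  nu <- as.numeric(grid)
  out <- numeric(length(nu))
  if (is.null(bands) || nrow(bands) == 0L) return(out)
  for (i in seq_len(nrow(bands))) {
    g <- bands$fwhm[i] / 2
    out <- out + bands$amplitude[i] * g^2 / ((nu - bands$center[i])^2 + g^2)
  }
  out
}

.default_weights <- function() {
  # Regions differ only in protein and nucleic-acid abundance -- the axis
  # the downstream clustering maps; structural components are held constant.
  list(
    nucleus   = c(lipid = 0.6, protein = 0.5, nucleic_acid = 1.00,
                  amino_acid = 0.5, phospholipid = 0.5),
    cytoplasm = c(lipid = 0.6, protein = 1.0, nucleic_acid = 0.25,
                  amino_acid = 0.5, phospholipid = 0.5),
    ecm       = c(lipid = 0.6, protein = 1.2, nucleic_acid = 0.05,
                  amino_acid = 0.5, phospholipid = 0.5)
  )
}

.default_layout <- function() {
  # Alternating cytoplasm/nucleus segments flanked by ECM, mimicking a wire
  # threading two cells of a monolayer.
  data.frame(
    region = c("ecm", "cytoplasm", "nucleus", "cytoplasm", "nucleus",
               "cytoplasm", "ecm"),
    length_um = c(5, 10, 8, 10, 8, 10, 5),
    stringsAsFactors = FALSE
  )
}

#' Generator configuration
#'
#' Collects every free parameter of the synthetic line-scan generator.
#'
#' @param grid_lo,grid_hi,grid_n spectral window (cm^-1) and feature count;
#'   defaults reproduce the 717-1827 cm^-1 window with 1015 features.
#' @param layout data.frame with columns `region`
#'   (nucleus/cytoplasm/ecm) and `length_um` (>= 1); one spectrum is placed
#'   at every `step_um` within each segment.
#' @param weights named list (per region) of named component-weight vectors.
#' @param library a `band_library`; defaults to [default_band_library()].
#' @param hotspot_cv coefficient of variation of the multiplicative
#'   log-normal per-spectrum hot-spot factor; the default 0.042 matches the
#'   ~4.2% relative standard deviation of band areas measured along a
#'   uniformly enhancing wire.
#' @param noise_sd standard deviation of additive Gaussian noise, in units
#'   of the (unit) maximum band amplitude.
#' @param baseline_degree,baseline_scale polynomial baseline: per spectrum,
#'   `degree + 1` coefficients are drawn from Uniform(0, scale) and the
#'   polynomial is evaluated on the window rescaled to \[0, 1\]; mimics a
#'   slowly varying fluorescence background.
#' @param step_um scan step in micrometres (1 um acquisition steps).
#' @param seed integer seed governing all randomness of a simulation.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(grid_lo = 717, grid_hi = 1827, grid_n = 1015L,
                             layout = .default_layout(),
                             weights = .default_weights(),
                             library = default_band_library(),
                             hotspot_cv = 0.042,
                             noise_sd = 0.05,
                             baseline_degree = 2L,
                             baseline_scale = 0.1,
                             step_um = 1,
                             seed = 1L) {
  stopifnot(hotspot_cv >= 0, noise_sd >= 0, baseline_degree >= 0,
            baseline_scale >= 0, step_um > 0)
  if (nrow(layout) > 0L) {
    stopifnot(all(layout$region %in% .region_levels),
              all(layout$length_um >= 1))
  }
  for (w in weights) stopifnot(all(w >= 0))
  validate_band_library(library)
  structure(list(grid_lo = grid_lo, grid_hi = grid_hi,
                 grid_n = as.integer(grid_n),
                 layout = layout, weights = weights, library = library,
                 hotspot_cv = hotspot_cv, noise_sd = noise_sd,
                 baseline_degree = as.integer(baseline_degree),
                 baseline_scale = baseline_scale,
                 step_um = step_um, seed = as.integer(seed)),
            class = "generator_config")
}

.region_signature <- function(config, region, extra_bands = NULL) {
  grid <- seq(config$grid_lo, config$grid_hi, length.out = config$grid_n)
  w <- config$weights[[region]]
  sig <- numeric(length(grid))
  for (comp in names(w)) {
    b <- config$library$shared[config$library$shared$component == comp, ,
                               drop = FALSE]
    sig <- sig + w[[comp]] * component_signature(b, grid)
  }
  if (!is.null(extra_bands)) sig <- sig + component_signature(extra_bands, grid)
  sig
}

.render_spectra <- function(config, signatures) {
  # signatures: n x p matrix of clean mixtures, one row per spectrum
  n <- nrow(signatures)
  p <- ncol(signatures)
  x01 <- seq(0, 1, length.out = p)
  s <- sqrt(log(1 + config$hotspot_cv^2))
  hot <- if (s > 0) stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
         else rep(1, n)
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    bl <- numeric(p)
    if (config$baseline_scale > 0) {
      coef <- stats::runif(config$baseline_degree + 1L, 0,
                           config$baseline_scale)
      for (d in seq_along(coef)) bl <- bl + coef[d] * x01^(d - 1L)
    }
    out[i, ] <- bl + hot[i] * signatures[i, ]
  }
  if (config$noise_sd > 0)
    out <- out + matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
  out
}

#' Simulate a SERS line scan along a wire
#'
#' Places one spectrum per `step_um` along the configured region layout.
#' Each spectrum is `baseline + hotspot * sum_c weight_c(region) *
#' signature_c + noise`; the region of every position is recorded as
#' `truth_region`. Identical configuration (including seed) gives
#' bit-identical output.
#'
#' @param config a [generator_config()].
#' @return a [spectrum_set()] with `position_um` and `truth_region` set.
#' @export
simulate_line_scan <- function(config = generator_config()) {
  if (nrow(config$layout) == 0L)
    stop("layout has no segments", call. = FALSE)
  n_per <- as.integer(round(config$layout$length_um / config$step_um))
  regions <- rep(config$layout$region, n_per)
  n <- length(regions)
  grid <- default_grid(config$grid_lo, config$grid_hi, config$grid_n)
  base <- lapply(unique(regions), function(r) .region_signature(config, r))
  names(base) <- unique(regions)
  signatures <- do.call(rbind, lapply(regions, function(r) base[[r]]))
  intens <- with_seed(config$seed, .render_spectra(config, signatures))
  spectrum_set(grid, intens,
               position_um = (seq_len(n) - 1L) * config$step_um,
               truth_region = regions)
}

#' Simulate a labeled 2D/3D culture-model pair
#'
#' Both sets share the library's common bands at whole-cell average weights;
#' each set additionally carries its model-specific bands scaled by
#' `model_amplitude`. With `model_amplitude = 0` the two classes are drawn
#' from one and the same distribution.
#'
#' @param config a [generator_config()]; layout/weights are ignored here,
#'   noise, hot-spot, baseline and seed are honoured.
#' @param n_2d,n_3d number of spectra per class (>= 1).
#' @param model_amplitude scale applied to the model-specific band lists.
#' @param mixture_weights named component-weight vector of the common
#'   (whole-cell) mixture; defaults to equal weights of 1.
#' @param attenuation_3d multiplicative factor on the 3D signal (default
#'   0.9): spheroids transmit less light than a monolayer, so 3D spectra
#'   are collected slightly dimmer. Applied to the clean signal before
#'   hot-spot scaling; baseline and noise are unattenuated.
#' @return list with elements `set_2d` and `set_3d` ([spectrum_set()]s with
#'   `model_label` filled in).
#' @export
simulate_model_pair <- function(config = generator_config(), n_2d, n_3d,
                                model_amplitude = 1,
                                mixture_weights = NULL,
                                attenuation_3d = 0.9) {
  stopifnot(attenuation_3d > 0, attenuation_3d <= 1)
  stopifnot(n_2d >= 1, n_3d >= 1)
  if (is.null(mixture_weights))
    mixture_weights <- stats::setNames(rep(1, length(.components)),
                                       .components)
  grid <- default_grid(config$grid_lo, config$grid_hi, config$grid_n)
  common <- numeric(length(grid))
  for (comp in names(mixture_weights)) {
    b <- config$library$shared[config$library$shared$component == comp, ,
                               drop = FALSE]
    common <- common + mixture_weights[[comp]] * component_signature(b, grid)
  }
  sig <- lapply(c("2D", "3D"), function(m) {
    extra <- config$library$model_specific[[m]]
    extra$amplitude <- extra$amplitude * model_amplitude
    common + component_signature(extra, grid)
  })
  names(sig) <- c("2D", "3D")
  sig[["3D"]] <- sig[["3D"]] * attenuation_3d
  intens <- with_seed(config$seed, {
    i2 <- .render_spectra(config, matrix(sig[["2D"]], n_2d,
                                         length(grid), byrow = TRUE))
    i3 <- .render_spectra(config, matrix(sig[["3D"]], n_3d,
                                         length(grid), byrow = TRUE))
    list(i2, i3)
  })
  list(
    set_2d = spectrum_set(grid, intens[[1L]],
                          position_um = seq_len(n_2d) - 1,
                          model_label = rep("2D", n_2d)),
    set_3d = spectrum_set(grid, intens[[2L]],
                          position_um = seq_len(n_3d) - 1,
                          model_label = rep("3D", n_3d))
  )
}
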