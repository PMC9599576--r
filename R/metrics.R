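#' Integrated band area
#'
#' Trapezoidal integral of a spectrum over the window
#' `[center - halfwidth, center + halfwidth]` (closed on both ends).
#' This is the quantity whose spread along a wire quantifies hot-spot
#' uniformity.
#'
#' @param spectrum numeric intensity vector.
#' @param grid [wavenumber_grid()] (or numeric vector) the spectrum lives on.
#' @param center band centre in cm^-1.
#' @param halfwidth window half width in cm^-1 (> 0).
#' @return integrated area in intensity * cm^-1.
#' @export
band_area <- function(spectrum, grid, center, halfwidth) {
  stopifnot(halfwidth > 0)
  nu <- as.numeric(grid)
  stopifnot(length(spectrum) == length(nu))
  keep <- nu >= center - halfwidth & nu <= center + halfwidth
  if (sum(keep) < 2L)
    stop("band window [", center - halfwidth, ", ", center + halfwidth,
         "] covers fewer than 2 grid points", call. = FALSE)
  x <- nu[keep]
  y <- spectrum[keep]
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

#' Band areas for every spectrum of a set
#' @param set a [spectrum_set()].
#' @param center,halfwidth window as in [band_area()].
#' @return numeric vector, one area per spectrum.
#' @export
band_areas <- function(set, center, halfwidth) {
  apply(set$intensities, 1L, band_area, grid = set$grid,
        center = center, halfwidth = halfwidth)
}

#' Relative standard deviation (percent)
#'
#' `100 * sd(values) / mean(values)` with the sample (n-1) standard
#' deviation; the uniformity statistic for band areas along a wire.
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return RSD in percent.
#' @export
rsd <- function(values) {
  stopifnot(length(values) >= 2L)
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero-mean values", call. = FALSE)
  100 * stats::sd(values) / m
}

#' SERS enhancement factor
#'
#' Concentration-normalised intensity ratio
#' `EF = (i_sers / c_sers) / (i_ref / c_ref)` comparing a SERS measurement
#' at analyte concentration `c_sers` with a normal-Raman reference at
#' `c_ref`.
#'
#' @param i_sers,i_ref band intensities (or areas), > 0.
#' @param c_sers,c_ref molar concentrations, > 0.
#' @return dimensionless enhancement factor.
#' @export
enhancement_factor <- function(i_sers, c_sers, i_ref, c_ref) {
  vals <- c(i_sers = i_sers, c_sers = c_sers, i_ref = i_ref, c_ref = c_ref)
  if (any(vals <= 0))
    stop("enhancement factor requires positive inputs; got ",
         paste(names(vals)[vals <= 0], collapse = ", "), " <= 0",
         call. = FALSE)
  (i_sers / c_sers) / (i_ref / c_ref)
}
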