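#' Construct a spectrum
#'
#' A spectrum is the basic container of the package: a strictly increasing
#' wavelength grid (nm) with one signal value per grid point and a kind tag
#' that fixes the unit convention (fluorescence in arbitrary units,
#' absorbance dimensionless, circular dichroism in millidegrees).
#'
#' @param wavelength numeric vector of wavelengths in nm, strictly
#'   increasing, length at least 2.
#' @param value numeric vector of signal values, same length as
#'   `wavelength`.
#' @param kind one of `"emission"`, `"absorbance"`, `"cd"`,
#'   `"synchronous"`.
#' @param meta named list of free-form annotations (e.g. excitation
#'   wavelength in nm, `delta_lambda` for synchronous scans, temperature
#'   in Celsius).
#'
#' @return An object of class `"spectrum"`.
#' @examples
#' s <- spectrum(300:380, exp(-((300:380) - 336)^2 / 800), "emission")
#' intensity_at(s, 336)
#' @export
spectrum <- function(wavelength, value,
                     kind = c("emission", "absorbance", "cd", "synchronous"),
                     meta = list()) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) < 2L)
    stop("a spectrum needs at least 2 grid points", call. = FALSE)
  if (length(wavelength) != length(value))
    stop(sprintf("wavelength (%d) and value (%d) lengths differ",
                 length(wavelength), length(value)), call. = FALSE)
  stop_if_not_finite(wavelength, "wavelength")
  check_strictly_increasing(wavelength, "wavelength")
  if (kind %in% c("emission", "absorbance") && any(value < 0, na.rm = TRUE))
    stop(sprintf("%s values must be non-negative", kind), call. = FALSE)
  structure(list(wavelength = wavelength, value = value, kind = kind,
                 meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %g-%g nm>\n",
              x$kind, length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  ylab <- switch(x$kind,
                 emission = "Fluorescence (a.u.)",
                 absorbance = "Absorbance",
                 cd = "Ellipticity (mdeg)",
                 synchronous = "Fluorescence (a.u.)")
  graphics::plot(x$wavelength, x$value, type = "l",
                 xlab = "Wavelength (nm)", ylab = ylab, ...)
  invisible(x)
}

#' Interpolated signal value at a wavelength
#'
#' Linear interpolation between the bracketing grid points; exact at grid
#' points. Querying outside the grid range is an error.
#'
#' @param spectrum a [spectrum()] object.
#' @param wavelength numeric vector of query wavelengths (nm).
#' @return Numeric vector of interpolated signal values.
#' @export
intensity_at <- function(spectrum, wavelength) {
  stopifnot(inherits(spectrum, "spectrum"))
  rng <- range(spectrum$wavelength)
  if (any(wavelength < rng[1L] | wavelength > rng[2L]))
    stop(sprintf("wavelength outside grid range [%g, %g] nm",
                 rng[1L], rng[2L]), call. = FALSE)
  stats::approx(spectrum$wavelength, spectrum$value, xout = wavelength,
                method = "linear", ties = "ordered")$y
}

#' Construct a titration series
#'
#' One quench titration at fixed protein concentration and temperature:
#' an ordered ligand-concentration grid with one spectrum per point, and
#' optionally the per-point absorbance increments at the excitation and
#' emission wavelengths used for inner-filter correction.
#'
#' @param protein_conc total protein concentration in mol/L (> 0).
#' @param ligand_conc numeric vector of total ligand concentrations in
#'   mol/L, non-negative, strictly increasing; the first entry is
#'   typically 0 (ligand-free reference).
#' @param temperature temperature in degrees Celsius.
#' @param spectra list of [spectrum()] objects, one per ligand
#'   concentration.
#' @param absorbance optional data frame with columns `A_ex` and `A_em`
#'   (dimensionless absorbance increments), one row per titration point.
#' @return An object of class `"titration_series"`.
#' @export
titration_series <- function(protein_conc, ligand_conc, temperature,
                             spectra, absorbance = NULL) {
  ligand_conc <- as.numeric(ligand_conc)
  if (length(protein_conc) != 1L || !is.finite(protein_conc) ||
      protein_conc <= 0)
    stop("protein_conc must be a single positive number (mol/L)",
         call. = FALSE)
  if (any(ligand_conc < 0))
    stop("ligand concentrations must be non-negative", call. = FALSE)
  check_strictly_increasing(ligand_conc, "ligand_conc")
  if (length(spectra) != length(ligand_conc))
    stop(sprintf("number of spectra (%d) must equal number of ligand concentrations (%d)",
                 length(spectra), length(ligand_conc)), call. = FALSE)
  if (!all(vapply(spectra, inherits, logical(1L), "spectrum")))
    stop("spectra must be a list of spectrum objects", call. = FALSE)
  if (!is.null(absorbance)) {
    absorbance <- as.data.frame(absorbance)
    if (!all(c("A_ex", "A_em") %in% names(absorbance)))
      stop("absorbance must have columns A_ex and A_em", call. = FALSE)
    if (nrow(absorbance) != length(ligand_conc))
      stop("absorbance must have one row per titration point", call. = FALSE)
    if (any(absorbance$A_ex < 0) || any(absorbance$A_em < 0))
      stop("absorbance increments must be non-negative", call. = FALSE)
  }
  structure(list(protein_conc = protein_conc, ligand_conc = ligand_conc,
                 temperature = temperature, spectra = spectra,
                 absorbance = absorbance),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series: [P] = %s M, %d points, [L] = %s-%s M, %g degC>\n",
    fmt_sci(x$protein_conc), length(x$ligand_conc),
    fmt_sci(min(x$ligand_conc)), fmt_sci(max(x$ligand_conc)),
    x$temperature))
  invisible(x)
}

#' @export
length.titration_series <- function(x) length(x$ligand_conc)

#' Construct an excitation-emission matrix surface
#'
#' @param excitation excitation wavelength grid (nm), strictly increasing.
#' @param emission emission wavelength grid (nm), strictly increasing.
#' @param intensity matrix of intensities, rows indexed by excitation and
#'   columns by emission.
#' @return An object of class `"eem_surface"`.
#' @export
eem_surface <- function(excitation, emission, intensity) {
  excitation <- as.numeric(excitation)
  emission <- as.numeric(emission)
  check_strictly_increasing(excitation, "excitation")
  check_strictly_increasing(emission, "emission")
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(excitation) ||
      ncol(intensity) != length(emission))
    stop(sprintf("intensity must be a %d x %d matrix (got %d x %d)",
                 length(excitation), length(emission),
                 nrow(intensity), ncol(intensity)), call. = FALSE)
  structure(list(excitation = excitation, emission = emission,
                 intensity = intensity),
            class = "eem_surface")
}

#' @export
print.eem_surface <- function(x, ...) {
  cat(sprintf("<eem_surface: %d x %d, ex %g-%g nm, em %g-%g nm>\n",
              length(x$excitation), length(x$emission),
              min(x$excitation), max(x$excitation),
              min(x$emission), max(x$emission)))
  invisible(x)
}

#' Construct a thermal melt curve
#'
#' Mean residue ellipticity at 222 nm versus temperature, for one scan
#' direction. Temperatures must be strictly monotone in the direction of
#' the scan (increasing for `"forward"`, decreasing or increasing for
#' `"reverse"`; reverse curves are stored sorted by temperature).
#'
#' @param temperature temperatures in degrees Celsius, strictly monotone.
#' @param mre mean residue ellipticity at 222 nm (deg cm^2 dmol^-1).
#' @param direction `"forward"` (heating) or `"reverse"` (cooling).
#' @return An object of class `"melt_curve"`.
#' @export
melt_curve <- function(temperature, mre,
                       direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  temperature <- as.numeric(temperature)
  mre <- as.numeric(mre)
  if (length(temperature) != length(mre))
    stop("temperature and mre must have equal length", call. = FALSE)
  d <- diff(temperature)
  if (!(all(d > 0) || all(d < 0)))
    stop("temperature must be strictly monotone", call. = FALSE)
  if (d[1L] < 0) {            # store sorted ascending
    temperature <- rev(temperature)
    mre <- rev(mre)
  }
  structure(list(temperature = temperature, mre = mre,
                 direction = direction),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve: %s, %d points, %g-%g degC>\n",
              x$direction, length(x$temperature),
              min(x$temperature), max(x$temperature)))
  invisible(x)
}
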