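#' Construct a spectrum
#'
#' A `spectrum` holds a single optical trace: a strictly increasing
#' wavelength grid (nm) and the measured values (absorbance in AU, or a
#' fluorescence ratio). All downstream analyses (unmixing, titration
#' fitting, whole-cell indices) consume this type.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param value Numeric vector of the same length; absorbance (AU) or
#'   fluorescence (arbitrary units). Must be finite.
#' @param kind One of `"absorbance"`, `"fluorescence_ratio"`,
#'   `"whole_cell"`.
#' @param meta Named list of free-form metadata (sample id, temperature in
#'   degrees C, pH, time in s, concentration in uM, ...).
#' @return An object of class `"spectrum"`.
#' @examples
#' s <- spectrum(620:720, dnorm(620:720, 630, 9))
#' @export
spectrum <- function(wavelength, value,
                     kind = c("absorbance", "fluorescence_ratio", "whole_cell"),
                     meta = list()) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) < 2L)
    stop("spectrum needs at least 2 points")
  if (length(wavelength) != length(value))
    stop("wavelength and value must have equal length")
  if (any(!is.finite(wavelength)) || any(!is.finite(value)))
    stop("non-finite values in spectrum")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(wavelength = wavelength, value = value,
                 kind = kind, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.4g-%.4g nm>\n",
              x$kind, length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Construct a titration series
#'
#' A set of absorbance spectra acquired at increasing apo-protein
#' concentration over a fixed pigment concentration; the input of the
#' dissociation-constant fit. Spectra are resampled onto the common
#' wavelength grid of the first spectrum on construction.
#'
#' @param spectra List of [spectrum] objects.
#' @param protein_conc Numeric vector, apo-protein concentration in uM,
#'   one per spectrum (NADPH assumed saturating, so protein + cofactor act
#'   as one binding partner).
#' @param pigment_conc Fixed pigment (protochlorophyllide) concentration
#'   in uM, > 0. Default 2 uM.
#' @param path_length Optical path in cm. Default 1.
#' @return An object of class `"titration_series"`.
#' @export
titration_series <- function(spectra, protein_conc, pigment_conc = 2,
                             path_length = 1) {
  if (!is.list(spectra) || !all(vapply(spectra, is_spectrum, logical(1))))
    stop("spectra must be a list of spectrum objects")
  protein_conc <- as.numeric(protein_conc)
  if (length(protein_conc) != length(spectra))
    stop("protein_conc must have one entry per spectrum")
  if (any(!is.finite(protein_conc)) || any(protein_conc < 0))
    stop("protein concentrations must be finite and >= 0")
  if (!is.finite(pigment_conc) || pigment_conc <= 0)
    stop("pigment_conc must be > 0")
  if (path_length <= 0) stop("path_length must be > 0")
  spectra <- resample_to_common_grid(spectra)
  structure(list(spectra = spectra, protein_conc = protein_conc,
                 pigment_conc = pigment_conc, path_length = path_length),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series: %d spectra, [protein] %.3g-%.3g uM, [pigment] %.3g uM>\n",
    length(x$spectra), min(x$protein_conc), max(x$protein_conc),
    x$pigment_conc))
  invisible(x)
}

#' Construct a pulsed-illumination time course
#'
#' Product-band absorbance (672 nm) recorded between light pulses during
#' an enzymatic photoconversion assay. `time_s` is elapsed assay time;
#' `light_s` the cumulative illumination time at each frame, which is the
#' natural abscissa for rate quantification since turnover only advances
#' under light.
#'
#' @param time_s Elapsed time in seconds, strictly increasing.
#' @param a672 Absorbance at 672 nm (AU), one value per frame.
#' @param illuminated Logical per frame: frame recorded during (or
#'   overlapping) a light pulse; such frames carry stray-light artifacts
#'   and are removed by [filter_illumination_events()].
#' @param light_s Cumulative illumination time (s) at each frame. If
#'   omitted, `time_s` is used (continuous illumination).
#' @param spectra Optional list of full [spectrum] objects, one per frame.
#' @return An object of class `"time_course"`.
#' @export
time_course <- function(time_s, a672, illuminated = NULL, light_s = NULL,
                        spectra = NULL) {
  time_s <- as.numeric(time_s)
  a672 <- as.numeric(a672)
  n <- length(time_s)
  if (n < 2L) stop("time course needs at least 2 frames")
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  if (length(a672) != n) stop("a672 must match time_s in length")
  if (is.null(illuminated)) illuminated <- rep(FALSE, n)
  if (length(illuminated) != n) stop("illuminated must match time_s in length")
  if (is.null(light_s)) light_s <- time_s
  if (length(light_s) != n) stop("light_s must match time_s in length")
  if (any(diff(light_s) < 0)) stop("light_s must be non-decreasing")
  if (!is.null(spectra) && length(spectra) != n)
    stop("spectra must match time_s in length")
  structure(list(time_s = time_s, a672 = a672,
                 illuminated = as.logical(illuminated),
                 light_s = as.numeric(light_s), spectra = spectra),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course: %d frames, %.4g-%.4g s, %d flagged>\n",
              length(x$time_s), min(x$time_s), max(x$time_s),
              sum(x$illuminated)))
  invisible(x)
}

#' Construct a differential scanning fluorimetry trace
#'
#' Intrinsic tryptophan fluorescence recorded at 350 and 330 nm along a
#' thermal ramp; the unfolding readout is the ratio F350/F330.
#'
#' @param temp_c Temperature in degrees C, strictly increasing.
#' @param f330,f350 Fluorescence intensities at 330 and 350 nm; `f330`
#'   must be positive everywhere.
#' @return An object of class `"dsf_trace"` with a derived `ratio` field.
#' @export
dsf_trace <- function(temp_c, f330, f350) {
  temp_c <- as.numeric(temp_c); f330 <- as.numeric(f330)
  f350 <- as.numeric(f350)
  n <- length(temp_c)
  if (n < 5L) stop("DSF trace needs at least 5 points")
  if (any(diff(temp_c) <= 0)) stop("temperatures must be strictly increasing")
  if (length(f330) != n || length(f350) != n)
    stop("channel lengths must match temperature grid")
  if (any(!is.finite(f330)) || any(!is.finite(f350)) || any(f330 <= 0))
    stop("fluorescence channels must be finite and f330 > 0")
  structure(list(temp_c = temp_c, f330 = f330, f350 = f350,
                 ratio = f350 / f330),
            class = "dsf_trace")
}

#' @export
print.dsf_trace <- function(x, ...) {
  cat(sprintf("<dsf_trace: %d points, %.4g-%.4g degC>\n",
              length(x$temp_c), min(x$temp_c), max(x$temp_c)))
  invisible(x)
}
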