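#' @include AllClasses.R
NULL

#' Accessors for Spectrum and related classes
#'
#' `wavelengths()` and `intensities()` return the grid and the signal of a
#' [Spectrum-class]; `spectrumKind()` its kind; `isCorrected()` the
#' inner-filter provenance flag. `ligandConc()` and `proteinConc()` return
#' concentrations (mol/L) from objects that carry them.
#'
#' @param x the object.
#' @return numeric vectors (or a character scalar for `spectrumKind`).
#' @name spectrum-accessors
#' @aliases wavelengths intensities spectrumKind isCorrected ligandConc
#'   proteinConc
NULL

#' @rdname spectrum-accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname spectrum-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname spectrum-accessors
#' @export
setGeneric("spectrumKind", function(x) standardGeneric("spectrumKind"))

#' @rdname spectrum-accessors
#' @export
setGeneric("isCorrected", function(x) standardGeneric("isCorrected"))

#' @rdname spectrum-accessors
#' @export
setGeneric("ligandConc", function(x) standardGeneric("ligandConc"))

#' @rdname spectrum-accessors
#' @export
setGeneric("proteinConc", function(x) standardGeneric("proteinConc"))

#' Wavelength of maximum signal
#'
#' Grid argmax of a spectrum. Ties are broken toward the shortest
#' wavelength; resolution equals the grid spacing (no sub-grid refinement).
#' An all-constant (e.g. all-zero) spectrum triggers a warning and returns
#' the shortest wavelength.
#'
#' @param x a [Spectrum-class] object.
#' @return the wavelength (nm) of the maximum value.
#' @examples
#' s <- Spectrum("emission", 300:400, dnorm(300:400, 340, 20),
#'               excitationNm = 295)
#' peakWavelength(s)  # 340
#' @export
setGeneric("peakWavelength", function(x) standardGeneric("peakWavelength"))

#' Trapezoidal band area of a spectrum
#'
#' Integrates the recorded curve between `loNm` and `hiNm` by the
#' trapezoidal rule on the recorded grid; window endpoints falling between
#' grid points are included by linear interpolation. The area is additive
#' over adjacent windows and linear in the spectrum values.
#'
#' @param x a [Spectrum-class] object.
#' @param loNm,hiNm window bounds, nm, `loNm < hiNm`, both inside the grid
#'   range.
#' @return the band area in signal units times nm.
#' @examples
#' s <- Spectrum("emission", 305:400, rep(1, 96), excitationNm = 295)
#' integrateBand(s, 305, 400)  # 95
#' @export
setGeneric("integrateBand",
           function(x, loNm, hiNm) standardGeneric("integrateBand"))

#' Intensity-weighted average fluorescence lifetime
#'
#' For a multiexponential decay with amplitudes `alpha` and lifetimes `tau`,
#' the average lifetime is \eqn{\sum \alpha_i \tau_i^2 / \sum \alpha_i
#' \tau_i}; for a single component it is that component's lifetime. The
#' value is invariant to rescaling all amplitudes by a common factor.
#'
#' @param fit a [DecayFit-class] object.
#' @return average lifetime, ns.
#' @export
setGeneric("averageLifetime", function(fit) standardGeneric("averageLifetime"))
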