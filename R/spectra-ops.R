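#' @include spectrum-methods.R
NULL

# Linear interpolation of an absorbance spectrum at arbitrary wavelengths.
# No extrapolation: a wavelength outside the recorded grid is an error.
.absorbanceAt <- function(absorbance, atNm) {
  stopifnot(is(absorbance, "Spectrum"))
  if (absorbance@kind != "absorbance")
    stop("expected a spectrum of kind 'absorbance'")
  if (any(absorbance@values < 0))
    stop("absorbance values must be non-negative")
  w <- absorbance@wavelength
  if (any(atNm < w[1L] - 1e-9) || any(atNm > w[length(w)] + 1e-9))
    stop(sprintf(
      "absorbance grid (%.1f-%.1f nm) does not cover required wavelengths (%.1f-%.1f nm)",
      w[1L], w[length(w)], min(atNm), max(atNm)))
  stats::approx(w, absorbance@values, xout = pmin(pmax(atNm, w[1L]),
                                                 w[length(w)]))$y
}

#' Subtract a buffer baseline from a sample spectrum
#'
#' Pointwise subtraction of the buffer (scatter) signal on an identical
#' wavelength grid; negative differences are clamped to zero, since a
#' fluorescence signal cannot be negative. The number of clamped points is
#' reported via a message when nonzero. No implicit resampling: a grid
#' mismatch is an error.
#'
#' @param sample,buffer [Spectrum-class] objects on identical grids.
#' @return a [Spectrum-class] with `sample - buffer` values (clamped at 0)
#'   and the sample's metadata.
#' @export
subtractBaseline <- function(sample, buffer) {
  stopifnot(is(sample, "Spectrum"), is(buffer, "Spectrum"))
  if (length(sample@wavelength) != length(buffer@wavelength) ||
      any(sample@wavelength != buffer@wavelength))
    stop("sample and buffer must share an identical wavelength grid")
  v <- sample@values - buffer@values
  nClamped <- sum(v < 0)
  if (nClamped > 0)
    message(sprintf("subtractBaseline: clamped %d negative point(s) to 0",
                    nClamped))
  out <- sample
  out@values <- pmax(v, 0)
  validObject(out)
  out
}

#' Whole-spectrum inner-filter correction of an emission spectrum
#'
#' Applies the multiplicative correction
#' \deqn{F_{corr}(\lambda) = F_{obs}(\lambda) \cdot
#'   10^{(A_{ex} + A(\lambda))/2}}
#' at every emission wavelength, where \eqn{A_{ex}} is the absorbance at the
#' excitation wavelength and \eqn{A(\lambda)} at the emission wavelength.
#' Absorbance is linearly interpolated onto the required wavelengths; the
#' absorbance grid must cover both the excitation wavelength and the full
#' emission grid (no extrapolation). With non-negative absorbances the
#' correction factor is >= 1 everywhere, so an absorbing ligand can only
#' have attenuated the observed signal.
#'
#' When the ligand absorbs asymmetrically across the emission band, the
#' uncorrected spectrum shows an apparent shift of the intensity maximum;
#' the correction removes it. Apply after [subtractBaseline()] so that
#' buffer scatter is not amplified.
#'
#' @param emission observed emission [Spectrum-class].
#' @param absorbance total-sample absorbance [Spectrum-class] (measured, or
#'   computed from the ligand concentration with
#'   [ligandAbsorbanceSpectrum()]).
#' @param excNm excitation wavelength, nm; defaults to the emission
#'   spectrum's `excitationNm` metadata.
#' @return the corrected [Spectrum-class], flagged `ifeCorrected = TRUE`.
#' @examples
#' grid <- 305:500
#' em <- Spectrum("emission", grid, dnorm(grid, 340, 25), excitationNm = 295)
#' ab <- Spectrum("absorbance", 240:520, rep(0, 281))
#' identical(intensities(innerFilterCorrect(em, ab)), intensities(em))
#' @export
innerFilterCorrect <- function(emission, absorbance,
                               excNm = emission@excitationNm) {
  stopifnot(is(emission, "Spectrum"))
  if (!emission@kind %in% c("emission", "synchronous"))
    stop("innerFilterCorrect expects an emission spectrum; use ",
         "innerFilterCorrectSynchronous for synchronous spectra")
  if (!is.finite(excNm)) stop("excitation wavelength is required")
  aEx <- .absorbanceAt(absorbance, excNm)
  aEm <- .absorbanceAt(absorbance, emission@wavelength)
  out <- emission
  out@values <- emission@values * 10^((aEx + aEm) / 2)
  out@ifeCorrected <- TRUE
  validObject(out)
  out
}

#' Inner-filter correction of a synchronous fluorescence spectrum
#'
#' Synchronous spectra are indexed by excitation wavelength with the
#' emission wavelength trailing at a fixed offset, so each point at
#' \eqn{\lambda_{exc}} is corrected with \eqn{A(\lambda_{exc})} and
#' \eqn{A(\lambda_{exc} + \Delta\lambda)}:
#' \deqn{F_{corr} = F_{obs} \cdot
#'   10^{(A(\lambda_{exc}) + A(\lambda_{exc}+\Delta\lambda))/2}}
#'
#' @param sync synchronous [Spectrum-class] (indexed by excitation
#'   wavelength).
#' @param absorbance absorbance [Spectrum-class] covering both the
#'   excitation range and the offset emission range.
#' @param deltaNm excitation-emission offset, nm; defaults to the spectrum's
#'   `deltaNm` metadata (60 nm is the usual tryptophan-selective choice).
#' @return the corrected [Spectrum-class], flagged `ifeCorrected = TRUE`.
#' @export
innerFilterCorrectSynchronous <- function(sync, absorbance,
                                          deltaNm = sync@deltaNm) {
  stopifnot(is(sync, "Spectrum"))
  if (sync@kind != "synchronous")
    stop("expected a spectrum of kind 'synchronous'")
  if (!is.finite(deltaNm)) stop("synchronous offset deltaNm is required")
  aExc <- .absorbanceAt(absorbance, sync@wavelength)
  aEm <- .absorbanceAt(absorbance, sync@wavelength + deltaNm)
  out <- sync
  out@values <- sync@values * 10^((aExc + aEm) / 2)
  out@ifeCorrected <- TRUE
  validObject(out)
  out
}

#' @rdname integrateBand
setMethod("integrateBand", "Spectrum", function(x, loNm, hiNm) {
  w <- x@wavelength; v <- x@values
  if (!(loNm < hiNm)) stop("integration window requires loNm < hiNm")
  if (loNm < w[1L] || hiNm > w[length(w)])
    stop(sprintf("window [%g, %g] outside the recorded grid [%g, %g]",
                 loNm, hiNm, w[1L], w[length(w)]))
  inside <- w > loNm & w < hiNm
  xs <- c(loNm, w[inside], hiNm)
  ys <- c(stats::approx(w, v, xout = loNm)$y, v[inside],
          stats::approx(w, v, xout = hiNm)$y)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
})

#' @rdname peakWavelength
setMethod("peakWavelength", "Spectrum", function(x) {
  v <- x@values
  if (all(v == v[1L])) {
    warning("spectrum is constant; returning the shortest wavelength")
    return(x@wavelength[1L])
  }
  # which.max returns the first maximum: ties break to shortest wavelength
  x@wavelength[which.max(v)]
})

#' Ligand absorbance spectrum by Beer-Lambert
#'
#' Builds a total-ligand absorbance [Spectrum-class] from the ligand
#' concentration and a unit-peak band shape: a split Gaussian centred at
#' `peakNm` with blue-side width `sigmaBlueNm` and a broader red-side width
#' `sigmaRedNm` (the red tail that overlaps a tryptophan emission band
#' asymmetrically), scaled by \eqn{\varepsilon \cdot c \cdot l}. Defaults
#' describe a piperlongumine-like absorber
#' (\eqn{\varepsilon = 18700\,M^{-1}cm^{-1}} at 326 nm, 1 cm path).
#'
#' @param ligandM ligand concentration, mol/L.
#' @param gridNm wavelength grid, nm.
#' @param peakNm band maximum, nm.
#' @param epsilon molar extinction coefficient at the peak, 1/(M cm).
#' @param sigmaBlueNm,sigmaRedNm Gaussian widths below/above the peak, nm.
#' @param pathCm optical path length, cm.
#' @return an absorbance [Spectrum-class] on `gridNm`.
#' @export
ligandAbsorbanceSpectrum <- function(ligandM, gridNm = 240:520,
                                     peakNm = 326, epsilon = 18700,
                                     sigmaBlueNm = 22, sigmaRedNm = 34,
                                     pathCm = 1) {
  stopifnot(ligandM >= 0, epsilon > 0, pathCm > 0)
  shape <- ifelse(gridNm <= peakNm,
                  exp(-(gridNm - peakNm)^2 / (2 * sigmaBlueNm^2)),
                  exp(-(gridNm - peakNm)^2 / (2 * sigmaRedNm^2)))
  Spectrum("absorbance", gridNm, epsilon * ligandM * pathCm * shape,
           ligandM = ligandM)
}
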