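#' @import methods
NULL

.SPECTRUM_KINDS <- c("emission", "synchronous", "absorbance", "cd")

#' Spectrum: a sampled optical curve
#'
#' Container for one optical spectrum on a strictly increasing wavelength
#' grid: fluorescence emission (a.u.), synchronous fluorescence (indexed by
#' excitation wavelength, a.u.), absorbance (AU) or circular dichroism
#' ellipticity (mdeg), together with the acquisition metadata needed
#' downstream (excitation wavelength, synchronous offset, temperature,
#' protein and ligand concentrations).
#'
#' The `ifeCorrected` flag records provenance: `TRUE` means the values are
#' free of inner-filter distortion (either measured without it, corrected
#' with [innerFilterCorrect()], or simulated as the hidden true band).
#' Quenching-curve construction refuses uncorrected fluorescence spectra.
#'
#' @slot kind one of `"emission"`, `"synchronous"`, `"absorbance"`, `"cd"`.
#' @slot wavelength numeric, nm, strictly increasing, length >= 2. For
#'   synchronous spectra this is the excitation wavelength; the emission
#'   wavelength of each point is `wavelength + deltaNm`.
#' @slot values numeric, same length as `wavelength`. Intensities (a.u.) for
#'   emission/synchronous, absorbance (AU, >= 0) or ellipticity (mdeg).
#' @slot excitationNm excitation wavelength, nm (required for emission).
#' @slot deltaNm synchronous excitation-emission offset, nm (required for
#'   synchronous spectra).
#' @slot temperatureK sample temperature, K.
#' @slot proteinM protein concentration, mol/L.
#' @slot ligandM ligand concentration, mol/L.
#' @slot ifeCorrected logical; `TRUE` if free of inner-filter distortion.
#' @seealso [Spectrum()] for the user constructor.
#' @export
setClass("Spectrum",
  representation(
    kind = "character",
    wavelength = "numeric",
    values = "numeric",
    excitationNm = "numeric",
    deltaNm = "numeric",
    temperatureK = "numeric",
    proteinM = "numeric",
    ligandM = "numeric",
    ifeCorrected = "logical"
  ),
  prototype(
    kind = "emission",
    excitationNm = NA_real_, deltaNm = NA_real_, temperatureK = NA_real_,
    proteinM = NA_real_, ligandM = NA_real_, ifeCorrected = FALSE
  )
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% .SPECTRUM_KINDS)
    msg <- c(msg, sprintf("kind must be one of: %s",
                          paste(.SPECTRUM_KINDS, collapse = ", ")))
  w <- object@wavelength
  v <- object@values
  if (length(w) < 2L)
    msg <- c(msg, "wavelength grid must have length >= 2")
  if (length(w) != length(v))
    msg <- c(msg, "wavelength and values must have equal length")
  if (anyNA(w) || any(!is.finite(w)))
    msg <- c(msg, "wavelengths must be finite")
  else if (length(w) >= 2L && any(diff(w) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "values must be finite")
  if (length(object@kind) == 1L && !anyNA(v)) {
    if (object@kind == "absorbance" && any(v < 0))
      msg <- c(msg, "absorbance values must be >= 0")
    if (object@kind %in% c("emission", "synchronous") && any(v < 0))
      msg <- c(msg, "fluorescence values must be >= 0")
    if (object@kind == "emission" && !is.finite(object@excitationNm))
      msg <- c(msg, "emission spectra require excitationNm")
    if (object@kind == "synchronous" && !is.finite(object@deltaNm))
      msg <- c(msg, "synchronous spectra require deltaNm")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param kind spectrum kind: `"emission"`, `"synchronous"`, `"absorbance"`
#'   or `"cd"`.
#' @param wavelength strictly increasing wavelength grid, nm.
#' @param values signal values, same length as `wavelength`.
#' @param excitationNm excitation wavelength (nm); required for emission.
#' @param deltaNm synchronous offset (nm); required for synchronous spectra.
#' @param temperatureK,proteinM,ligandM optional acquisition metadata
#'   (Kelvin, mol/L).
#' @param ifeCorrected logical provenance flag: is the spectrum free of
#'   inner-filter distortion?
#' @return a [Spectrum-class] object.
#' @examples
#' s <- Spectrum("emission", 305:500, dnorm(305:500, 340, 25),
#'               excitationNm = 295)
#' peakWavelength(s)
#' @export
Spectrum <- function(kind, wavelength, values,
                     excitationNm = NA_real_, deltaNm = NA_real_,
                     temperatureK = NA_real_, proteinM = NA_real_,
                     ligandM = NA_real_, ifeCorrected = FALSE) {
  new("Spectrum", kind = kind,
      wavelength = as.numeric(wavelength), values = as.numeric(values),
      excitationNm = as.numeric(excitationNm), deltaNm = as.numeric(deltaNm),
      temperatureK = as.numeric(temperatureK),
      proteinM = as.numeric(proteinM), ligandM = as.numeric(ligandM),
      ifeCorrected = ifeCorrected)
}

#' TitrationSeries: an ordered ligand ladder of spectra
#'
#' One spectrum per titration step at fixed protein concentration and
#' temperature, ordered by strictly increasing total ligand concentration.
#'
#' @slot spectra list of [Spectrum-class] objects sharing kind and grid.
#' @slot ligandM total ligand concentration per step, mol/L, strictly
#'   increasing (typically starting at 0 for the reference point).
#' @slot proteinM protein concentration, mol/L.
#' @slot temperatureK temperature, K.
#' @export
setClass("TitrationSeries",
  representation(
    spectra = "list",
    ligandM = "numeric",
    proteinM = "numeric",
    temperatureK = "numeric"
  )
)

setValidity("TitrationSeries", function(object) {
  msg <- character()
  n <- length(object@spectra)
  if (n < 1L) msg <- c(msg, "series must contain at least one spectrum")
  if (length(object@ligandM) != n)
    msg <- c(msg, "ligandM must have one entry per spectrum")
  if (n >= 2L && any(diff(object@ligandM) <= 0))
    msg <- c(msg, "ligandM must be strictly increasing")
  if (!all(vapply(object@spectra, is, logical(1), "Spectrum")))
    msg <- c(msg, "spectra must all be Spectrum objects")
  else if (n >= 2L) {
    k <- vapply(object@spectra, function(s) s@kind, character(1))
    if (length(unique(k)) != 1L)
      msg <- c(msg, "all spectra in a series must share the same kind")
    g1 <- object@spectra[[1L]]@wavelength
    same <- vapply(object@spectra, function(s)
      length(s@wavelength) == length(g1) && all(s@wavelength == g1),
      logical(1))
    if (!all(same))
      msg <- c(msg, "all spectra in a series must share the wavelength grid")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TitrationSeries
#'
#' @param spectra list of [Spectrum-class] objects (same kind and grid).
#' @param ligandM strictly increasing total ligand concentrations, mol/L.
#' @param proteinM protein concentration, mol/L.
#' @param temperatureK temperature, K.
#' @return a [TitrationSeries-class] object.
#' @export
TitrationSeries <- function(spectra, ligandM, proteinM = NA_real_,
                            temperatureK = NA_real_) {
  new("TitrationSeries", spectra = spectra, ligandM = as.numeric(ligandM),
      proteinM = as.numeric(proteinM), temperatureK = as.numeric(temperatureK))
}

#' QuenchingCurve: F0/F (or A0/A) ratios along a ligand ladder
#'
#' @slot ligandM total ligand concentrations, mol/L, strictly increasing,
#'   first entry 0 (the unquenched reference).
#' @slot ratio dimensionless F0/F (intensity mode) or A0/A (area mode);
#'   first entry 1 by construction.
#' @slot mode `"intensity"` or `"area"`.
#' @slot read read wavelength (nm, intensity mode) or integration window
#'   `c(lo, hi)` (nm, area mode).
#' @slot temperatureK temperature, K.
#' @slot proteinM protein concentration, mol/L.
#' @export
setClass("QuenchingCurve",
  representation(
    ligandM = "numeric",
    ratio = "numeric",
    mode = "character",
    read = "numeric",
    temperatureK = "numeric",
    proteinM = "numeric"
  )
)

setValidity("QuenchingCurve", function(object) {
  msg <- character()
  if (!object@mode %in% c("intensity", "area"))
    msg <- c(msg, "mode must be 'intensity' or 'area'")
  if (length(object@ligandM) != length(object@ratio))
    msg <- c(msg, "ligandM and ratio must have equal length")
  if (length(object@ligandM)) {
    if (object@ligandM[1L] != 0)
      msg <- c(msg, "first ligand concentration must be 0 (reference)")
    if (any(diff(object@ligandM) <= 0))
      msg <- c(msg, "ligandM must be strictly increasing")
    if (abs(object@ratio[1L] - 1) > 1e-12)
      msg <- c(msg, "reference ratio must equal 1")
    if (any(object@ratio <= 0))
      msg <- c(msg, "all ratios must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Stern-Volmer fit result
#'
#' @slot Ksv Stern-Volmer constant, 1/M.
#' @slot KsvSE standard error of `Ksv`.
#' @slot r2 coefficient of determination of the fit.
#' @slot kq bimolecular quenching rate constant `Ksv / tau0`, 1/(M s);
#'   `NA` when no lifetime was supplied.
#' @slot tau0 unquenched fluorophore lifetime, s (`NA` if not supplied).
#' @slot intercept fitted intercept (exactly 1 when fixed).
#' @slot interceptFixed logical: was the intercept fixed at 1?
#' @slot mode,temperatureK provenance from the quenching curve.
#' @export
setClass("SternVolmerResult",
  representation(
    Ksv = "numeric", KsvSE = "numeric", r2 = "numeric",
    kq = "numeric", tau0 = "numeric",
    intercept = "numeric", interceptFixed = "logical",
    mode = "character", temperatureK = "numeric"
  )
)

#' Double-log binding fit result
#'
#' @slot Ka association (binding) constant, 1/M.
#' @slot KaSE standard error of `Ka` (delta-method from the regression).
#' @slot nSites number of binding sites (regression slope), dimensionless.
#' @slot nSitesSE standard error of `nSites`.
#' @slot r2 coefficient of determination.
#' @slot nUsed number of titration points entering the regression.
#' @slot mode,temperatureK provenance from the quenching curve.
#' @export
setClass("BindingFit",
  representation(
    Ka = "numeric", KaSE = "numeric",
    nSites = "numeric", nSitesSE = "numeric",
    r2 = "numeric", nUsed = "integer",
    mode = "character", temperatureK = "numeric"
  )
)

#' Quenching-mechanism classification
#'
#' @slot verdict `"static"`, `"dynamic"` or `"mixed"`.
#' @slot evidence named list: `kq`, `kqThreshold`, `maxTauDeviation`
#'   (max tau0/tau - 1), `maxIntensityDeviation` (max F0/F - 1),
#'   `maxRelDifference` (max |tau0/tau - F0/F| / (F0/F)) and the tolerances
#'   used.
#' @export
setClass("MechanismCall",
  representation(verdict = "character", evidence = "list"))

#' Van't Hoff thermodynamic decomposition
#'
#' @slot temperatures input temperatures, K.
#' @slot deltaH binding enthalpy, kJ/mol, with `deltaHSE`.
#' @slot deltaS binding entropy, J/(mol K), with `deltaSSE`.
#' @slot deltaG Gibbs free energy `deltaH - T deltaS` at each input
#'   temperature, kJ/mol (regression form).
#' @slot deltaGdirect Gibbs free energy `-R T ln Ka` at each input
#'   temperature, kJ/mol, with `deltaGdirectSE` propagated from Ka errors
#'   when supplied (NA otherwise).
#' @slot TdeltaS entropic term `T deltaS` at each temperature, kJ/mol.
#' @slot r2 coefficient of determination of the Van't Hoff regression.
#' @slot gasConstant 8.314 J/(mol K), fixed.
#' @export
setClass("ThermoResult",
  representation(
    temperatures = "numeric",
    deltaH = "numeric", deltaHSE = "numeric",
    deltaS = "numeric", deltaSSE = "numeric",
    deltaG = "numeric", deltaGdirect = "numeric", deltaGdirectSE = "numeric",
    TdeltaS = "numeric", r2 = "numeric", gasConstant = "numeric"
  ),
  prototype(gasConstant = 8.314)
)

#' IDF constant-quench levels
#'
#' Result of [matchLevels()]: one row per quench level `deltaF` (%), with the
#' mass-conservation regression of total ligand on protein concentration —
#' slope `sumNu` (binding density, dimensionless) and intercept
#' `freeLigandM` (mol/L) — plus acceptance status.
#'
#' @slot levels data.frame with columns `deltaF`, `sumNu`, `sumNuSE`,
#'   `freeLigandM`, `freeLigandSE`, `r2`, `accepted` (logical), `reason`.
#' @slot totals matrix of interpolated total ligand concentrations (mol/L),
#'   levels x protein concentrations.
#' @slot proteinM protein concentrations of the input series, mol/L.
#' @slot mode signal mode used for the quench percentages.
#' @slot temperatureK temperature, K.
#' @export
setClass("IDFLevels",
  representation(
    levels = "data.frame",
    totals = "matrix",
    proteinM = "numeric",
    mode = "character",
    temperatureK = "numeric"
  )
)

#' Binding density curve
#'
#' Paired (free ligand, binding density) points from accepted IDF levels,
#' ascending in free ligand, consumed by [scatchard()] and [hillFit()].
#'
#' @slot freeLigandM free ligand concentration, mol/L, strictly increasing.
#' @slot sumNu binding density (average ligands bound per protein).
#' @export
setClass("BindingDensityCurve",
  representation(freeLigandM = "numeric", sumNu = "numeric"))

setValidity("BindingDensityCurve", function(object) {
  msg <- character()
  if (length(object@freeLigandM) != length(object@sumNu))
    msg <- c(msg, "freeLigandM and sumNu must have equal length")
  if (length(object@freeLigandM) >= 2L && any(diff(object@freeLigandM) <= 0))
    msg <- c(msg, "freeLigandM must be strictly increasing")
  if (any(object@freeLigandM < 0))
    msg <- c(msg, "freeLigandM must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a BindingDensityCurve
#'
#' @param freeLigandM free ligand concentrations, mol/L.
#' @param sumNu binding densities at those concentrations.
#' @return a [BindingDensityCurve-class]; points are sorted by ascending
#'   free ligand.
#' @export
BindingDensityCurve <- function(freeLigandM, sumNu) {
  o <- order(freeLigandM)
  new("BindingDensityCurve", freeLigandM = as.numeric(freeLigandM)[o],
      sumNu = as.numeric(sumNu)[o])
}

#' Multi-class cooperative Hill model
#'
#' Fitted occupancy model
#' \deqn{\sum\nu = \sum_j n_j (k_j L)^{w_j} / (1 + (k_j L)^{w_j})}
#' with classes ordered by descending binding constant.
#'
#' @slot classes data.frame with columns `n` (sites per class), `k` (1/M),
#'   `kSE`, `w` (affinity index), `wSE`.
#' @slot nClasses number of site classes selected.
#' @slot rss residual sum of squares of the selected model.
#' @slot aicc corrected Akaike information criterion of the selected model.
#' @slot scan data.frame of the model-selection scan: `nClasses`, `rss`,
#'   `aicc`, `converged`.
#' @slot nPoints number of (free ligand, sumNu) points fitted.
#' @export
setClass("HillModel",
  representation(
    classes = "data.frame",
    nClasses = "integer",
    rss = "numeric",
    aicc = "numeric",
    scan = "data.frame",
    nPoints = "integer"
  )
)

#' Scatchard transform and cooperativity verdict
#'
#' @slot sumNu binding densities (x axis of the Scatchard plot).
#' @slot ratio `sumNu / freeLigandM`, 1/M (y axis).
#' @slot verdict `"positive-cooperative"` (rises to an interior maximum then
#'   falls), `"non-cooperative"` (monotone decreasing) or `"indeterminate"`.
#' @export
setClass("ScatchardResult",
  representation(sumNu = "numeric", ratio = "numeric", verdict = "character"))

#' TCSPC decay trace
#'
#' @slot timeNs time grid from 0, ns, strictly increasing.
#' @slot counts photon counts, non-negative.
#' @slot excitationNm,emissionNm acquisition wavelengths, nm.
#' @slot ligandM ligand concentration, mol/L.
#' @export
setClass("DecayTrace",
  representation(
    timeNs = "numeric", counts = "numeric",
    excitationNm = "numeric", emissionNm = "numeric", ligandM = "numeric"
  ),
  prototype(excitationNm = NA_real_, emissionNm = NA_real_,
            ligandM = NA_real_)
)

setValidity("DecayTrace", function(object) {
  msg <- character()
  if (length(object@timeNs) != length(object@counts))
    msg <- c(msg, "timeNs and counts must have equal length")
  if (length(object@timeNs) >= 2L && any(diff(object@timeNs) <= 0))
    msg <- c(msg, "timeNs must be strictly increasing")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a DecayTrace
#'
#' @param timeNs strictly increasing time grid, ns.
#' @param counts non-negative photon counts.
#' @param excitationNm,emissionNm acquisition wavelengths, nm.
#' @param ligandM ligand concentration, mol/L.
#' @return a [DecayTrace-class] object.
#' @export
DecayTrace <- function(timeNs, counts, excitationNm = NA_real_,
                       emissionNm = NA_real_, ligandM = NA_real_) {
  new("DecayTrace", timeNs = as.numeric(timeNs), counts = as.numeric(counts),
      excitationNm = as.numeric(excitationNm),
      emissionNm = as.numeric(emissionNm), ligandM = as.numeric(ligandM))
}

#' Multiexponential decay fit
#'
#' @slot alpha fractional amplitudes, normalised to sum 1, ordered with
#'   their lifetimes by descending lifetime.
#' @slot tau lifetimes, ns, descending.
#' @slot tauSE standard errors of the lifetimes, ns.
#' @slot chisqRed reduced chi-square of the weighted fit.
#' @slot nPoints number of fitted points.
#' @export
setClass("DecayFit",
  representation(
    alpha = "numeric", tau = "numeric", tauSE = "numeric",
    chisqRed = "numeric", nPoints = "integer"
  )
)

setValidity("DecayFit", function(object) {
  msg <- character()
  if (length(object@alpha) != length(object@tau))
    msg <- c(msg, "alpha and tau must have equal length")
  if (any(object@tau <= 0)) msg <- c(msg, "lifetimes must be positive")
  if (length(object@tau) >= 2L && any(diff(object@tau) > 0))
    msg <- c(msg, "components must be ordered by descending lifetime")
  if (length(msg)) msg else TRUE
})

#' Ground truth for the synthetic titration generator
#'
#' Hidden parameters of the simulator: the cooperative two-class occupancy
#' model, the static quench efficiency, the emission and ligand-absorbance
#' band shapes, the unquenched lifetime, the titration design and the noise
#' model. See [groundTruth()] for defaults and units.
#'
#' @slot siteN sites per class (fixed at 1 each by default).
#' @slot siteK class binding constants, 1/M.
#' @slot siteW class affinity (Hill) indices.
#' @slot quenchEfficiency fraction of fluorescence lost at full average
#'   occupancy (scales with `sumNu / sum(siteN)`).
#' @slot emissionPeakNm,emissionFwhmNm,emissionAsym log-normal emission band:
#'   peak (nm), full width at half maximum (nm), asymmetry (dimensionless).
#' @slot absPeakNm,absEpsilon,absSigmaBlueNm,absSigmaRedNm ligand absorbance
#'   band: peak (nm), molar extinction coefficient at the peak (1/(M cm)),
#'   blue- and red-side Gaussian widths (nm).
#' @slot pathCm optical path length, cm.
#' @slot tau0Ns unquenched fluorophore lifetime, ns.
#' @slot proteinM protein concentrations of the design, mol/L.
#' @slot ligandM total ligand ladder, mol/L.
#' @slot temperatureK design temperature, K.
#' @slot excitationNm excitation wavelength, nm.
#' @slot gridNm emission wavelength grid, nm.
#' @slot noiseSd additive Gaussian noise, relative to the zero-ligand peak.
#' @slot peakCounts Poisson peak counts for simulated decays.
#' @slot seed integer RNG seed.
#' @export
setClass("GroundTruth",
  representation(
    siteN = "numeric", siteK = "numeric", siteW = "numeric",
    quenchEfficiency = "numeric",
    emissionPeakNm = "numeric", emissionFwhmNm = "numeric",
    emissionAsym = "numeric",
    absPeakNm = "numeric", absEpsilon = "numeric",
    absSigmaBlueNm = "numeric", absSigmaRedNm = "numeric",
    pathCm = "numeric",
    tau0Ns = "numeric",
    proteinM = "numeric", ligandM = "numeric", temperatureK = "numeric",
    excitationNm = "numeric", gridNm = "numeric",
    noiseSd = "numeric", peakCounts = "numeric", seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  nc <- length(object@siteK)
  if (length(object@siteN) != nc || length(object@siteW) != nc)
    msg <- c(msg, "siteN, siteK and siteW must have equal length")
  if (any(object@siteK <= 0) || any(object@siteW <= 0) ||
      any(object@siteN <= 0))
    msg <- c(msg, "site parameters must be positive")
  if (object@quenchEfficiency < 0 || object@quenchEfficiency > 1)
    msg <- c(msg, "quenchEfficiency must lie in [0, 1]")
  if (any(object@ligandM < 0) || any(object@proteinM < 0))
    msg <- c(msg, "concentrations must be non-negative")
  if (length(msg)) msg else TRUE
})
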