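#' @include AllGenerics.R
NULL

#' @rdname spectrum-accessors
setMethod("wavelengths", "Spectrum", function(x) x@wavelength)

#' @rdname spectrum-accessors
setMethod("intensities", "Spectrum", function(x) x@values)

#' @rdname spectrum-accessors
setMethod("spectrumKind", "Spectrum", function(x) x@kind)

#' @rdname spectrum-accessors
setMethod("isCorrected", "Spectrum", function(x) x@ifeCorrected)

#' @rdname spectrum-accessors
setMethod("ligandConc", "Spectrum", function(x) x@ligandM)

#' @rdname spectrum-accessors
setMethod("proteinConc", "Spectrum", function(x) x@proteinM)

#' @rdname spectrum-accessors
setMethod("ligandConc", "TitrationSeries", function(x) x@ligandM)

#' @rdname spectrum-accessors
setMethod("proteinConc", "TitrationSeries", function(x) x@proteinM)

#' @rdname spectrum-accessors
setMethod("ligandConc", "QuenchingCurve", function(x) x@ligandM)

setMethod("show", "Spectrum", function(object) {
  rng <- range(object@wavelength)
  cat(sprintf("Spectrum (%s): %d points, %.1f-%.1f nm\n",
              object@kind, length(object@wavelength), rng[1], rng[2]))
  meta <- c(
    if (is.finite(object@excitationNm))
      sprintf("exc %g nm", object@excitationNm),
    if (is.finite(object@deltaNm)) sprintf("delta %g nm", object@deltaNm),
    if (is.finite(object@temperatureK)) sprintf("%g K", object@temperatureK),
    if (is.finite(object@proteinM))
      sprintf("[P] %.3g M", object@proteinM),
    if (is.finite(object@ligandM)) sprintf("[L] %.3g M", object@ligandM),
    if (object@ifeCorrected) "inner-filter free")
  if (length(meta)) cat(" ", paste(meta, collapse = ", "), "\n")
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf(
    "TitrationSeries: %d steps, ligand %.3g-%.3g M, [P] = %.3g M, T = %g K\n",
    length(object@spectra), min(object@ligandM), max(object@ligandM),
    object@proteinM, object@temperatureK))
})

setMethod("show", "QuenchingCurve", function(object) {
  cat(sprintf(
    "QuenchingCurve (%s mode): %d points, max ratio %.3f, T = %g K\n",
    object@mode, length(object@ratio), max(object@ratio),
    object@temperatureK))
})

setMethod("show", "SternVolmerResult", function(object) {
  cat(sprintf("Stern-Volmer fit (%s mode, T = %g K)\n",
              object@mode, object@temperatureK))
  cat(sprintf("  Ksv = %.4g +/- %.2g 1/M (r2 = %.4f)\n",
              object@Ksv, object@KsvSE, object@r2))
  if (is.finite(object@kq))
    cat(sprintf("  kq  = %.4g 1/(M s) with tau0 = %.3g s\n",
                object@kq, object@tau0))
})

setMethod("show", "BindingFit", function(object) {
  cat(sprintf("Double-log binding fit (%s mode, T = %g K, %d points)\n",
              object@mode, object@temperatureK, object@nUsed))
  cat(sprintf("  Ka = %.4g +/- %.2g 1/M,  n = %.3f +/- %.3f (r2 = %.4f)\n",
              object@Ka, object@KaSE, object@nSites, object@nSitesSE,
              object@r2))
})

setMethod("show", "MechanismCall", function(object) {
  cat(sprintf("Quenching mechanism: %s\n", object@verdict))
  ev <- object@evidence
  cat(sprintf(
    "  kq = %.3g 1/(M s) (threshold %.1g); max(tau0/tau - 1) = %.3g; max(F0/F - 1) = %.3g\n",
    ev$kq, ev$kqThreshold, ev$maxTauDeviation, ev$maxIntensityDeviation))
})

setMethod("show", "ThermoResult", function(object) {
  cat("Van't Hoff decomposition\n")
  cat(sprintf("  deltaH = %.2f +/- %.2f kJ/mol\n",
              object@deltaH, object@deltaHSE))
  cat(sprintf("  deltaS = %.2f +/- %.2f J/(mol K)   (r2 = %.4f)\n",
              object@deltaS, object@deltaSSE, object@r2))
  df <- data.frame(
    T_K = object@temperatures,
    deltaG_kJmol = round(object@deltaG, 2),
    deltaG_direct_kJmol = round(object@deltaGdirect, 2),
    TdeltaS_kJmol = round(object@TdeltaS, 2))
  print(df, row.names = FALSE)
})

setMethod("show", "IDFLevels", function(object) {
  acc <- sum(object@levels$accepted)
  cat(sprintf(
    "IDF levels: %d quench levels (%d accepted) over %d protein concentrations\n",
    nrow(object@levels), acc, length(object@proteinM)))
})

setMethod("show", "BindingDensityCurve", function(object) {
  cat(sprintf(
    "BindingDensityCurve: %d points, free ligand %.3g-%.3g M, sumNu %.3f-%.3f\n",
    length(object@sumNu), min(object@freeLigandM), max(object@freeLigandM),
    min(object@sumNu), max(object@sumNu)))
})

setMethod("show", "HillModel", function(object) {
  cat(sprintf("Hill model: %d site class(es), RSS = %.3g, AICc = %.2f\n",
              object@nClasses, object@rss, object@aicc))
  cl <- object@classes
  for (j in seq_len(nrow(cl)))
    cat(sprintf("  class %d: n = %g, k = %.3g +/- %.2g 1/M, w = %.3f +/- %.3f\n",
                j, cl$n[j], cl$k[j], cl$kSE[j], cl$w[j], cl$wSE[j]))
})

setMethod("show", "ScatchardResult", function(object) {
  cat(sprintf("Scatchard transform: %d points, verdict: %s\n",
              length(object@sumNu), object@verdict))
})

setMethod("show", "DecayTrace", function(object) {
  cat(sprintf("DecayTrace: %d channels, 0-%.1f ns, peak %d counts\n",
              length(object@timeNs), max(object@timeNs),
              round(max(object@counts))))
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("Decay fit: %d component(s), reduced chi-square %.3f\n",
              length(object@tau), object@chisqRed))
  for (i in seq_along(object@tau))
    cat(sprintf("  tau = %.3f ns (alpha = %.3f)\n",
                object@tau[i], object@alpha[i]))
  cat(sprintf("  tau_avg = %.3f ns\n", averageLifetime(object)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d site class(es), k = %s 1/M, w = %s; quench efficiency %.2f\n",
    length(object@siteK),
    paste(signif(object@siteK, 3), collapse = "/"),
    paste(signif(object@siteW, 3), collapse = "/"),
    object@quenchEfficiency))
  cat(sprintf("  design: [P] = %s M, ligand 0-%.3g M (%d steps), T = %g K\n",
              paste(signif(object@proteinM, 3), collapse = "/"),
              max(object@ligandM), length(object@ligandM),
              object@temperatureK))
})
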