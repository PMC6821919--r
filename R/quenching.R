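#' @include spectra-ops.R
NULL

#' Build a quenching curve from a titration series
#'
#' Reduces each spectrum of a titration to one scalar signal — the
#' intensity at a read wavelength (intensity mode) or the trapezoidal band
#' area over a window (area mode) — and forms the ratios
#' \eqn{F_0/F} (or \eqn{A_0/A}) against the zero-ligand reference.
#'
#' All spectra must be inner-filter corrected (or otherwise free of
#' inner-filter distortion); whole-spectrum correction is a prerequisite of
#' any ratio-based quenching analysis, so uncorrected input is an error,
#' not a warning.
#'
#' @param series a [TitrationSeries-class] whose ladder includes a
#'   zero-ligand reference.
#' @param mode `"intensity"` or `"area"`.
#' @param read read wavelength in nm (intensity mode; default 340) or
#'   window `c(lo, hi)` in nm (area mode; default `c(305, 400)`).
#' @return a [QuenchingCurve-class].
#' @examples
#' tr <- simulateTitration(groundTruth(proteinM = 4e-6, noiseSd = 0))
#' crv <- buildCurve(tr$trueSeries[[1]], mode = "area")
#' sternVolmerFit(crv, tau0 = 6.71e-9)
#' @export
buildCurve <- function(series, mode = c("intensity", "area"), read = NULL) {
  stopifnot(is(series, "TitrationSeries"))
  mode <- match.arg(mode)
  if (is.null(read)) read <- if (mode == "intensity") 340 else c(305, 400)
  if (mode == "intensity" && length(read) != 1L)
    stop("intensity mode takes a single read wavelength")
  if (mode == "area" && length(read) != 2L)
    stop("area mode takes a window c(lo, hi)")
  if (series@ligandM[1L] != 0)
    stop("titration series lacks a zero-ligand reference point")
  bad <- !vapply(series@spectra, isCorrected, logical(1))
  if (any(bad))
    stop(sprintf(
      "%d spectrum/spectra are not inner-filter corrected; correct the whole spectrum before building quenching ratios",
      sum(bad)))
  signal <- vapply(series@spectra, function(s) {
    if (mode == "intensity")
      stats::approx(s@wavelength, s@values, xout = read)$y
    else integrateBand(s, read[1L], read[2L])
  }, numeric(1))
  if (any(signal <= 0)) stop("non-positive signal in the titration series")
  new("QuenchingCurve", ligandM = series@ligandM,
      ratio = signal[1L] / signal, mode = mode, read = as.numeric(read),
      temperatureK = series@temperatureK, proteinM = series@proteinM)
}

#' Stern-Volmer fit
#'
#' Fits \eqn{F_0/F = 1 + K_{SV} [L]}. By default the intercept is fixed at
#' its theoretical value of 1 (the model has no free intercept), i.e. the
#' least-squares slope of `ratio - 1` on `[L]` through the origin; set
#' `fixIntercept = FALSE` for an ordinary regression of `ratio` on `[L]` as
#' a diagnostic. When the unquenched lifetime `tau0` is supplied, the
#' bimolecular quenching rate constant \eqn{k_q = K_{SV}/\tau_0} is
#' reported; \eqn{k_q} above \eqn{10^{10}\,M^{-1}s^{-1}} exceeds the
#' diffusion limit and argues against purely collisional quenching.
#'
#' @param curve a [QuenchingCurve-class] with at least 3 points.
#' @param tau0 unquenched lifetime in seconds (optional; enables `kq`).
#' @param fixIntercept fix the intercept at 1 (default `TRUE`).
#' @return a [SternVolmerResult-class].
#' @export
sternVolmerFit <- function(curve, tau0 = NA_real_, fixIntercept = TRUE) {
  stopifnot(is(curve, "QuenchingCurve"))
  if (length(curve@ligandM) < 3L)
    stop("Stern-Volmer fit requires at least 3 points")
  if (is.finite(tau0) && tau0 <= 0) stop("tau0 must be positive")
  L <- curve@ligandM
  r <- curve@ratio
  if (fixIntercept) {
    fit <- stats::lm(I(r - 1) ~ 0 + L)
    Ksv <- unname(stats::coef(fit)[1L])
    KsvSE <- unname(sqrt(diag(suppressWarnings(stats::vcov(fit))))[1L])
    intercept <- 1
  } else {
    fit <- stats::lm(r ~ L)
    Ksv <- unname(stats::coef(fit)[2L])
    KsvSE <- unname(sqrt(diag(suppressWarnings(stats::vcov(fit))))[2L])
    intercept <- unname(stats::coef(fit)[1L])
  }
  if (is.na(Ksv)) Ksv <- 0
  if (Ksv < 0)
    warning("negative Stern-Volmer slope: fluorescence enhancement, not quenching")
  r2 <- suppressWarnings(summary(fit))$r.squared
  new("SternVolmerResult", Ksv = Ksv, KsvSE = KsvSE, r2 = r2,
      kq = if (is.finite(tau0)) Ksv / tau0 else NA_real_,
      tau0 = tau0, intercept = intercept, interceptFixed = fixIntercept,
      mode = curve@mode, temperatureK = curve@temperatureK)
}

#' Classify the quenching mechanism
#'
#' Applies the standard diagnostics: purely collisional (dynamic) quenching
#' makes lifetime and intensity fall together (\eqn{\tau_0/\tau = F_0/F}),
#' while static ground-state complexation leaves the lifetime nearly
#' untouched and is betrayed by an apparent \eqn{k_q} far above the
#' diffusion-limited \eqn{10^{10}\,M^{-1}s^{-1}}.
#'
#' Rules, in order: *dynamic* if
#' \eqn{\max |\tau_0/\tau - F_0/F| / (F_0/F) <} `equivTol`;
#' *static* if \eqn{k_q >} `kqThreshold` and the lifetime stays close to
#' unity — \eqn{\max(\tau_0/\tau - 1) <} `unityTol` \eqn{\times \max(F_0/F
#' - 1)} — while the intensity ratio grows; *mixed* otherwise.
#'
#' @param sv a [SternVolmerResult-class] carrying `kq` (fit with `tau0`).
#' @param lifetimeRatios \eqn{\tau_0/\tau} per ligand concentration.
#' @param intensityRatios \eqn{F_0/F} on the same ligand ladder.
#' @param kqThreshold diffusion limit for `kq`, 1/(M s).
#' @param equivTol relative tolerance declaring lifetime/intensity
#'   equivalence (default 5%).
#' @param unityTol fraction of the intensity response below which the
#'   lifetime response counts as "close to unity" (default 25%).
#' @return a [MechanismCall-class].
#' @export
classifyMechanism <- function(sv, lifetimeRatios, intensityRatios,
                              kqThreshold = 1e10, equivTol = 0.05,
                              unityTol = 0.25) {
  stopifnot(is(sv, "SternVolmerResult"))
  if (length(lifetimeRatios) != length(intensityRatios))
    stop("lifetime and intensity ratios must be aligned on the same ligand ladder")
  if (!is.finite(sv@kq))
    stop("mechanism classification needs kq: fit Stern-Volmer with tau0")
  relDiff <- max(abs(lifetimeRatios - intensityRatios) / intensityRatios)
  maxTau <- max(lifetimeRatios - 1)
  maxInt <- max(intensityRatios - 1)
  verdict <- if (relDiff < equivTol) "dynamic"
  else if (sv@kq > kqThreshold && maxInt > 0 && maxTau < unityTol * maxInt)
    "static"
  else "mixed"
  new("MechanismCall", verdict = verdict,
      evidence = list(kq = sv@kq, kqThreshold = kqThreshold,
                      maxTauDeviation = maxTau,
                      maxIntensityDeviation = maxInt,
                      maxRelDifference = relDiff,
                      equivTol = equivTol, unityTol = unityTol))
}

#' Double-log binding fit
#'
#' One-pass regression of the double-log binding-equilibrium model
#' \deqn{\log\frac{F_0 - F}{F} = n \log K_a -
#'   n \log\frac{1}{[L] - \frac{F_0-F}{F_0}[P]}}
#' (base-10 logs). The bound-ligand correction subtracts
#' \eqn{(F_0-F)/F_0 \cdot [P]} from the total ligand concentration with no
#' iteration. The slope is the number of sites `n`; the binding constant is
#' \eqn{K_a = 10^{intercept/n}}. Points with no quenching (ratio <= 1) or a
#' non-positive corrected ligand concentration are dropped with a warning;
#' at least 4 usable points are required. The fit is invariant to rescaling
#' all fluorescence values by a common positive factor (only ratios enter).
#'
#' @param curve a [QuenchingCurve-class].
#' @param proteinM protein concentration, mol/L (defaults to the curve's).
#' @return a [BindingFit-class].
#' @export
doubleLogFit <- function(curve, proteinM = curve@proteinM) {
  stopifnot(is(curve, "QuenchingCurve"))
  if (!is.finite(proteinM) || proteinM < 0)
    stop("a protein concentration is required")
  L <- curve@ligandM[-1L]
  r <- curve@ratio[-1L]
  # (F0 - F)/F = r - 1;  (F0 - F)/F0 = 1 - 1/r
  y <- r - 1
  Lcorr <- L - (1 - 1 / r) * proteinM
  usable <- y > 0 & Lcorr > 0
  if (any(!usable))
    warning(sprintf(
      "doubleLogFit: dropped %d point(s) with non-positive log argument",
      sum(!usable)))
  if (sum(usable) < 4L)
    stop("double-log fit requires at least 4 usable points with ratio > 1")
  ly <- log10(y[usable])
  lx <- log10(Lcorr[usable])
  fit <- stats::lm(ly ~ lx)
  cf <- stats::coef(fit)
  n <- unname(cf[2L])
  b <- unname(cf[1L])
  if (n <= 0) stop("non-positive fitted slope: no binding isotherm")
  V <- suppressWarnings(stats::vcov(fit))
  Ka <- 10^(b / n)
  # delta method on Ka = 10^(b/n): d/db = Ka ln10 / n, d/dn = -Ka ln10 b/n^2
  g <- c(Ka * log(10) / n, -Ka * log(10) * b / n^2)
  KaSE <- sqrt(drop(t(g) %*% V %*% g))
  new("BindingFit", Ka = Ka, KaSE = KaSE,
      nSites = n, nSitesSE = sqrt(V[2L, 2L]),
      r2 = suppressWarnings(summary(fit))$r.squared, nUsed = sum(usable),
      mode = curve@mode, temperatureK = curve@temperatureK)
}
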