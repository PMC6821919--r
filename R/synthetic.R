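#' @include cd.R
NULL

#' Ground truth for the synthetic titration generator
#'
#' Builds the [GroundTruth-class] record that drives the simulator. The
#' defaults emulate a tryptophan-quenching titration of a serum albumin by
#' an absorbing ligand: a log-normal emission band peaking at 340 nm under
#' 295 nm excitation; cooperative static quenching by two single-site
#' classes with \eqn{k = 2.3\times10^5, 1.3\times10^5\,M^{-1}} and affinity
#' indices \eqn{w = 2.93, 8.15}; a ligand absorbance band at 326 nm
#' (\eqn{\varepsilon = 18700\,M^{-1}cm^{-1}}) whose asymmetric overlap with
#' the emission band produces inner-filter attenuation and an apparent red
#' shift of the observed maximum; a titration ladder 0-32 uM in 2 uM steps
#' at protein concentrations 2/4/8 uM and 288 K; and an unquenched lifetime
#' of 6.71 ns.
#'
#' @param siteN sites per class.
#' @param siteK class binding constants, 1/M.
#' @param siteW class affinity (Hill) indices.
#' @param quenchEfficiency fraction of fluorescence lost at full average
#'   occupancy.
#' @param emissionPeakNm,emissionFwhmNm,emissionAsym emission band peak
#'   (nm), width (FWHM, nm) and log-normal asymmetry.
#' @param absPeakNm,absEpsilon,absSigmaBlueNm,absSigmaRedNm ligand
#'   absorbance band parameters (see [ligandAbsorbanceSpectrum()]).
#' @param pathCm optical path, cm.
#' @param tau0Ns unquenched lifetime, ns.
#' @param proteinM protein concentrations of the design, mol/L.
#' @param ligandM total-ligand ladder, mol/L.
#' @param temperatureK design temperature, K.
#' @param excitationNm excitation wavelength, nm.
#' @param gridNm emission wavelength grid, nm.
#' @param noiseSd additive Gaussian noise, relative to the zero-ligand peak
#'   intensity (0 = noiseless).
#' @param peakCounts Poisson peak counts for simulated decays.
#' @param seed integer RNG seed.
#' @return a [GroundTruth-class] object.
#' @export
groundTruth <- function(siteN = c(1, 1), siteK = c(2.3e5, 1.3e5),
                        siteW = c(2.93, 8.15), quenchEfficiency = 0.4,
                        emissionPeakNm = 340, emissionFwhmNm = 60,
                        emissionAsym = 0.1,
                        absPeakNm = 326, absEpsilon = 18700,
                        absSigmaBlueNm = 22, absSigmaRedNm = 34,
                        pathCm = 1, tau0Ns = 6.71,
                        proteinM = c(2e-6, 4e-6, 8e-6),
                        ligandM = seq(0, 32e-6, by = 2e-6),
                        temperatureK = 288, excitationNm = 295,
                        gridNm = 305:500, noiseSd = 0,
                        peakCounts = 1e4, seed = 1L) {
  new("GroundTruth", siteN = siteN, siteK = siteK, siteW = siteW,
      quenchEfficiency = quenchEfficiency,
      emissionPeakNm = emissionPeakNm, emissionFwhmNm = emissionFwhmNm,
      emissionAsym = emissionAsym,
      absPeakNm = absPeakNm, absEpsilon = absEpsilon,
      absSigmaBlueNm = absSigmaBlueNm, absSigmaRedNm = absSigmaRedNm,
      pathCm = pathCm, tau0Ns = tau0Ns,
      proteinM = proteinM, ligandM = ligandM, temperatureK = temperatureK,
      excitationNm = excitationNm, gridNm = as.numeric(gridNm),
      noiseSd = noiseSd, peakCounts = peakCounts, seed = as.integer(seed))
}

# Unit-peak log-normal emission band (Siano-Metzler form): maximum exactly
# at peakNm, mild red tail for asym > 0; zero outside the support.
.emissionBand <- function(gridNm, peakNm, fwhmNm, asym) {
  if (abs(asym) < 1e-8)
    return(exp(-4 * log(2) * ((gridNm - peakNm) / fwhmNm)^2))
  arg <- 1 + 2 * asym * (gridNm - peakNm) / fwhmNm
  out <- numeric(length(gridNm))
  ok <- arg > 0
  out[ok] <- exp(-log(2) * (log(arg[ok]) / asym)^2)
  out
}

# Ligand absorbance evaluated analytically at arbitrary wavelengths.
.absAt <- function(truth, ligandM, atNm) {
  shape <- ifelse(atNm <= truth@absPeakNm,
                  exp(-(atNm - truth@absPeakNm)^2 /
                        (2 * truth@absSigmaBlueNm^2)),
                  exp(-(atNm - truth@absPeakNm)^2 /
                        (2 * truth@absSigmaRedNm^2)))
  truth@absEpsilon * ligandM * truth@pathCm * shape
}

# Occupancy sum_j n_j (k_j L)^w_j / (1 + (k_j L)^w_j) and its dL derivative.
.truthNu <- function(truth, L) .hillNu(L, truth@siteN, truth@siteK,
                                       truth@siteW)

.truthNuPrime <- function(truth, L) {
  if (L <= 0) return(0)
  out <- 0
  for (j in seq_along(truth@siteK)) {
    x <- (truth@siteK[j] * L)^truth@siteW[j]
    out <- out + truth@siteN[j] * truth@siteW[j] * x / (L * (1 + x)^2)
  }
  out
}

#' Solve the free-ligand concentration under mass conservation
#'
#' Finds the unique root of
#' \deqn{[L]_{total} - [L]_{free} - \sum\nu([L]_{free]) \cdot [P] = 0}
#' on \eqn{[0, [L]_{total}]}, where \eqn{\sum\nu} is the ground-truth
#' cooperative occupancy. Bracketed root finding polished by Newton steps;
#' the conservation residual is driven below \eqn{10^{-12} [L]_{total}}.
#'
#' @param totalLigandM total ligand concentration(s), mol/L.
#' @param proteinM protein concentration, mol/L.
#' @param truth a [GroundTruth-class].
#' @return data.frame with columns `totalLigandM`, `freeLigandM`, `sumNu`.
#' @export
solveFreeLigand <- function(totalLigandM, proteinM, truth) {
  stopifnot(is(truth, "GroundTruth"), proteinM >= 0,
            all(totalLigandM >= 0))
  one <- function(Ltot) {
    if (Ltot == 0) return(c(0, 0))
    if (proteinM == 0) return(c(Ltot, .truthNu(truth, Ltot)))
    g <- function(Lf) Ltot - Lf - .truthNu(truth, Lf) * proteinM
    Lf <- stats::uniroot(g, c(0, Ltot), tol = 1e-15 * Ltot)$root
    for (i in 1:4) {
      gp <- -1 - .truthNuPrime(truth, Lf) * proteinM
      step <- g(Lf) / gp
      LfNew <- min(max(Lf - step, 0), Ltot)
      if (!is.finite(LfNew)) break
      Lf <- LfNew
      if (abs(g(Lf)) < 1e-15 * Ltot) break
    }
    c(Lf, .truthNu(truth, Lf))
  }
  res <- vapply(totalLigandM, one, numeric(2))
  data.frame(totalLigandM = totalLigandM, freeLigandM = res[1L, ],
             sumNu = res[2L, ])
}

#' Simulate a cooperative static-quenching titration
#'
#' Forward model of the study design, one titration per protein
#' concentration in the ground truth:
#' \enumerate{
#'   \item free ligand and binding density from exact mass conservation
#'     ([solveFreeLigand()]);
#'   \item the hidden *true* emission band scaled by the static-quenching
#'     factor \eqn{1 - q_e \sum\nu / \sum n_j} (wavelength-independent,
#'     as for a single fluorophore class equally accessible to the
#'     quencher);
#'   \item the *observed* spectrum attenuated by the inner-filter factor
#'     \eqn{10^{-(A_{ex} + A(\lambda))/2}} with the ligand absorbance at
#'     the total ligand concentration, plus additive Gaussian noise
#'     (relative to the zero-ligand peak, clamped at zero).
#' }
#' Because the observation model is exactly the inverse of the
#' whole-spectrum inner-filter correction, correcting the noiseless
#' observed spectra with the generator's own absorbances recovers the
#' hidden true spectra to round-off.
#'
#' The occupancy-to-quench mapping (step 2) is a simulator convention — a
#' simple single-channel static model — not a measured property of any
#' particular system.
#'
#' @param truth a [GroundTruth-class]. The RNG seed in `truth@seed` is set
#'   at entry, so outputs are reproducible.
#' @return a list with elements
#'   \describe{
#'     \item{observed}{list of [TitrationSeries-class] (one per protein
#'       concentration) of observed, inner-filter-distorted spectra
#'       (`ifeCorrected = FALSE`);}
#'     \item{trueSeries}{matching list of hidden true spectra
#'       (`ifeCorrected = TRUE`);}
#'     \item{absorbance}{list of absorbance [Spectrum-class], one per
#'       ladder step (ligand absorbance at the total concentration);}
#'     \item{occupancy}{data.frame of `proteinM`, `totalLigandM`,
#'       `freeLigandM`, `sumNu` for every design point;}
#'     \item{truth}{the input [GroundTruth-class].}
#'   }
#' @export
simulateTitration <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  set.seed(truth@seed)
  grid <- truth@gridNm
  base <- .emissionBand(grid, truth@emissionPeakNm, truth@emissionFwhmNm,
                        truth@emissionAsym) * 1000
  peak0 <- max(base)
  absGrid <- seq(min(240, floor(min(grid, truth@excitationNm))),
                 max(520, ceiling(max(grid))), by = 1)
  aEx <- .absAt(truth, 1, truth@excitationNm)   # per mol/L
  aEm <- .absAt(truth, 1, grid)                 # per mol/L
  absorbance <- lapply(truth@ligandM, function(L)
    Spectrum("absorbance", absGrid, .absAt(truth, L, absGrid), ligandM = L))
  names(absorbance) <- sprintf("L_%g", truth@ligandM)

  observed <- list(); trueSeries <- list(); occ <- list()
  for (p in truth@proteinM) {
    sol <- solveFreeLigand(truth@ligandM, p, truth)
    occ[[length(occ) + 1L]] <- cbind(proteinM = p, sol)
    obs <- list(); tru <- list()
    for (i in seq_along(truth@ligandM)) {
      L <- truth@ligandM[i]
      qf <- 1 - truth@quenchEfficiency * sol$sumNu[i] / sum(truth@siteN)
      if (qf <= 0)
        stop("design produces non-positive intensities; reduce quenchEfficiency")
      vTrue <- base * qf
      vObs <- vTrue * 10^(-(aEx * L + aEm * L) / 2)
      if (truth@noiseSd > 0)
        vObs <- pmax(vObs + stats::rnorm(length(vObs),
                                         sd = truth@noiseSd * peak0), 0)
      mk <- function(v, corrected) Spectrum(
        "emission", grid, v, excitationNm = truth@excitationNm,
        temperatureK = truth@temperatureK, proteinM = p, ligandM = L,
        ifeCorrected = corrected)
      obs[[i]] <- mk(vObs, FALSE)
      tru[[i]] <- mk(vTrue, TRUE)
    }
    observed[[length(observed) + 1L]] <-
      TitrationSeries(obs, truth@ligandM, proteinM = p,
                      temperatureK = truth@temperatureK)
    trueSeries[[length(trueSeries) + 1L]] <-
      TitrationSeries(tru, truth@ligandM, proteinM = p,
                      temperatureK = truth@temperatureK)
  }
  names(observed) <- names(trueSeries) <- sprintf("P_%g", truth@proteinM)
  list(observed = observed, trueSeries = trueSeries,
       absorbance = absorbance, occupancy = do.call(rbind, occ),
       truth = truth)
}

#' Simulate a TCSPC decay trace
#'
#' Forward model of a (mono)exponential tryptophan decay on a 0-50 ns grid
#' with Poisson counting noise. Under the default purely static quenching
#' convention the lifetime is unchanged by ligand; `lifetimeMode = "mixed"`
#' adds a mild collisional contribution that shortens the lifetime linearly
#' with ligand, reaching `tauTopNs` at the top of the ladder.
#'
#' @param truth a [GroundTruth-class] (uses `tau0Ns`, `peakCounts`, `seed`,
#'   the ladder maximum and the acquisition wavelengths).
#' @param ligandM ligand concentration of this trace, mol/L.
#' @param lifetimeMode `"static"` (default) or `"mixed"`.
#' @param tauTopNs lifetime at the top of the ladder in mixed mode, ns.
#' @param noise Poisson noise on (default); `FALSE` returns expected counts.
#' @param dtNs channel width, ns.
#' @return a [DecayTrace-class].
#' @export
simulateDecay <- function(truth, ligandM = 0,
                          lifetimeMode = c("static", "mixed"),
                          tauTopNs = 6.28, noise = TRUE, dtNs = 0.05) {
  stopifnot(is(truth, "GroundTruth"), truth@peakCounts >= 100)
  lifetimeMode <- match.arg(lifetimeMode)
  tau <- if (lifetimeMode == "static") truth@tau0Ns
  else truth@tau0Ns - (truth@tau0Ns - tauTopNs) *
    ligandM / max(truth@ligandM)
  t <- seq(0, 50, by = dtNs)
  expected <- truth@peakCounts * exp(-t / tau)
  counts <- if (noise) {
    set.seed(truth@seed + as.integer(round(ligandM * 1e7)))
    stats::rpois(length(t), expected)
  } else expected
  DecayTrace(t, counts, excitationNm = truth@excitationNm,
             emissionNm = truth@emissionPeakNm, ligandM = ligandM)
}

#' Simulate a circular dichroism spectrum
#'
#' Deterministic double-Gaussian band model with negative minima at the
#' alpha-helix diagnostic wavelengths (208 and 222 nm by default; the band
#' widths are narrow enough that band overlap moves each minimum by less
#' than the grid spacing), plus optional Gaussian noise.
#'
#' @param centersNm band centres, nm.
#' @param amplitudesMdeg band amplitudes, mdeg (negative for helix bands).
#' @param sigmaNm Gaussian band widths, nm.
#' @param gridNm wavelength grid, nm.
#' @param noiseSd additive Gaussian noise, mdeg.
#' @param seed RNG seed used when `noiseSd > 0`.
#' @return a [Spectrum-class] of kind `"cd"`.
#' @export
simulateCD <- function(centersNm = c(208, 222),
                       amplitudesMdeg = c(-20, -19),
                       sigmaNm = c(4, 4),
                       gridNm = seq(200, 260, by = 0.5),
                       noiseSd = 0, seed = 1L) {
  stopifnot(length(centersNm) == length(amplitudesMdeg),
            length(sigmaNm) %in% c(1L, length(centersNm)))
  sigmaNm <- rep_len(sigmaNm, length(centersNm))
  v <- numeric(length(gridNm))
  for (j in seq_along(centersNm))
    v <- v + amplitudesMdeg[j] *
      exp(-(gridNm - centersNm[j])^2 / (2 * sigmaNm[j]^2))
  if (noiseSd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noiseSd)
  }
  Spectrum("cd", gridNm, v)
}
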