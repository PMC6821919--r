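# Shared fixtures, built in code.

# Flat emission spectrum of a given value on a small grid.
flatEmission <- function(value, grid = 300:420, corrected = TRUE) {
  Spectrum("emission", grid, rep(value, length(grid)), excitationNm = 295,
           ifeCorrected = corrected)
}

# Titration series with prescribed scalar signals (flat spectra).
signalSeries <- function(signals, ligandM, proteinM = 4e-6,
                         temperatureK = 298, corrected = TRUE) {
  TitrationSeries(lapply(signals, flatEmission, corrected = corrected),
                  ligandM, proteinM = proteinM, temperatureK = temperatureK)
}

# Quenching curve straight from ratios (bypassing spectra).
ratioCurve <- function(ligandM, ratio, mode = "intensity",
                       proteinM = 4e-6, temperatureK = 298) {
  new("QuenchingCurve", ligandM = ligandM, ratio = ratio, mode = mode,
      read = if (mode == "intensity") 340 else c(305, 400),
      temperatureK = temperatureK, proteinM = proteinM)
}

# Two-class cooperative occupancy used as the recovery ground truth.
eq8SumNu <- function(L, k = c(2.3e5, 1.3e5), w = c(2.93, 8.15)) {
  (k[1] * L)^w[1] / (1 + (k[1] * L)^w[1]) +
    (k[2] * L)^w[2] / (1 + (k[2] * L)^w[2])
}

# Exact bound fraction for a 1:1 binding equilibrium.
boundConc <- function(Ka, P, L) {
  b <- -(Ka * P + Ka * L + 1)
  (-b - sqrt(b^2 - 4 * Ka * Ka * P * L)) / (2 * Ka)
}

# Noiseless simulated study design, corrected observed series per protein.
simulatedCorrected <- function(noiseSd = 0, seed = 1L) {
  sim <- simulateTitration(groundTruth(noiseSd = noiseSd, seed = seed))
  list(sim = sim, corrected = lapply(sim$observed, correctTitration))
}
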