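test_that("free-ligand solver honours mass conservation to high precision", {
  gt <- groundTruth()
  expect_equal(solveFreeLigand(5e-6, 0, gt)$freeLigandM, 5e-6)
  expect_equal(unlist(solveFreeLigand(0, 4e-6, gt)[, 2:3]),
               c(freeLigandM = 0, sumNu = 0))
  for (p in gt@proteinM) {
    sol <- solveFreeLigand(gt@ligandM, p, gt)
    resid <- abs(gt@ligandM - sol$freeLigandM - sol$sumNu * p)
    nz <- gt@ligandM > 0
    expect_lt(max(resid[nz] / gt@ligandM[nz]), 1e-12)
    # occupancy is the ground-truth model evaluated at the solved root
    expect_equal(sol$sumNu, eq8SumNu(sol$freeLigandM), tolerance = 1e-12)
  }
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulateTitration(groundTruth(noiseSd = 0.01, seed = 5L))
  b <- simulateTitration(groundTruth(noiseSd = 0.01, seed = 5L))
  for (p in names(a$observed))
    for (i in seq_along(a$observed[[p]]@spectra))
      expect_identical(intensities(a$observed[[p]]@spectra[[i]]),
                       intensities(b$observed[[p]]@spectra[[i]]))
  c <- simulateTitration(groundTruth(noiseSd = 0.01, seed = 6L))
  expect_false(identical(intensities(a$observed[[1]]@spectra[[2]]),
                         intensities(c$observed[[1]]@spectra[[2]])))
})

test_that("switching off quenching, absorbance and noise freezes the spectra", {
  gt <- groundTruth(quenchEfficiency = 0, absEpsilon = 1e-9, noiseSd = 0)
  sim <- simulateTitration(gt)
  ref <- intensities(sim$observed[[1]]@spectra[[1]])
  for (p in names(sim$observed))
    for (s in sim$observed[[p]]@spectra)
      expect_equal(intensities(s), ref, tolerance = 1e-9)
})

test_that("correcting observed spectra with generator absorbances closes the loop", {
  sim <- simulateTitration(groundTruth())
  for (p in names(sim$observed)) {
    corr <- correctTitration(sim$observed[[p]],
                             absorbance = sim$absorbance)
    tru <- sim$trueSeries[[p]]
    for (i in seq_along(corr@spectra))
      expect_equal(intensities(corr@spectra[[i]]),
                   intensities(tru@spectra[[i]]), tolerance = 1e-12)
  }
})

test_that("observed quench depth matches the occupancy model", {
  sim <- simulateTitration(groundTruth())
  gt <- sim$truth
  series <- sim$trueSeries[["P_4e-06"]]
  crv <- buildCurve(series, mode = "area")
  occ <- sim$occupancy[sim$occupancy$proteinM == 4e-6, ]
  expected <- 1 / (1 - gt@quenchEfficiency * occ$sumNu / sum(gt@siteN))
  expect_equal(crv@ratio, expected, tolerance = 1e-9)
})
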