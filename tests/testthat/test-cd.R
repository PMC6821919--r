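test_that("mean residue ellipticity conversion is exact and invertible", {
  expect_equal(meanResidueEllipticity(0, 4e-6, 0.01), 0)
  expect_equal(meanResidueEllipticity(100, 4e-6, 0.01, 584),
               100 / (10 * 4e-6 * 0.01 * 584))
  # linear in theta, halved by doubling the concentration
  expect_equal(meanResidueEllipticity(50, 4e-6, 0.01),
               meanResidueEllipticity(100, 4e-6, 0.01) / 2)
  expect_equal(meanResidueEllipticity(100, 8e-6, 0.01),
               meanResidueEllipticity(100, 4e-6, 0.01) / 2)
  # round trip
  mre <- meanResidueEllipticity(-12.3, 4e-6, 0.01, 584)
  expect_equal(mre * 10 * 4e-6 * 0.01 * 584, -12.3)
  expect_error(meanResidueEllipticity(10, 0, 0.01), "positive")
})

test_that("negative band minima are located on the grid", {
  expect_equal(bandMinima(simulateCD()), c(208, 222))

  grid <- seq(200, 260, 0.5)
  pos <- Spectrum("cd", grid, 5 + (grid - 230)^2 / 100)
  expect_equal(bandMinima(pos), numeric(0))

  parab <- Spectrum("cd", grid, (grid - 215)^2 / 50 - 10)
  expect_equal(bandMinima(parab), 215)

  expect_error(bandMinima(flatEmission(1)), "kind 'cd'")
})

test_that("simulated CD spectra are reproducible and scale with amplitude", {
  s1 <- simulateCD(noiseSd = 0.2, seed = 11L)
  s2 <- simulateCD(noiseSd = 0.2, seed = 11L)
  expect_identical(intensities(s1), intensities(s2))
  flat <- simulateCD(amplitudesMdeg = c(0, 0))
  expect_true(all(intensities(flat) == 0))
})
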