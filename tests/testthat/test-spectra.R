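test_that("spectra round-trip through the delimited text format", {
  grid <- 305:307
  s1 <- Spectrum("emission", grid, c(1, 5, 2), excitationNm = 295,
                 temperatureK = 298, proteinM = 4e-6, ligandM = 0)
  s2 <- Spectrum("emission", grid, c(2, 4, 1), excitationNm = 295,
                 temperatureK = 298, proteinM = 4e-6, ligandM = 2e-6)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(list(a = s1, b = s2), path)
  back <- readSpectra(path)
  expect_length(back, 2L)
  expect_equal(names(back), c("a", "b"))
  expect_equal(intensities(back$a), c(1, 5, 2))
  expect_equal(wavelengths(back$b), as.numeric(grid))
  expect_equal(ligandConc(back$b), 2e-6)
  expect_equal(back$a@excitationNm, 295)

  # tab-delimited round-trip too
  pathTsv <- withr::local_tempfile(fileext = ".tsv")
  writeSpectra(list(a = s1), pathTsv, delim = "\t")
  expect_equal(intensities(readSpectra(pathTsv)$a), c(1, 5, 2))
})

test_that("reader enforces metadata and grid validity", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# kind: emission", "series_id,wavelength_nm,value",
               "s1,305,1", "s1,306,2"), path)
  expect_error(readSpectra(path), "excitation_nm")

  writeLines(c("# kind: absorbance", "series_id,wavelength_nm,value",
               "s1,305,1", "s1,304,2", "s1,306,2"), path)
  expect_error(readSpectra(path), "strictly increasing")

  writeLines(c("# kind emission", "series_id,wavelength_nm,value",
               "s1,305,1", "s1,306,2"), path)
  expect_error(readSpectra(path), "line 1")

  expect_error(readSpectra(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("baseline subtraction clamps at zero and keeps metadata", {
  grid <- 305:306
  sample <- Spectrum("emission", grid, c(10, 20), excitationNm = 295,
                     ligandM = 1e-6)
  buffer <- Spectrum("emission", grid, c(12, 5), excitationNm = 295)
  expect_message(out <- subtractBaseline(sample, buffer), "clamped 1")
  expect_equal(intensities(out), c(0, 15))
  expect_equal(ligandConc(out), 1e-6)

  # self-subtraction and zero buffer
  expect_equal(intensities(subtractBaseline(sample, sample)), c(0, 0))
  zero <- Spectrum("emission", grid, c(0, 0), excitationNm = 295)
  expect_equal(intensities(subtractBaseline(sample, zero)), c(10, 20))

  off <- Spectrum("emission", grid + 1, c(0, 0), excitationNm = 295)
  expect_error(subtractBaseline(sample, off), "grid")
})

test_that("inner-filter correction reproduces the closed-form factor", {
  grid <- 305:500
  em <- Spectrum("emission", grid, dnorm(grid, 340, 25) * 1e3,
                 excitationNm = 295)
  zeroAbs <- Spectrum("absorbance", 240:520, rep(0, 281))
  expect_identical(intensities(innerFilterCorrect(em, zeroAbs)),
                   intensities(em))
  expect_true(isCorrected(innerFilterCorrect(em, zeroAbs)))

  # A(exc) = A(lambda) = 1 => factor 10
  oneAbs <- Spectrum("absorbance", 240:520, rep(1, 281))
  expect_equal(intensities(innerFilterCorrect(em, oneAbs)),
               10 * intensities(em))

  # increasing any absorbance never decreases any corrected intensity
  a <- runif(281, 0, 0.5)
  for (i in c(1L, 100L, 281L)) {
    a2 <- a; a2[i] <- a2[i] + 0.3
    lo <- innerFilterCorrect(em, Spectrum("absorbance", 240:520, a))
    hi <- innerFilterCorrect(em, Spectrum("absorbance", 240:520, a2))
    expect_true(all(intensities(hi) >= intensities(lo)))
  }

  # coverage and sign guards
  short <- Spectrum("absorbance", 300:400, rep(0.1, 101))
  expect_error(innerFilterCorrect(em, short), "cover")
  neg <- Spectrum("cd", 240:520, rep(-0.1, 281))
  neg@kind <- "absorbance"  # bypass constructor to probe the guard
  expect_error(innerFilterCorrect(em, neg), "non-negative")
})

test_that("synchronous correction pairs excitation and offset wavelengths", {
  sync <- Spectrum("synchronous", 240:350, rep(100, 111), deltaNm = 60)
  zeroAbs <- Spectrum("absorbance", 200:450, rep(0, 251))
  expect_equal(intensities(innerFilterCorrectSynchronous(sync, zeroAbs)),
               intensities(sync))

  # absorbance nonzero only at 283 and 343 nm: the point excited at 283
  # sees both (its emission sits at 283 + 60 = 343); the point excited at
  # 343 sees only its excitation absorbance; everything else is untouched
  a <- rep(0, 251)
  a[c(283, 343) - 200 + 1] <- c(0.4, 0.6)
  ab <- Spectrum("absorbance", 200:450, a)
  out <- innerFilterCorrectSynchronous(sync, ab)
  i283 <- match(283, wavelengths(sync))
  i343 <- match(343, wavelengths(sync))
  expect_equal(intensities(out)[i283], 100 * 10^((0.4 + 0.6) / 2))
  expect_equal(intensities(out)[i343], 100 * 10^(0.6 / 2))
  expect_equal(intensities(out)[-c(i283, i343)], rep(100, 109))
})

test_that("band integration is exact on simple shapes, additive and linear", {
  grid <- 305:400
  expect_equal(integrateBand(flatEmission(1, grid), 305, 400), 95)
  expect_equal(integrateBand(flatEmission(0, grid), 305, 400), 0)

  tri <- Spectrum("emission", grid,
                  pmax(0, 1 - abs(grid - 340) / 35), excitationNm = 295)
  expect_equal(integrateBand(tri, 305, 375), 35)

  s <- Spectrum("emission", grid, runif(96), excitationNm = 295)
  expect_equal(integrateBand(s, 305, 340) + integrateBand(s, 340, 400),
               integrateBand(s, 305, 400))
  s2 <- s; s2@values <- 3 * s@values
  expect_equal(integrateBand(s2, 310, 390), 3 * integrateBand(s, 310, 390))
  # endpoints between grid points come in by linear interpolation
  expect_equal(integrateBand(flatEmission(2, grid), 305.5, 306.5), 2)
  expect_error(integrateBand(s, 300, 340), "outside")
  expect_error(integrateBand(s, 340, 339), "loNm < hiNm")
})

test_that("peak location uses grid argmax with short-wavelength tie-break", {
  grid <- 300:400
  expect_equal(peakWavelength(Spectrum("emission", grid,
                                       dnorm(grid, 340, 10),
                                       excitationNm = 295)), 340)
  v <- rep(0, 101); v[c(39, 43)] <- 5  # equal maxima at 338 and 342
  expect_equal(peakWavelength(Spectrum("emission", grid, v,
                                       excitationNm = 295)), 338)
  expect_warning(
    w <- peakWavelength(Spectrum("emission", grid, rep(0, 101),
                                 excitationNm = 295)), "constant")
  expect_equal(w, 300)
})

test_that("correction eliminates the apparent red shift on simulated data", {
  sim <- simulateTitration(groundTruth())
  for (p in names(sim$observed)) {
    obs <- sim$observed[[p]]
    tru <- sim$trueSeries[[p]]
    n <- length(obs@spectra)
    # uncorrected top-of-ladder spectrum peaks red of 340
    expect_gt(peakWavelength(obs@spectra[[n]]), 340)
    expect_equal(peakWavelength(tru@spectra[[n]]), 340)
    corr <- correctTitration(obs)
    peaks <- vapply(corr@spectra, peakWavelength, numeric(1))
    expect_true(all(abs(peaks - 340) <= 1))
    # correction with the generator's own absorbances recovers the truth
    corr2 <- correctTitration(obs, absorbance = sim$absorbance)
    for (i in seq_len(n))
      expect_equal(intensities(corr2@spectra[[i]]),
                   intensities(tru@spectra[[i]]), tolerance = 1e-12)
  }
})
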