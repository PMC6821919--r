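test_that("quenching curves form reference ratios and guard their inputs", {
  s <- signalSeries(c(100, 50, 25), c(0, 1e-6, 2e-6))
  crv <- buildCurve(s, mode = "intensity", read = 340)
  expect_equal(crv@ratio, c(1, 2, 4))

  noZero <- signalSeries(c(100, 50), c(1e-6, 2e-6))
  expect_error(buildCurve(noZero), "zero-ligand")

  raw <- signalSeries(c(100, 50, 25), c(0, 1e-6, 2e-6), corrected = FALSE)
  expect_error(buildCurve(raw), "inner-filter")
})

test_that("intensity and area modes agree when quenching is flat in wavelength", {
  x <- simulatedCorrected()
  series <- x$corrected[["P_4e-06"]]
  ci <- buildCurve(series, mode = "intensity", read = 340)
  ca <- buildCurve(series, mode = "area", read = c(305, 400))
  expect_equal(ci@ratio, ca@ratio, tolerance = 1e-6)
  svI <- sternVolmerFit(ci)
  svA <- sternVolmerFit(ca)
  expect_lt(abs(svI@Ksv - svA@Ksv) / svI@Ksv, 1e-3)
})

test_that("Stern-Volmer fit recovers an exact line and the kq identity", {
  L <- seq(0, 32e-6, 2e-6)
  crv <- ratioCurve(L, 1 + 2.11e4 * L)
  sv <- sternVolmerFit(crv, tau0 = 6.71e-9)
  expect_equal(sv@Ksv, 2.11e4, tolerance = 1e-12)
  expect_equal(sv@kq, sv@Ksv / 6.71e-9)          # exact identity
  expect_equal(sv@kq, 3.14e12, tolerance = 2e-3)  # 3.14e12 1/(M s)
  expect_equal(sv@r2, 1, tolerance = 1e-12)

  # free-intercept diagnostic on the same line
  svFree <- sternVolmerFit(crv, fixIntercept = FALSE)
  expect_equal(svFree@Ksv, 2.11e4, tolerance = 1e-9)
  expect_equal(svFree@intercept, 1, tolerance = 1e-9)

  flat <- ratioCurve(L, rep(1, length(L)))
  expect_equal(sternVolmerFit(flat)@Ksv, 0)
  expect_error(sternVolmerFit(ratioCurve(c(0, 1e-6), c(1, 1.1))),
               "3 points")
})

test_that("mechanism classification follows the published rules", {
  L <- seq(2e-6, 32e-6, 2e-6)
  Fr <- 1 + 2.11e4 * L   # intensity ratios reaching ~1.68
  sv <- sternVolmerFit(ratioCurve(c(0, L), c(1, Fr)), tau0 = 6.71e-9)

  # lifetime flat near 1 while intensity grows, kq far above 1e10: static
  tauR <- seq(1, 6.71 / 6.28, length.out = length(L))
  expect_equal(classifyMechanism(sv, tauR, Fr)@verdict, "static")

  # exact equivalence => dynamic even with modest kq
  svDyn <- new("SternVolmerResult", Ksv = 5e3, KsvSE = 0, r2 = 1,
               kq = 5e9, tau0 = 1e-9, intercept = 1, interceptFixed = TRUE,
               mode = "intensity", temperatureK = 298)
  expect_equal(classifyMechanism(svDyn, Fr, Fr)@verdict, "dynamic")

  # halfway between unity and the intensity response: mixed
  expect_equal(classifyMechanism(sv, (1 + Fr) / 2, Fr)@verdict, "mixed")

  expect_error(classifyMechanism(sv, tauR[-1], Fr), "aligned")
})

test_that("double-log fit recovers a 1:1 binding model", {
  Ka <- 2.24e4; P <- 4e-6
  L <- seq(2e-6, 32e-6, 2e-6)
  B <- boundConc(Ka, P, L)
  F0 <- 1000
  Fs <- F0 * (1 - B / P)
  crv <- ratioCurve(c(0, L), c(F0, Fs)[1] / c(F0, Fs), proteinM = P)
  fit <- doubleLogFit(crv)
  expect_equal(fit@Ka, 2.24e4, tolerance = 0.05)
  expect_lt(abs(fit@nSites - 1), 0.05)
  expect_equal(fit@r2, 1, tolerance = 1e-9)
})

test_that("double-log fit is exactly log-linear and scale invariant", {
  # construct data where (F0-F)/F = Ka * Lcorr exactly
  Ka <- 1e5; P <- 4e-6
  L <- seq(2e-6, 32e-6, 2e-6)
  r <- numeric(length(L))  # solve r - 1 = Ka (L - (1-1/r) P) per point
  for (i in seq_along(L))
    r[i] <- uniroot(function(x) (x - 1) - Ka * (L[i] - (1 - 1 / x) * P),
                    c(1 + 1e-12, 1e5), tol = 1e-14)$root
  crv <- ratioCurve(c(0, L), c(1, r), proteinM = P)
  fit <- doubleLogFit(crv)
  expect_equal(fit@nSites, 1, tolerance = 1e-6)
  expect_equal(fit@Ka, Ka, tolerance = 1e-4)

  # ratios are scale-free: rescaling all fluorescence leaves the fit alone
  s <- signalSeries(1000 * c(1, 1 / r), c(0, L), proteinM = P)
  s2 <- signalSeries(7.3 * 1000 * c(1, 1 / r), c(0, L), proteinM = P)
  f1 <- doubleLogFit(buildCurve(s))
  f2 <- doubleLogFit(buildCurve(s2))
  expect_equal(f1@Ka, f2@Ka)
  expect_equal(f1@nSites, f2@nSites)

  flat <- ratioCurve(c(0, L), rep(1, length(L) + 1))
  expect_error(suppressWarnings(doubleLogFit(flat)), "4 usable")
})
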