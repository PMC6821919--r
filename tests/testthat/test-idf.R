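test_that("quench percentage follows its definition", {
  expect_equal(quenchPercentage(80, 80), 0)
  expect_equal(quenchPercentage(40, 80), 50)
  expect_equal(quenchPercentage(0, 80), 100)
  expect_error(quenchPercentage(10, 0), "positive")
})

test_that("level matching solves the mass-conservation line exactly on crafted data", {
  # three titrations built so each quench level is sampled exactly at
  # totals T = Lfree + 0.5 [P]: slope must be 0.5, intercept Lfree, r2 = 1
  P <- c(2e-6, 4e-6, 8e-6)
  Lfree <- (1:8) * 1e-6
  dF <- 5 * (1:8)
  seriesList <- lapply(P, function(p) {
    totals <- c(0, Lfree + 0.5 * p)
    signalSeries(1000 * c(1, 1 - dF / 100), totals, proteinM = p,
                 temperatureK = 288)
  })
  lv <- matchLevels(seriesList, levels = dF[2:7], mode = "intensity",
                    read = 340)
  expect_true(all(lv@levels$accepted))
  expect_equal(lv@levels$sumNu, rep(0.5, 6), tolerance = 1e-9)
  expect_equal(lv@levels$freeLigandM, Lfree[2:7], tolerance = 1e-9)
  expect_equal(lv@levels$r2, rep(1, 6), tolerance = 1e-9)
  # the level at Lfree = 2 uM with [P] = 2/4/8 uM inverts to totals 3/4/6 uM
  lv1 <- matchLevels(seriesList, levels = dF[2], mode = "intensity")
  expect_equal(unname(lv1@totals[1, ]), c(3, 4, 6) * 1e-6,
               tolerance = 1e-9)
})

test_that("level matching recovers the generator's occupancy model", {
  x <- simulatedCorrected()
  lv <- matchLevels(x$corrected, nLevels = 20)
  gt <- x$sim$truth
  acc <- lv@levels[lv@levels$accepted, ]
  # forward-model oracle: deltaF = 100 * qE * sumNu / sum(n)
  nuExpected <- acc$deltaF / 100 * sum(gt@siteN) / gt@quenchEfficiency
  relErr <- abs(acc$sumNu - nuExpected) / nuExpected
  expect_lt(median(relErr), 0.02)   # interpolation error only
  expect_lt(max(relErr), 0.15)
  # free ligand consistent with inverting the occupancy curve
  LfreeExpected <- vapply(nuExpected, function(nu)
    uniroot(function(L) eq8SumNu(L) - nu, c(1e-9, 1e-3), tol = 1e-15)$root,
    numeric(1))
  expect_lt(median(abs(acc$freeLigandM - LfreeExpected) / LfreeExpected),
            0.02)
})

test_that("level matching rejects degenerate designs", {
  x <- simulatedCorrected()
  expect_error(matchLevels(x$corrected[1]), ">= 2 protein")
  # gross non-monotone series beyond tolerance, named in the error
  bad <- signalSeries(c(1000, 800, 950, 600), seq(0, 6e-6, 2e-6),
                      proteinM = 2e-6, temperatureK = 288)
  ok <- signalSeries(c(1000, 900, 800, 700), seq(0, 6e-6, 2e-6),
                     proteinM = 4e-6, temperatureK = 288)
  expect_error(matchLevels(list(bad, ok), nLevels = 5), "series 1")
})

test_that("Scatchard transform diagnoses cooperativity correctly", {
  # independent-site Langmuir: monotone declining, never cooperative
  k <- 1e5
  L <- 10^seq(-6, -4.3, length.out = 5)
  nu <- k * L / (1 + k * L)
  sc <- scatchard(BindingDensityCurve(L, nu))
  expect_equal(sc@verdict, "non-cooperative")
  expect_equal(sc@ratio, nu / L)

  # cooperative Hill curve: interior maximum of nu/L
  L2 <- 10^seq(-6, -4.5, length.out = 12)
  nu2 <- (2.3e5 * L2)^2.93 / (1 + (2.3e5 * L2)^2.93)
  expect_equal(scatchard(BindingDensityCurve(L2, nu2))@verdict,
               "positive-cooperative")

  expect_error(scatchard(BindingDensityCurve(L[1:3], nu[1:3])), "4 points")
})

test_that("Scatchard never calls w = 1 data cooperative", {
  for (k in 10^seq(4, 6, by = 0.5)) {
    L <- 10^seq(log10(0.05 / k), log10(20 / k), length.out = 8)
    nu <- k * L / (1 + k * L)
    expect_false(scatchard(BindingDensityCurve(L, nu))@verdict ==
                   "positive-cooperative")
  }
})

test_that("Hill fit recovers a single Langmuir class exactly", {
  k <- 1e5
  L <- 10^seq(-6, -4, length.out = 12)
  fit <- hillFit(BindingDensityCurve(L, k * L / (1 + k * L)),
                 maxClasses = 2)
  expect_equal(fit@nClasses, 1L)
  expect_equal(fit@classes$k, k, tolerance = 1e-6)
  expect_equal(fit@classes$w, 1, tolerance = 1e-6)
})

test_that("Hill fit recovers the two-class cooperative truth from noiseless points", {
  L <- 10^seq(log10(2e-6), log10(1.6e-5), length.out = 30)
  fit <- hillFit(BindingDensityCurve(L, eq8SumNu(L)), maxClasses = 3)
  expect_equal(fit@nClasses, 2L)
  expect_equal(fit@classes$k[1], 2.3e5, tolerance = 0.05)
  expect_equal(fit@classes$k[2], 1.3e5, tolerance = 0.05)
  expect_equal(fit@classes$w[1], 2.93, tolerance = 0.05)
  expect_equal(fit@classes$w[2], 8.15, tolerance = 0.05)
  # the fitted occupancy evaluates to the closed form at k1 L = 1
  expect_equal(predictSumNu(fit, 1 / 2.3e5), 0.5095, tolerance = 1e-3)
  expect_error(hillFit(BindingDensityCurve(L, eq8SumNu(L)), maxClasses = 0),
               "maxClasses")
})

test_that("predicted binding density is monotone and saturates at sum(n)", {
  set.seed(42)
  for (i in 1:5) {
    model <- new("HillModel",
                 classes = data.frame(n = c(1, 1),
                                      k = 10^runif(2, 4, 6),
                                      kSE = NA_real_,
                                      w = runif(2, 0.5, 6),
                                      wSE = NA_real_),
                 nClasses = 2L, rss = 0, aicc = 0,
                 scan = data.frame(), nPoints = 0L)
    L <- 10^seq(-8, -2, length.out = 200)
    nu <- predictSumNu(model, L)
    expect_true(all(diff(nu) > 0))
    expect_true(all(nu < 2))
    expect_gt(max(nu), 1.99)   # saturation approached at high ligand
  }
})
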