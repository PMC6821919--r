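test_that("decay fits recover noiseless exponential parameters", {
  t <- seq(0, 50, by = 0.05)
  f1 <- fitDecay(DecayTrace(t, 1e4 * exp(-t / 6.71)), 1)
  expect_lt(abs(f1@tau - 6.71) / 6.71, 1e-3)

  f2 <- fitDecay(DecayTrace(t, 1e4 * (0.7 * exp(-t / 7) +
                                        0.3 * exp(-t / 2))), 2)
  expect_equal(f2@tau, c(7, 2), tolerance = 0.01)
  expect_equal(f2@alpha, c(0.7, 0.3), tolerance = 0.01)
  expect_equal(sum(f2@alpha), 1)          # amplitudes normalised
  expect_true(all(diff(f2@tau) < 0))      # descending lifetimes

  expect_error(fitDecay(DecayTrace(t, rep(0, length(t))), 1), "no counts")
  expect_error(fitDecay(DecayTrace(t, exp(-t)), 3), "1- or 2-component")
})

test_that("average lifetime is the intensity-weighted mean and scale free", {
  mk <- function(a, tau) new("DecayFit", alpha = a / sum(a), tau = tau,
                             tauSE = rep(NA_real_, length(tau)),
                             chisqRed = 1, nPoints = 100L)
  expect_equal(averageLifetime(mk(1, 6.71)), 6.71)
  expect_equal(averageLifetime(mk(c(0.5, 0.5), c(4, 2))), 10 / 3)
  # zero-amplitude component is inert
  expect_equal(averageLifetime(mk(c(0, 1), c(99, 5))), 5)
  # amplitude rescaling cancels in the ratio of moments
  a <- c(0.7, 0.3)
  expect_equal(averageLifetime(mk(a, c(7, 2))),
               averageLifetime(mk(10 * a, c(7, 2))))
  # tau_avg lies between the component lifetimes
  tavg <- averageLifetime(mk(c(0.6, 0.4), c(8, 3)))
  expect_true(tavg > 3 && tavg < 8)
})

test_that("lifetime ratio series references the zero-ligand lifetime", {
  t <- seq(0, 50, by = 0.05)
  fits <- lapply(c(6.71, 6.28), function(tau)
    fitDecay(DecayTrace(t, 1e4 * exp(-t / tau)), 1))
  out <- lifetimeRatioSeries(fits, c(0, 32e-6))
  expect_equal(out$tauRatio, c(1, 6.71 / 6.28), tolerance = 1e-4)

  same <- lifetimeRatioSeries(rep(fits[1], 3), c(0, 1e-6, 2e-6))
  expect_equal(same$tauRatio, rep(1, 3))

  expect_error(lifetimeRatioSeries(list(), numeric(0)), "empty")
  expect_error(lifetimeRatioSeries(fits, c(1e-6, 2e-6)), "zero-ligand")
})

test_that("lifetime recovery is unbiased under Poisson noise", {
  errs <- vapply(1:50, function(s) {
    tr <- simulateDecay(groundTruth(seed = s), ligandM = 0)
    (fitDecay(tr, 1)@tau - 6.71) / 6.71
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("simulated decays are deterministic and follow the lifetime modes", {
  gt <- groundTruth(seed = 7L)
  tr1 <- simulateDecay(gt, 8e-6)
  tr2 <- simulateDecay(gt, 8e-6)
  expect_identical(tr1@counts, tr2@counts)

  # pure static: lifetime unchanged; mixed: shortened to 6.28 at the top
  top <- max(gt@ligandM)
  fStatic <- fitDecay(simulateDecay(gt, top, noise = FALSE), 1)
  expect_equal(fStatic@tau, 6.71, tolerance = 1e-3)
  fMixed <- fitDecay(simulateDecay(gt, top, lifetimeMode = "mixed",
                                   noise = FALSE), 1)
  expect_equal(fMixed@tau, 6.28, tolerance = 1e-3)
  expect_equal(6.71 / fMixed@tau, 1.068, tolerance = 1e-3)

  # decay trace round-trip through the two-column text format
  path <- withr::local_tempfile(fileext = ".csv")
  writeDecay(tr1, path)
  back <- readDecay(path)
  expect_equal(back@counts, tr1@counts)
  expect_equal(back@ligandM, 8e-6)
})
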