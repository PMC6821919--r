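test_that("Gibbs free energy from Ka matches hand calculation", {
  expect_equal(gibbsFromKa(2.24e4, 298), -8.314 * 298 * log(2.24e4) / 1000)
  expect_equal(gibbsFromKa(1, 310), 0)
  expect_lt(gibbsFromKa(2, 298), 0)   # Ka > 1 <=> spontaneous
  expect_gt(gibbsFromKa(0.5, 298), 0)
  expect_error(gibbsFromKa(-1, 298), "positive")
  expect_error(gibbsFromKa(10, 0), "positive")
})

test_that("Van't Hoff regression recovers exact linear inputs", {
  # generate ln Ka exactly linear in 1/T from known dH, dS
  dH <- 14.5e3; dS <- 130  # J/mol, J/(mol K)
  Ts <- c(288, 298, 308, 318)
  Ka <- exp(-dH / (8.314 * Ts) + dS / 8.314)
  th <- vantHoffFit(Ts, Ka)
  expect_equal(th@deltaH, dH / 1000, tolerance = 1e-10)
  expect_equal(th@deltaS, dS, tolerance = 1e-10)
  expect_equal(th@r2, 1, tolerance = 1e-12)
  # deltaG consistency: dH - T dS equals -RT ln Ka on exact inputs
  expect_equal(th@deltaG, th@deltaGdirect, tolerance = 1e-10)
  expect_equal(th@TdeltaS, Ts * dS / 1000)
})

test_that("flat Ka across temperature gives dH = 0 and dS = R ln Ka", {
  th <- vantHoffFit(c(288, 298, 308), rep(5e4, 3))
  expect_equal(th@deltaH, 0, tolerance = 1e-9)
  expect_equal(th@deltaS, 8.314 * log(5e4), tolerance = 1e-9)
})

test_that("Van't Hoff preconditions and sign conventions hold", {
  expect_error(vantHoffFit(c(288, 298), c(1e4, 2e4)), "3 temperatures")
  expect_error(vantHoffFit(c(288, 298, 308), c(1e4, -2e4, 3e4)), "positive")
  # Ka rising with T => endothermic (dH > 0), entropy-driven
  th <- vantHoffFit(c(288, 298, 308), c(1.72e4, 2.24e4, 2.54e4))
  expect_gt(th@deltaH, 0)
  expect_gt(th@deltaS, 0)
  expect_true(all(th@deltaG < 0))
  # unit audit: TdS (kJ/mol) = T * dS (J/(mol K)) / 1000
  expect_equal(th@TdeltaS, th@temperatures * th@deltaS / 1000)
})

test_that("weighted fit uses Ka uncertainties and propagates direct dG errors", {
  Ts <- c(288, 298, 308)
  Ka <- c(1.72e4, 2.24e4, 2.54e4)
  KaSE <- c(0.07e4, 0.09e4, 0.09e4)
  th <- vantHoffFit(Ts, Ka, KaSE = KaSE, weighted = TRUE)
  expect_true(all(is.finite(th@deltaGdirectSE)))
  expect_equal(th@deltaGdirectSE,
               8.314 * Ts * (KaSE / Ka) / 1000)
  expect_error(vantHoffFit(Ts, Ka, weighted = TRUE), "KaSE")
})
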