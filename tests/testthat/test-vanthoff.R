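# van't Hoff regression and bootstrap uncertainties.

test_that("a noiseless line is recovered to machine precision", {
  tab <- generateVantHoffTable(syntheticVantHoffSpec(
    deltaH = -11.6, deltaS = -0.016, noiseSD = 0, seed = 1))
  prof <- fitVantHoff(tab, Tref = 300)
  expect_equal(ddH(prof), -11.6, tolerance = 1e-9)
  expect_equal(minusTddS(prof), 4.8, tolerance = 1e-9)
  expect_equal(prof@rSquared, 1, tolerance = 1e-9)
  # reconstruction reproduces the fitted line at every input temperature
  expect_equal(predictDG(prof, tab$temperature), tab$dG, tolerance = 1e-9)
})

test_that("the analytic harmonic free energy has zero enthalpy", {
  temps <- vantHoffTemperatures()
  tab <- data.frame(temperature = temps, replicate = 1L,
                    dG = kB * temps / 2 * log(2))
  prof <- fitVantHoff(tab)
  expect_equal(ddH(prof), 0, tolerance = 1e-12)
  expect_equal(prof@ddS, -kB / 2 * log(2), tolerance = 1e-12)
})

test_that("the profile is invariant to permuting temperature rows", {
  tab <- generateVantHoffTable(syntheticVantHoffSpec(seed = 3))
  p1 <- fitVantHoff(tab)
  set.seed(1)
  p2 <- fitVantHoff(tab[sample(nrow(tab)), ])
  expect_equal(ddH(p1), ddH(p2), tolerance = 1e-12)
  expect_equal(minusTddS(p1), minusTddS(p2), tolerance = 1e-12)
})

test_that("profile additivity ddG(Tref) = ddH + (-Tref ddS) holds by construction", {
  tab <- generateVantHoffTable(syntheticVantHoffSpec(seed = 4))
  prof <- fitVantHoff(tab, Tref = 300)
  expect_equal(predictDG(prof, 300), ddH(prof) + minusTddS(prof),
               tolerance = 1e-12)
})

test_that("too few temperatures are rejected", {
  tab <- data.frame(temperature = c(290, 300), replicate = 1, dG = c(-1, -1.1))
  expect_error(fitVantHoff(tab), "at least 3 distinct temperatures")
  expect_error(fitVantHoff(data.frame(temperature = rep(300, 5), dG = 1:5)),
               "at least 3 distinct temperatures")
})

test_that("bootstrap intervals are seed-reproducible and collapse at zero noise", {
  tab <- generateVantHoffTable(syntheticVantHoffSpec(noiseSD = 0.2, seed = 5))
  b1 <- bootstrapProfile(tab, nBoot = 200, seed = 11)
  b2 <- bootstrapProfile(tab, nBoot = 200, seed = 11)
  expect_identical(b1$ciDdH, b2$ciDdH)
  tab0 <- generateVantHoffTable(syntheticVantHoffSpec(noiseSD = 0, seed = 5))
  b0 <- bootstrapProfile(tab0, nBoot = 100, seed = 1)
  expect_equal(diff(b0$ciDdH), 0, tolerance = 1e-9)
  expect_equal(diff(b0$ciMinusTddS), 0, tolerance = 1e-9)
})

test_that("a single replicate falls back to regression standard errors with a warning", {
  tab <- generateVantHoffTable(syntheticVantHoffSpec(nReplicates = 1L, seed = 6))
  expect_warning(b <- bootstrapProfile(tab, nBoot = 50, seed = 1),
                 "regression standard errors")
  prof <- fitVantHoff(tab)
  expect_equal(b$ciDdH, prof@ciDdH)
})

test_that("bootstrap interval width is comparable to the regression standard error", {
  tab <- generateVantHoffTable(syntheticVantHoffSpec(
    deltaH = -11.6, deltaS = -0.016, noiseSD = 0.2, seed = 7))
  prof <- fitVantHoff(tab)
  b <- bootstrapProfile(tab, nBoot = 1000, seed = 2)
  halfWidth <- diff(b$ciDdH) / 2
  regHalfWidth <- qnorm(0.975) * prof@seDdH
  expect_gt(halfWidth / regHalfWidth, 0.5)
  expect_lt(halfWidth / regHalfWidth, 1.5)
})
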