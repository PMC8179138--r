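# Ki-to-free-energy conversion.

test_that("unit Ki gives zero free energy and halving lowers it by RT ln 2", {
  expect_equal(kiToDeltaG(1), 0)
  RT <- kB * 298.15
  expect_equal(kiToDeltaG(0.5e-6) - kiToDeltaG(1e-6), -RT * log(2),
               tolerance = 1e-12)
})

test_that("the Ki ratio for a 45 nM vs 39 uM pair is -4.0 kcal/mol", {
  a <- affinityRecord("adenosine", Ki = 45e-9)
  b <- affinityRecord("3-deazaadenosine", Ki = 39e-6)
  expect_equal(round(ddgFromKi(a, b), 1), -4.0)
  # antisymmetry is exact
  expect_equal(ddgFromKi(a, b), -ddgFromKi(b, a), tolerance = 1e-15)
  # and the ratio equals the difference of the absolute conversions
  expect_equal(ddgFromKi(a, b), kiToDeltaG(a) - kiToDeltaG(b),
               tolerance = 1e-12)
})

test_that("a 103 nM Ki converts to about -9.53 kcal/mol at 298.15 K", {
  expect_equal(kiToDeltaG(affinityRecord("cpd4", Ki = 103e-9)), -9.532,
               tolerance = 5e-4)
})

test_that("equal affinities give zero relative free energy", {
  a <- affinityRecord("x", Ki = 2e-7); b <- affinityRecord("y", Ki = 2e-7)
  expect_equal(ddgFromKi(a, b), 0)
})

test_that("invalid or incomparable records are rejected", {
  expect_error(affinityRecord("bad", Ki = -1), "positive")
  expect_error(kiToDeltaG(-2), "positive")
  pct <- affinityRecord("weak", percentInhibition = 35)
  expect_error(kiToDeltaG(pct), "no Ki")
  a <- affinityRecord("x", Ki = 1e-7, temperature = 298.15)
  b <- affinityRecord("y", Ki = 1e-7, temperature = 310)
  expect_error(ddgFromKi(a, b), "temperature mismatch")
})
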