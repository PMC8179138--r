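# Zwanzig estimator, leg accumulation and thermodynamic-cycle combination.

test_that("degenerate perturbation distributions are estimated exactly", {
  z <- zwanzigWindow(perturbationSeries(rep(0, 100)))
  expect_identical(z$dG, 0)
  expect_identical(z$sem, 0)
  z <- zwanzigWindow(perturbationSeries(rep(1.234, 50)))
  expect_equal(z$dG, 1.234, tolerance = 1e-12)
  expect_equal(z$sem, 0, tolerance = 1e-12)
})

test_that("the Zwanzig estimate is invariant under frame reordering", {
  set.seed(5)
  for (i in 1:5) {
    dU <- rnorm(200, mean = 0.3, sd = 0.5)
    a <- zwanzigWindow(perturbationSeries(dU))$dG
    b <- zwanzigWindow(perturbationSeries(sample(dU)))$dG
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("empty or non-finite series are rejected", {
  expect_error(perturbationSeries(numeric(0)), "non-empty")
  expect_error(perturbationSeries(c(1, NaN)), "non-finite")
  expect_warning(zwanzigWindow(perturbationSeries(rep(0.1, 5))), "fewer than 10")
})

test_that("the full harmonic ladder recovers the closed-form free energy", {
  spec <- harmonicSpec(1, 1, 2, temperature = 300)
  analytic <- harmonicFreeEnergy(spec)
  # independent oracle: quadrature of the two partition functions
  expect_equal(quadHarmonicDF(1, 2, 300), analytic, tolerance = 1e-9)
  leg <- fepLeg(spec, "bound", lambdaLadder(84), nSteps = 2e4, seed = 1)
  expect_lt(abs(legDG(leg) - analytic), 3 * leg@legSEM)
})

test_that("forward and reverse transformations close the cycle (hysteresis)", {
  fwd <- harmonicSpec(1, 1, 2)
  rev <- harmonicSpec(1, 2, 1)
  lf <- fepLeg(fwd, "bound", lambdaLadder(24), nSteps = 2e4, seed = 2)
  lr <- fepLeg(rev, "bound", lambdaLadder(24), nSteps = 2e4, seed = 3)
  sem <- sqrt(lf@legSEM^2 + lr@legSEM^2)
  expect_lt(abs(legDG(lf) + legDG(lr)), 3 * sem)
})

test_that("doubling the ladder leaves the leg free energy unchanged within error", {
  spec <- harmonicSpec(1, 1, 2)
  l1 <- fepLeg(spec, "bound", lambdaLadder(12), nSteps = 4e4, seed = 4)
  l2 <- fepLeg(spec, "bound", lambdaLadder(24), nSteps = 4e4, seed = 5)
  expect_lt(abs(legDG(l1) - legDG(l2)), sqrt(l1@legSEM^2 + l2@legSEM^2) * 3)
})

test_that("harmonic leg free energy scales linearly with temperature (zero enthalpy)", {
  temps <- c(280, 300, 320)
  over_t <- vapply(seq_along(temps), function(i) {
    spec <- harmonicSpec(1, 1, 2, temperature = temps[i])
    legDG(fepLeg(spec, "bound", lambdaLadder(12), nSteps = 2e4,
                 seed = 30 + i)) / temps[i]
  }, numeric(1))
  expect_lt(max(over_t) - min(over_t), 1e-4)
  expect_equal(mean(over_t), kB / 2 * log(2), tolerance = 0.02)
})

test_that("leg accumulation sums windows and checks the ladder", {
  expect_equal(legDG(accumulateLeg(0.5, "bound")), 0.5)
  expect_equal(legDG(accumulateLeg(c(0.1, -0.2, 0.3), "bound")), 0.2,
               tolerance = 1e-12)
  expect_error(accumulateLeg(c(0.1, 0.2), "bound", ladder = lambdaLadder(3)),
               "does not match")
})

test_that("cycle combination differences the legs and propagates errors", {
  b <- feResult(-8, "bound"); u <- feResult(-2, "unbound")
  expect_equal(ddG(cycleCombine(b, u)), -6)
  expect_equal(ddG(cycleCombine(feResult(1.1, "bound"), feResult(1.1, "unbound"))), 0)
  expect_error(cycleCombine(feResult(1, "bound", temperature = 300),
                            feResult(1, "unbound", temperature = 310)),
               "temperature mismatch")
  expect_error(cycleCombine(u, u), "labelled")
})

test_that("replicate legs combine as mean and SEM of replicate differences", {
  bReps <- c(-7.9, -8.1, -8.0); uReps <- c(-2.1, -1.9, -2.0)
  b <- combineReplicates(lapply(bReps, feResult, label = "bound"))
  u <- combineReplicates(lapply(uReps, feResult, label = "unbound"))
  rbfe <- cycleCombine(b, u)
  diffs <- bReps - uReps
  expect_equal(ddG(rbfe), mean(diffs), tolerance = 1e-12)
  expect_equal(rbfe@sem, sd(diffs) / sqrt(3), tolerance = 1e-12)
  expect_equal(b@replicateDGs, bReps)
})

test_that("independent seeds give compatible harmonic free energies", {
  spec <- harmonicSpec(1, 1, 2)
  l1 <- fepLeg(spec, "bound", lambdaLadder(12), nSteps = 2e4, seed = 6)
  l2 <- fepLeg(spec, "bound", lambdaLadder(12), nSteps = 2e4, seed = 7)
  expect_false(identical(legDG(l1), legDG(l2)))
  expect_lt(abs(legDG(l1) - legDG(l2)), 3 * sqrt(l1@legSEM^2 + l2@legSEM^2))
})

test_that("poor overlap triggers the concentration warning", {
  set.seed(1)
  dU <- c(rnorm(99, 10, 0.1), -15) # one frame dominates the average
  expect_warning(zwanzigWindow(perturbationSeries(dU)), "poor overlap")
})
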