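# Synthetic-system generators: determinism, Boltzmann sampling quality and
# energy bookkeeping.

test_that("identical harmonic end states give identically zero perturbation energies", {
  spec <- harmonicSpec(1, forceConstantA = 1.5, forceConstantB = 1.5)
  path <- sampleAlchemicalPath(spec, lambdaLadder(11), nSteps = 2000, seed = 3)
  expect_length(path, 11)
  for (s in path) expect_true(all(s@deltaU == 0))
})

test_that("samplers are deterministic functions of their seed", {
  spec <- harmonicSpec(1, 1, 2)
  a <- sampleAlchemicalPath(spec, lambdaLadder(4), nSteps = 2000, seed = 9)
  b <- sampleAlchemicalPath(spec, lambdaLadder(4), nSteps = 2000, seed = 9)
  c <- sampleAlchemicalPath(spec, lambdaLadder(4), nSteps = 2000, seed = 10)
  expect_identical(lapply(a, slot, "deltaU"), lapply(b, slot, "deltaU"))
  expect_false(identical(a[[1]]@deltaU, c[[1]]@deltaU))

  hg <- hostGuestBenchmark(nWater = 6L)
  e1 <- sampleEndState(hg, "A", nSteps = 500, seed = 4)
  e2 <- sampleEndState(hg, "A", nSteps = 500, seed = 4)
  expect_identical(e1$energies, e2$energies)

  tab1 <- generateVantHoffTable(syntheticVantHoffSpec(seed = 7))
  tab2 <- generateVantHoffTable(syntheticVantHoffSpec(seed = 7))
  expect_identical(tab1, tab2)

  n1 <- generateWaterNetwork(plantedSixSiteNetwork(seed = 2, nFrames = 50))
  n2 <- generateWaterNetwork(plantedSixSiteNetwork(seed = 2, nFrames = 50))
  expect_identical(n1@frames, n2@frames)
})

test_that("Metropolis sampling satisfies equipartition on a harmonic well", {
  k <- 1.3
  spec <- harmonicSpec(1, k, k, temperature = 300)
  path <- sampleAlchemicalPath(spec, lambdaLadder(2), nSteps = 1e5, seed = 21,
                               keepPositions = TRUE)
  x <- attr(path, "positions")[[1]][, 1]
  x2 <- x^2
  nb <- 10
  bm <- tapply(x2, cut(seq_along(x2), nb, labels = FALSE), mean)
  sem <- sd(bm) / sqrt(nb)
  expect_lt(abs(mean(x2) - kB * 300 / k), 3 * sem)
})

test_that("recorded host-guest energies match a brute-force O(N^2) recomputation", {
  spec <- hostGuestBenchmark(nWater = 8L)
  es <- sampleEndState(spec, "B", nSteps = 400, seed = 12, stride = 40,
                       trajStride = 40)
  nTraj <- length(es$trajectory@frames)
  expect_gt(nTraj, 3)
  nh <- nrow(spec@host)
  for (k in seq_len(nTraj)) {
    fr <- es$trajectory@frames[[k]]
    guest <- fr$solute[-seq_len(nh), , drop = FALSE]
    ref <- hostGuestEnergy(spec, guest, fr$water, fr$orient)
    rec <- es$components[k, names(ref)]
    expect_lt(max(abs(rec - ref)), 1e-8)
  }
})

test_that("invalid system specifications are rejected with diagnostics", {
  expect_error(harmonicSpec(1, 0, 2), "strictly positive")
  expect_error(harmonicSpec(1, 1, 2, temperature = -10), "positive")
  expect_error(harmonicSpec(2, 1, 2), "1 or 3")
  # two unbonded guests on top of each other
  g <- data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 0),
                  eps = 0.2, sig = 3, mu = 0)
  spec <- hostGuestSpec(host = data.frame(x = 3, y = 0, z = 0, eps = 0.2,
                                          sig = 3, mu = 0), guest = g)
  expect_error(sampleAlchemicalPath(spec, lambdaLadder(2), 100, seed = 1),
               "overlapping particle initialization")
  expect_error(sampleAlchemicalPath(harmonicSpec(), lambdaLadder(2), 100),
               "seed is mandatory")
})

test_that("synthetic free-energy tables lie exactly on the line when noiseless", {
  spec <- syntheticVantHoffSpec(deltaH = -11.6, deltaS = -0.016, noiseSD = 0,
                                seed = 1)
  tab <- generateVantHoffTable(spec)
  expect_equal(tab$dG, -11.6 - tab$temperature * (-0.016), tolerance = 1e-12)
  expect_equal(nrow(tab), 8 * 3)
  # fewer than three temperatures is impossible by construction
  expect_error(syntheticVantHoffSpec(temperatures = c(300, 300, 300), seed = 1),
               "3 distinct temperatures")
  expect_error(syntheticVantHoffSpec(temperatures = 300, seed = 1),
               "3 distinct temperatures")
})

test_that("a zero-spread always-occupied planted site sits exactly at its center", {
  spec <- plantedNetworkSpec(
    data.frame(x = 1, y = -2, z = 0.5, positionalSD = 0,
               orientationalConcentration = 5, occupancyProb = 1),
    bulkDensity = 0, regionRadius = 6, nFrames = 40, seed = 8)
  net <- generateWaterNetwork(spec)
  for (f in net@frames) {
    expect_equal(nrow(f$water), 1)
    expect_equal(as.numeric(f$water), c(1, -2, 0.5), tolerance = 1e-12)
  }
})

test_that("planted sites outside the region are rejected", {
  expect_error(plantedNetworkSpec(
    data.frame(x = 10, y = 0, z = 0, positionalSD = 0.2,
               orientationalConcentration = 1, occupancyProb = 0.5),
    regionRadius = 6, nFrames = 10, seed = 1), "within regionRadius")
})

test_that("von Mises-Fisher orientations concentrate around the site mean direction", {
  net <- generateWaterNetwork(plantedNetworkSpec(
    data.frame(x = 0, y = 0, z = 3, positionalSD = 0.1,
               orientationalConcentration = 50, occupancyProb = 1),
    bulkDensity = 0, regionRadius = 6, nFrames = 200, seed = 3))
  u <- t(vapply(net@frames, function(f) f$orient[1, ], numeric(3)))
  # mean direction is radial (+z here); kappa = 50 means <cos> ~ 0.98
  expect_gt(mean(u[, 3]), 0.9)
})
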