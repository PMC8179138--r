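# Hydration-site clustering, energetics, entropies and network comparison.

test_that("a planted six-site network is recovered with correct geometry and occupancy", {
  net <- generateWaterNetwork(plantedSixSiteNetwork(seed = 5, nFrames = 1000))
  planted <- attr(net, "planted")
  ss <- clusterSites(net, siteRadius = 1.0, minOccupancy = 0.5)
  s <- siteTable(ss)
  expect_equal(nrow(s), 6)
  for (k in seq_len(nrow(planted))) {
    d <- sqrt((s$x - planted$x[k])^2 + (s$y - planted$y[k])^2 +
              (s$z - planted$z[k])^2)
    expect_lt(min(d), 0.5)
    i <- which.min(d)
    p <- planted$occupancyProb[k]
    tol <- 3 * sqrt(p * (1 - p) / 1000) + 0.01 # binomial 3 sigma + bulk pickup
    expect_lt(abs(s$occupancy[i] - p), max(tol, 0.005))
  }
})

test_that("an always-occupied site has occupancy exactly 1", {
  net <- generateWaterNetwork(plantedNetworkSpec(
    data.frame(x = 0, y = 0, z = 0, positionalSD = 0.2,
               orientationalConcentration = 0, occupancyProb = 1),
    bulkDensity = 0, regionRadius = 5, nFrames = 200, seed = 2))
  ss <- clusterSites(net)
  expect_equal(siteTable(ss)$occupancy, 1)
})

test_that("clustering is stable under frame permutation", {
  net <- generateWaterNetwork(plantedSixSiteNetwork(seed = 9, nFrames = 300))
  s1 <- siteTable(clusterSites(net))
  set.seed(4)
  net2 <- net
  net2@frames <- net@frames[sample(length(net@frames))]
  s2 <- siteTable(clusterSites(net2))
  o1 <- s1[order(s1$x, s1$y), c("x", "y", "z")]
  o2 <- s2[order(s2$x, s2$y), c("x", "y", "z")]
  expect_equal(as.matrix(o1), as.matrix(o2), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("empty or short trajectories are handled", {
  frames <- list(list(solute = matrix(0, 0, 3), water = matrix(0, 0, 3),
                      orient = matrix(0, 0, 3)))
  tr <- trajectory(frames, regionRadius = 5)
  expect_error(suppressWarnings(clusterSites(tr)), "empty trajectory")
  net <- generateWaterNetwork(plantedNetworkSpec(
    data.frame(x = 0, y = 0, z = 0, positionalSD = 0.1,
               orientationalConcentration = 0, occupancyProb = 1),
    bulkDensity = 0, regionRadius = 5, nFrames = 20, seed = 1))
  expect_warning(clusterSites(net), "fewer than 100 frames")
})

test_that("site energies reproduce the pair potential for fixed configurations", {
  pot <- waterPairPotential()
  r <- 3.1
  u1 <- c(0, 0, 1); u2 <- c(0, 1 / sqrt(2), 1 / sqrt(2))
  tr <- fixedWaterTrajectory(rbind(c(0, 0, 0), c(r, 0, 0)), rbind(u1, u2),
                             nFrames = 120)
  ss <- siteEnergies(clusterSites(tr), tr, pot)
  expected <- pot$ww(r, sum(u1 * u2))
  expect_equal(siteTable(ss)$E_ww, rep(expected, 2), tolerance = 1e-9)
  expect_equal(siteTable(ss)$E_sw, c(0, 0))

  # with a solute particle: alignment of the water dipole with the axis
  sol <- matrix(c(0, 0, -2.9), 1, 3)
  tr2 <- fixedWaterTrajectory(matrix(c(0, 0, 0), 1, 3),
                              matrix(u1, 1, 3), nFrames = 120, solute = sol)
  ss2 <- siteEnergies(clusterSites(tr2), tr2, pot)
  expect_equal(siteTable(ss2)$E_sw, pot$sw(2.9, 1), tolerance = 1e-9)
  expect_equal(siteTable(ss2)$E_ww, 0)
})

test_that("an isolated site water has zero interaction energies", {
  tr <- fixedWaterTrajectory(matrix(0, 1, 3), matrix(c(0, 0, 1), 1, 3),
                             nFrames = 120)
  ss <- siteEnergies(clusterSites(tr), tr)
  expect_equal(siteTable(ss)$E_ww, 0)
  expect_equal(siteTable(ss)$E_sw, 0)
})

test_that("a bulk-like site has near-zero relative entropies", {
  a <- 3
  rho <- 3 / (4 * pi * a^3)
  tr <- bulkLikeSiteTrajectory(nFrames = 1500, a = a, seed = 6)
  ss <- clusterSites(tr, siteRadius = a + 0.1, minOccupancy = 0.5)
  ss <- siteEntropy(ss, tr, bulkDensity = rho)
  s <- siteTable(ss)
  # estimator noise scale is a few times kB/sqrt(n); both are clamped <= 0
  expect_gt(s$S_trans, -0.1 * kB)
  expect_gt(s$S_orient, -0.1 * kB)
})

test_that("translational entropy follows the Gaussian closed form and is monotone in spread", {
  rho <- 0.0334
  sds <- c(0.15, 0.3, 0.6)
  est <- the <- numeric(length(sds))
  for (i in seq_along(sds)) {
    tr <- gaussianSiteTrajectory(nFrames = 1200, sd = sds[i], kappa = 0,
                                 seed = 20 + i)
    ss <- siteEntropy(clusterSites(tr, siteRadius = 4 * sds[i] + 0.2), tr,
                      bulkDensity = rho)
    est[i] <- siteTable(ss)$S_trans[1]
    the[i] <- min(0, kB * (gaussianEntropy3D(sds[i]) + log(rho)))
  }
  expect_true(all(diff(est) > 0)) # tighter site = more negative
  expect_equal(est, the, tolerance = 0.08) # relative tolerance on kcal/(mol K)
})

test_that("orientational entropy follows the von Mises-Fisher closed form and is monotone in concentration", {
  kappas <- c(0, 5, 20)
  est <- the <- numeric(length(kappas))
  for (i in seq_along(kappas)) {
    tr <- gaussianSiteTrajectory(nFrames = 1200, sd = 0.2, kappa = kappas[i],
                                 seed = 30 + i)
    ss <- siteEntropy(clusterSites(tr), tr, bulkDensity = 0.0334)
    est[i] <- siteTable(ss)$S_orient[1]
    the[i] <- min(0, kB * (vmfEntropy(kappas[i]) - log(4 * pi)))
  }
  expect_true(all(diff(est) < 0)) # higher concentration = more negative
  expect_gt(est[1], -0.15 * kB)  # uniform orientations are bulk-like
  expect_equal(est[2:3], the[2:3], tolerance = 0.08)
})

test_that("entropy estimates converge toward the closed form with more frames", {
  rho <- 0.0334; sdv <- 0.25
  theory <- kB * (gaussianEntropy3D(sdv) + log(rho))
  errs <- sapply(1:20, function(s) {
    sapply(c(150, 600), function(n) {
      tr <- gaussianSiteTrajectory(nFrames = n, sd = sdv, kappa = 0,
                                   seed = 100 + s)
      abs(siteTable(siteEntropy(clusterSites(tr), tr, rho))$S_trans[1] - theory)
    })
  })
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
})

test_that("identical networks compare to zero with no displaced sites", {
  A <- siteSetFromTable(rbind(siteRow(1L, 0, 0, 0, Eww = -2, Esw = -1, mTdS = 1),
                              siteRow(2L, 3, 0, 0, Eww = -1.5, Esw = -0.5, mTdS = 0.7)))
  cmp <- compareNetworks(A, A)
  expect_equal(nrow(cmp@matches), 2)
  expect_length(cmp@displacedA, 0)
  expect_equal(unname(cmp@totals), rep(0, 4))
})

test_that("a missing site is flagged displaced and totals stay additive", {
  A <- siteSetFromTable(rbind(siteRow(1L, 0, 0, 0, Eww = -2, Esw = -1, mTdS = 1),
                              siteRow(2L, 3, 0, 0, Eww = -1.5, Esw = 0.5, mTdS = 0.7),
                              siteRow(3L, -3, 1, 0, Eww = -1, Esw = -0.2, mTdS = 0.4)))
  B <- siteSetFromTable(rbind(siteRow(1L, 0.2, 0, 0, Eww = -2.5, Esw = -0.8, mTdS = 1.4),
                              siteRow(2L, 3.1, 0.1, 0, Eww = -1.2, Esw = 0.3, mTdS = 0.6)))
  cmp <- compareNetworks(A, B, matchRadius = 1.5)
  expect_equal(cmp@displacedA, 3L)
  expect_length(cmp@onlyB, 0)
  dEww <- sum(cmp@matches$dEww) - (-1)
  dEpw <- sum(cmp@matches$dEsw) - (-0.2)
  expect_equal(cmp@totals[["dEww"]], dEww, tolerance = 1e-12)
  expect_equal(cmp@totals[["dEpw"]], dEpw, tolerance = 1e-12)
  expect_equal(cmp@totals[["dEtotal"]], dEww + dEpw, tolerance = 1e-12)
})

test_that("planted-network comparison flags the removed site", {
  netA <- generateWaterNetwork(plantedSixSiteNetwork(seed = 7, nFrames = 400))
  planted <- attr(netA, "planted")
  specB <- plantedNetworkSpec(planted[-3, ], bulkDensity = 0.005,
                              regionRadius = 8, nFrames = 400, seed = 8)
  netB <- generateWaterNetwork(specB)
  sA <- clusterSites(netA); sB <- clusterSites(netB)
  cmp <- compareNetworks(sA, sB, matchRadius = 1.5)
  expect_length(cmp@displacedA, 1)
  disp <- siteTable(sA)[siteTable(sA)$siteId == cmp@displacedA, ]
  dPlanted <- sqrt((disp$x - planted$x[3])^2 + (disp$y - planted$y[3])^2 +
                   (disp$z - planted$z[3])^2)
  expect_lt(dPlanted, 0.5)
})
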