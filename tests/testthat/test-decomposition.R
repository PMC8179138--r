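# Ligand/surroundings enthalpy decomposition and profile assembly.

test_that("component aggregation reproduces the worked binding-enthalpy numbers", {
  comp <- ligandEnergyComponents(-3.6, -1.7, 1.0, 6.5)
  expect_equal(comp@desolvation, -5.5, tolerance = 1e-9)
  expect_equal(comp@ddUL, -10.8, tolerance = 1e-9)
})

test_that("surroundings energy is the enthalpy/ligand difference with quadrature errors", {
  d1 <- surroundingsEnergy(-11.6, -10.8, semDdH = 0.1, semDdUL = 0.8)
  expect_equal(d1@ddUS, -0.8, tolerance = 1e-9)
  expect_equal(d1@sems[["ddUS"]], sqrt(0.1^2 + 0.8^2), tolerance = 1e-12)
  expect_equal(surroundingsEnergy(-10.3, 4.3)@ddUS, -14.6, tolerance = 1e-9)
  expect_equal(surroundingsEnergy(0, 0)@ddUS, 0)
  expect_error(surroundingsEnergy(NA_real_, 1), "finite")
})

test_that("identical end-state tables give all-zero components", {
  tab <- data.frame(frame = 1:50, receptor_ligand = rnorm(50),
                    ligand_internal = rnorm(50), ligand_water = rnorm(50))
  comp <- ligandComponents(tab, tab, tab, tab)
  expect_equal(comp@receptorLigand, 0)
  expect_equal(comp@ligandInternal, 0)
  expect_equal(comp@desolvation, 0)
  expect_equal(comp@ddUL, 0)
})

test_that("missing tag categories are rejected by name", {
  tab <- data.frame(frame = 1:20, receptor_ligand = 0, ligand_internal = 0,
                    ligand_water = 0)
  expect_error(ligandComponents(tab[, -2], tab, tab, tab), "receptor_ligand")
  expect_error(ligandComponents(tab, tab, tab[, c("frame", "ligand_internal")], tab),
               "ligand_water")
})

test_that("host-guest components equal direct averages of the tagged energy tables", {
  spec <- hostGuestBenchmark(nWater = 8L)
  usp <- unboundSpec(spec)
  bA <- sampleEndState(spec, "A", nSteps = 1500, seed = 41)$energies
  bB <- sampleEndState(spec, "B", nSteps = 1500, seed = 42)$energies
  uA <- sampleEndState(usp, "A", nSteps = 1500, seed = 43)$energies
  uB <- sampleEndState(usp, "B", nSteps = 1500, seed = 44)$energies
  comp <- ligandComponents(bA, bB, uA, uB)
  # independent arithmetic on the raw tables
  expect_equal(comp@receptorLigand,
               mean(bB$receptor_ligand) - mean(bA$receptor_ligand),
               tolerance = 1e-12)
  expect_equal(comp@ligandInternal,
               (mean(bB$ligand_internal) - mean(bA$ligand_internal)) -
                 (mean(uB$ligand_internal) - mean(uA$ligand_internal)),
               tolerance = 1e-12)
  expect_equal(comp@desolvation,
               (mean(bB$ligand_water) - mean(bA$ligand_water)) -
                 (mean(uB$ligand_water) - mean(uA$ligand_water)),
               tolerance = 1e-12)
  # bookkeeping identities hold exactly
  expect_equal(comp@ddUL,
               comp@receptorLigand + comp@ligandInternal + comp@desolvation,
               tolerance = 1e-9)
})

test_that("profile assembly flags additivity discrepancies beyond the combined error", {
  ok <- assembleProfile(-6.8, -11.6, 4.8)
  expect_false(ok@flag)
  expect_equal(ok@discrepancy, 0, tolerance = 1e-12)
  bad <- assembleProfile(-6.7, -11.6, 4.8)
  expect_true(bad@flag)
  expect_equal(bad@discrepancy, 0.1, tolerance = 1e-9)
  # within the stated uncertainty the same gap is tolerated
  tol <- assembleProfile(-6.7, -11.6, 4.8, semDdG = 0.2)
  expect_false(tol@flag)
})

test_that("the analytic harmonic profile is pure entropy", {
  temps <- vantHoffTemperatures()
  tab <- data.frame(temperature = temps, replicate = 1L,
                    dG = kB * temps / 2 * log(2))
  prof <- fitVantHoff(tab, Tref = 300)
  ddg <- kB * 300 / 2 * log(2)
  tp <- assembleProfile(ddg, prof)
  expect_false(tp@flag)
  expect_equal(tp@minusTddS, ddg, tolerance = 1e-9)
  expect_equal(tp@ddH, 0, tolerance = 1e-9)
})

test_that("temperature mismatches between free energy and profile are an error", {
  tab <- generateVantHoffTable(syntheticVantHoffSpec(seed = 1))
  prof <- fitVantHoff(tab, Tref = 310)
  expect_error(assembleProfile(-6.8, prof, temperature = 300),
               "temperature mismatch")
})
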