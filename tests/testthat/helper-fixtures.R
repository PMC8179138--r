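# Shared fixture builders; everything is generated in code at test time.

kB <- kBoltzmann()

# trajectory with the same waters (fixed positions/orientations) every frame
fixedWaterTrajectory <- function(waterPos, orient, nFrames = 30,
                                 solute = matrix(0, 0, 3), regionRadius = 10) {
  frames <- replicate(nFrames, list(solute = solute, water = waterPos,
                                    orient = orient), simplify = FALSE)
  trajectory(frames, regionRadius = regionRadius)
}

# one water per frame, uniform in a ball of radius a (bulk-like site when
# bulkDensity = 3 / (4 pi a^3)), orientations uniform on the sphere
bulkLikeSiteTrajectory <- function(nFrames, a, seed) {
  set.seed(seed)
  frames <- lapply(seq_len(nFrames), function(f) {
    repeat {
      p <- runif(3, -a, a)
      if (sum(p^2) <= a^2) break
    }
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    list(solute = matrix(0, 0, 3), water = matrix(p, 1, 3),
         orient = matrix(u, 1, 3))
  })
  trajectory(frames, regionRadius = a + 1e-6)
}

# one water per frame at a Gaussian-spread site with vMF orientations
gaussianSiteTrajectory <- function(nFrames, sd, kappa, seed, R = 6) {
  spec <- plantedNetworkSpec(
    data.frame(x = 0, y = 0, z = 0, positionalSD = sd,
               orientationalConcentration = kappa, occupancyProb = 1),
    bulkDensity = 0, regionRadius = R, nFrames = nFrames, seed = seed)
  generateWaterNetwork(spec)
}

# a bare HydrationSiteSet with given site table (for comparison tests)
siteSetFromTable <- function(sites, nFrames = 100L) {
  members <- data.frame(site = sites$siteId, frame = 1L,
                        water = seq_len(nrow(sites)),
                        x = sites$x, y = sites$y, z = sites$z)
  new("HydrationSiteSet", sites = sites, members = members,
      siteRadius = 1.0, nFrames = nFrames, regionCenter = c(0, 0, 0),
      regionRadius = 10, temperature = 300)
}

siteRow <- function(id, x, y, z, occ = 1, Eww = 0, Esw = 0, mTdS = 0) {
  data.frame(siteId = id, x = x, y = y, z = z, occupancy = occ, nClaimed = 1L,
             E_ww = Eww, E_sw = Esw, S_trans = 0, S_orient = 0, minusTdS = mTdS)
}

# small FreeEnergyResult without sampling
feResult <- function(dG, label, sem = 0, temperature = 300) {
  accumulateLeg(dG, label, temperature = temperature)
}

# numerical-quadrature free energy for a 1D harmonic mutation (independent
# oracle for the closed form): F = -kT log Z with Z = int exp(-U/kT) dx
quadHarmonicDF <- function(kA, kBconst, temperature) {
  kT <- kB * temperature
  z <- function(k) integrate(function(x) exp(-0.5 * k * x^2 / kT),
                             -Inf, Inf, rel.tol = 1e-12)$value
  -kT * (log(z(kBconst)) - log(z(kA)))
}

# differential entropy (nats) of an isotropic 3D Gaussian with sd sigma
gaussianEntropy3D <- function(sigma) 1.5 * log(2 * pi * exp(1) * sigma^2)

# differential entropy (nats) of a von Mises-Fisher distribution on S^2
vmfEntropy <- function(kappa) {
  if (kappa < 1e-12) return(log(4 * pi))
  log(4 * pi * sinh(kappa) / kappa) - kappa * (1 / tanh(kappa) - 1 / kappa)
}
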