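# Synthetic water networks with planted hydration sites: trajectories whose
# site centers, occupancies, positional spread and orientational order are
# known exactly, used to validate the clustering and entropy estimators.

#' Create a planted hydration-network specification
#'
#' @param sites data.frame with columns x, y, z (site centers, Angstrom),
#'   positionalSD (Gaussian spread, Angstrom), orientationalConcentration
#'   (von Mises-Fisher kappa; 0 = uniform orientations), occupancyProb
#'   (per-frame Bernoulli occupancy) and optionally ux, uy, uz (mean
#'   orientation; defaults to the outward radial direction).
#' @param bulkDensity uniform background waters per cubic Angstrom.
#' @param regionRadius radius of the spherical region (Angstrom), centered
#'   at the origin.
#' @param nFrames number of frames.
#' @param seed mandatory RNG seed.
#' @param temperature K.
#' @return A [PlantedNetworkSpec-class].
#' @seealso [plantedSixSiteNetwork()], [generateWaterNetwork()]
#' @export
plantedNetworkSpec <- function(sites, bulkDensity = 0.005, regionRadius = 8,
                               nFrames = 2000L, seed, temperature = 300) {
  .stopIfNot(!missing(seed), "seed is mandatory")
  if (is.null(sites$ux)) {
    r <- sqrt(sites$x^2 + sites$y^2 + sites$z^2)
    sites$ux <- ifelse(r > 0, sites$x / r, 0)
    sites$uy <- ifelse(r > 0, sites$y / r, 0)
    sites$uz <- ifelse(r > 0, sites$z / r, 1)
  }
  if (nrow(sites) > 1) {
    d <- as.matrix(stats::dist(sites[, c("x", "y", "z")]))
    diag(d) <- Inf
    if (min(d) < 2)
      warning("site centers closer than 2 A; downstream clustering at the ",
              "default 1 A radius may merge them")
  }
  new("PlantedNetworkSpec", sites = sites, bulkDensity = bulkDensity,
      regionRadius = regionRadius, nFrames = as.integer(nFrames),
      seed = as.integer(seed), temperature = temperature)
}

#' A six-site planted network
#'
#' Six well-separated hydration sites inside an 8 Angstrom sphere --- a
#' miniature of the ordered water network a purine-like ligand faces in a
#' binding pocket.  One site is occupied in every frame, one in 78% of
#' frames, the rest in between.
#'
#' @param seed mandatory RNG seed.
#' @param nFrames number of frames.
#' @param bulkDensity background water density (waters/A^3).
#' @return A [PlantedNetworkSpec-class].
#' @export
plantedSixSiteNetwork <- function(seed, nFrames = 2000L, bulkDensity = 0.005) {
  sites <- data.frame(
    x = c(0, 3.0, -3.0, 0.0, 2.2, -2.2),
    y = c(0, 0.5, 0.5, 3.2, -2.6, -2.6),
    z = c(0, 2.2, 2.2, -1.5, 1.8, -1.8),
    positionalSD = c(0.22, 0.25, 0.25, 0.3, 0.25, 0.28),
    orientationalConcentration = c(12, 8, 8, 4, 6, 5),
    occupancyProb = c(1.0, 0.95, 0.9, 0.85, 0.78, 0.88))
  plantedNetworkSpec(sites, bulkDensity = bulkDensity, nFrames = nFrames,
                     seed = seed)
}

# von Mises-Fisher sampler on the unit sphere (mean direction m, kappa >= 0)
.rvmf <- function(n, m, kappa) {
  if (kappa < 1e-12) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    return(u / sqrt(rowSums(u^2)))
  }
  u <- runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  v <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  local <- cbind(s * cos(v), s * sin(v), w)
  # rotate +z onto m
  m <- m / sqrt(sum(m^2))
  if (abs(m[3] - 1) < 1e-12) return(local)
  if (abs(m[3] + 1) < 1e-12) return(local %*% diag(c(1, -1, -1)))
  a <- c(-m[2], m[1], 0); a <- a / sqrt(sum(a^2)) # axis = z x m
  ang <- acos(m[3])
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  local %*% t(R)
}

# uniform points in a sphere of radius R
.runifSphere <- function(n, R) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  u * (R * runif(n)^(1 / 3))
}

#' Generate a water-network trajectory with planted hydration sites
#'
#' Per frame, each planted site is occupied with its occupancy probability by
#' a water at the site center plus isotropic Gaussian noise (resampled until
#' inside the region), with orientation drawn from a von Mises-Fisher
#' distribution of the site's concentration about its mean direction.  A
#' uniform bulk background of `round(bulkDensity * volume)` waters with
#' uniform orientations is added.  Deterministic given the spec's seed.
#'
#' @param spec a [PlantedNetworkSpec-class].
#' @return A [Trajectory-class]; the attribute `planted` carries the ground
#'   truth site table.
#' @export
generateWaterNetwork <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  R <- spec@regionRadius
  nBulk <- round(spec@bulkDensity * 4 / 3 * pi * R^3)
  s <- spec@sites
  ns <- nrow(s)
  frames <- vector("list", spec@nFrames)
  for (f in seq_len(spec@nFrames)) {
    occ <- runif(ns) < s$occupancyProb
    pos <- matrix(0, 0, 3); ori <- matrix(0, 0, 3)
    for (k in which(occ)) {
      repeat {
        p <- c(s$x[k], s$y[k], s$z[k]) + rnorm(3, 0, s$positionalSD[k])
        if (sum(p^2) <= R^2) break
      }
      pos <- rbind(pos, p)
      ori <- rbind(ori, .rvmf(1, c(s$ux[k], s$uy[k], s$uz[k]),
                              s$orientationalConcentration[k]))
    }
    if (nBulk > 0) {
      pos <- rbind(pos, .runifSphere(nBulk, R))
      ori <- rbind(ori, .rvmf(nBulk, c(0, 0, 1), 0))
    }
    rownames(pos) <- rownames(ori) <- NULL
    frames[[f]] <- list(solute = matrix(0, 0, 3), water = pos, orient = ori)
  }
  traj <- new("Trajectory", frames = frames, regionCenter = c(0, 0, 0),
              regionRadius = R, temperature = spec@temperature)
  attr(traj, "planted") <- s
  traj
}
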