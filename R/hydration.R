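# Hydration-site analysis: clustering of water positions across frames,
# per-site occupancy, interaction energies, nearest-neighbour entropies and
# cross-complex network comparison.

.EULER_GAMMA <- 0.5772156649015329

#' Build a trajectory object
#'
#' @param frames list of frames; each a list with `solute` (n x 3 matrix,
#'   possibly 0-row), `water` (m x 3) and `orient` (m x 3 unit vectors).
#' @param regionCenter,regionRadius spherical region (Angstrom).
#' @param temperature K.
#' @return A [Trajectory-class].
#' @export
trajectory <- function(frames, regionCenter = c(0, 0, 0), regionRadius,
                       temperature = 300) {
  new("Trajectory", frames = frames, regionCenter = regionCenter,
      regionRadius = regionRadius, temperature = temperature)
}

#' Number of frames in a trajectory
#' @param traj a [Trajectory-class].
#' @return integer frame count.
#' @export
nFrames <- function(traj) length(traj@frames)

#' Cluster water observations into hydration sites
#'
#' Greedy density clustering across all frames: the position whose
#' `siteRadius` neighbourhood contains the most water observations becomes a
#' site center, its observations are claimed and removed, and the procedure
#' repeats until the best remaining candidate's occupancy (distinct frames
#' claimed / total frames) falls below `minOccupancy`.  Count ties are broken
#' deterministically in favour of the lexicographically smallest (x, y, z)
#' observation, so the recovered site centers are invariant to permuting the
#' frames.
#'
#' @param traj a [Trajectory-class] (at least 100 frames recommended; fewer
#'   raises a warning).
#' @param siteRadius site radius (Angstrom), default 1.0.
#' @param minOccupancy minimum site occupancy, default 0.5.
#' @return A [HydrationSiteSet-class] with geometry and occupancy filled;
#'   energies and entropies are NA until [siteEnergies()] and
#'   [siteEntropy()] are applied.
#' @export
clusterSites <- function(traj, siteRadius = 1.0, minOccupancy = 0.5) {
  nf <- length(traj@frames)
  if (nf < 100) warning("fewer than 100 frames; occupancies will be noisy")
  nw <- vapply(traj@frames, function(f) nrow(f$water), integer(1))
  if (sum(nw) == 0) stop("empty trajectory: no water observations")
  pts <- do.call(rbind, lapply(traj@frames, `[[`, "water"))
  frameId <- rep.int(seq_len(nf), nw)
  waterId <- unlist(lapply(nw, seq_len), use.names = FALSE)
  res <- greedy_cluster_cpp(pts, frameId - 1L, nf, siteRadius, minOccupancy)
  ns <- length(res$x)
  sites <- data.frame(siteId = seq_len(ns), x = res$x, y = res$y, z = res$z,
                      occupancy = res$occupancy, nClaimed = res$n_claimed,
                      E_ww = NA_real_, E_sw = NA_real_, S_trans = NA_real_,
                      S_orient = NA_real_, minusTdS = NA_real_)
  keep <- res$assignment > 0
  members <- data.frame(site = res$assignment[keep], frame = frameId[keep],
                        water = waterId[keep], x = pts[keep, 1],
                        y = pts[keep, 2], z = pts[keep, 3])
  # at most one observation per (site, frame): keep the nearest to the center
  if (nrow(members)) {
    d2 <- (members$x - sites$x[members$site])^2 +
      (members$y - sites$y[members$site])^2 +
      (members$z - sites$z[members$site])^2
    members <- members[order(members$site, members$frame, d2), ]
    dup <- duplicated(members[, c("site", "frame")])
    members <- members[!dup, ]
  }
  new("HydrationSiteSet", sites = sites, members = members,
      siteRadius = siteRadius, nFrames = as.integer(nf),
      regionCenter = traj@regionCenter, regionRadius = traj@regionRadius,
      temperature = traj@temperature)
}

#' Lennard-Jones plus dipole pair potential pair
#'
#' The default water-water and solute-water pair potentials used by
#' [siteEnergies()], matching the pseudo-water Hamiltonian of the synthetic
#' systems: \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] - \mu_1\mu_2
#' \cos\theta / r^3}, where \eqn{\cos\theta} is the dipole-dipole alignment
#' for water pairs and the alignment of the water dipole with the
#' solute-to-water axis for solute pairs.
#'
#' @param eps,sig water LJ parameters (kcal/mol, Angstrom).
#' @param mu water dipole strength.
#' @param soluteEps,soluteSig,soluteMu solute parameters.
#' @return list of two functions: `ww(r, cosUU)` and `sw(r, cosUR)`.
#' @export
waterPairPotential <- function(eps = 0.15, sig = 2.8, mu = 2.0,
                               soluteEps = 0.25, soluteSig = 3.0,
                               soluteMu = 1.5) {
  lj <- function(e, s, r) { s6 <- (s / r)^6; 4 * e * (s6 * s6 - s6) }
  list(
    ww = function(r, cosUU) lj(eps, sig, r) - mu^2 * cosUU / r^3,
    sw = function(r, cosUR) lj(sqrt(eps * soluteEps), (sig + soluteSig) / 2, r) -
      mu * soluteMu * cosUR / r^3)
}

# site water row index within a frame, or NA
.siteWaterInFrame <- function(members, siteId) {
  m <- members[members$site == siteId, ]
  m[order(m$frame), ]
}

#' Per-site interaction energies
#'
#' For every site, averages over its occupied frames the site water's total
#' pair energy with all other waters (`E_ww`) and with all solute particles
#' (`E_sw`).  The full pair energy is assigned to the site water (no 1/2
#' factor); conventions differ between published implementations, so this
#' choice is stated explicitly.
#'
#' @param sset a [HydrationSiteSet-class] from [clusterSites()].
#' @param traj the same [Trajectory-class] the sites were clustered from.
#' @param pairPotential list with functions `ww(r, cosUU)` and
#'   `sw(r, cosUR)`; see [waterPairPotential()].
#' @return The site set with `E_ww` and `E_sw` columns filled.
#' @export
siteEnergies <- function(sset, traj, pairPotential = waterPairPotential()) {
  sites <- sset@sites
  for (si in sites$siteId) {
    mem <- .siteWaterInFrame(sset@members, si)
    if (nrow(mem) == 0) stop(sprintf("site %d is never occupied", si))
    eww <- esw <- numeric(nrow(mem))
    for (k in seq_len(nrow(mem))) {
      fr <- traj@frames[[mem$frame[k]]]
      w <- mem$water[k]
      p <- fr$water[w, ]; u <- fr$orient[w, ]
      others <- setdiff(seq_len(nrow(fr$water)), w)
      if (length(others)) {
        dv <- fr$water[others, , drop = FALSE] -
          matrix(p, length(others), 3, byrow = TRUE)
        r <- sqrt(rowSums(dv^2))
        cosUU <- as.numeric(fr$orient[others, , drop = FALSE] %*% u)
        eww[k] <- sum(pairPotential$ww(r, cosUU))
      }
      if (nrow(fr$solute)) {
        dv <- matrix(p, nrow(fr$solute), 3, byrow = TRUE) - fr$solute
        r <- sqrt(rowSums(dv^2))
        cosUR <- as.numeric((dv / r) %*% u)
        esw[k] <- sum(pairPotential$sw(r, cosUR))
      }
    }
    sites$E_ww[sites$siteId == si] <- mean(eww)
    sites$E_sw[sites$siteId == si] <- mean(esw)
  }
  sset@sites <- sites
  sset
}

# k = 1 nearest-neighbour (Kozachenko-Leonenko) differential entropy with the
# Euler-gamma log-correction, in nats
.nnEntropy <- function(dists, dim, logVolUnitBall) {
  d <- dists[dists > 0] # coincident samples carry no log-distance information
  .EULER_GAMMA + digamma(length(dists)) + logVolUnitBall + dim * mean(log(d))
}

#' Per-site translational and orientational entropies
#'
#' Nearest-neighbour entropy estimation relative to bulk.  Translational:
#' the k = 1 Kozachenko-Leonenko estimator (with the Euler-gamma
#' log-correction) applied to the site water's positions across occupied
#' frames, referenced to a uniform fluid at `bulkDensity` --- a site
#' water whose positional distribution is exactly bulk-like scores zero.
#' Orientational: the same estimator on the unit sphere using geodesic
#' nearest-neighbour angles, referenced to the uniform orientation
#' distribution (entropy \eqn{\ln 4\pi}).  Both are reported as entropies
#' relative to bulk, clamped at zero from above (ordering can only lower the
#' entropy), together with \eqn{-T\Delta S} at the trajectory temperature.
#'
#' @param sset a [HydrationSiteSet-class] from [clusterSites()].
#' @param traj the trajectory the sites came from.
#' @param bulkDensity bulk water density (waters/A^3) used as the
#'   translational reference.
#' @param minOccupied minimum occupied frames before a warning (default 20).
#' @return The site set with `S_trans`, `S_orient` (kcal/(mol K)) and
#'   `minusTdS` (kcal/mol) filled.
#' @export
siteEntropy <- function(sset, traj, bulkDensity, minOccupied = 20L) {
  sites <- sset@sites
  for (si in sites$siteId) {
    mem <- .siteWaterInFrame(sset@members, si)
    n <- nrow(mem)
    if (n == 0) stop(sprintf("site %d is never occupied", si))
    if (n < minOccupied)
      warning(sprintf("site %d has only %d occupied frames; entropies unreliable", si, n))
    pos <- as.matrix(mem[, c("x", "y", "z")])
    hTrans <- .nnEntropy(nn_dist_cpp(pos), 3, log(4 * pi / 3))
    sTrans <- min(0, .kB * (hTrans + log(bulkDensity)))
    u <- t(vapply(seq_len(n), function(k)
      traj@frames[[mem$frame[k]]]$orient[mem$water[k], ], numeric(3)))
    hOrient <- .nnEntropy(nn_angle_cpp(u), 2, log(pi))
    sOrient <- min(0, .kB * (hOrient - log(4 * pi)))
    i <- sites$siteId == si
    sites$S_trans[i] <- sTrans
    sites$S_orient[i] <- sOrient
    sites$minusTdS[i] <- -sset@temperature * (sTrans + sOrient)
  }
  sset@sites <- sites
  sset
}

#' Compare two hydration-site networks
#'
#' Greedy one-to-one matching of site centers (closest pair first, within
#' `matchRadius`); sites of the reference network A with no partner in B are
#' flagged displaced.  Per matched site and in total, reports B-minus-A
#' differences of water-water energy, solute-water energy and
#' \eqn{-T\Delta S}; displaced sites contribute the loss of their reference
#' values to the totals and B-only sites their full values.
#'
#' @param sitesA reference [HydrationSiteSet-class].
#' @param sitesB comparison [HydrationSiteSet-class] over the same region.
#' @param matchRadius maximum center-center distance for a match (Angstrom),
#'   default 1.5.
#' @return A [NetworkComparison-class].
#' @export
compareNetworks <- function(sitesA, sitesB, matchRadius = 1.5) {
  A <- sitesA@sites; B <- sitesB@sites
  matches <- data.frame(idA = integer(), idB = integer(), dist = numeric(),
                        dEww = numeric(), dEsw = numeric(), dEsurr = numeric(),
                        dMinusTdS = numeric())
  freeA <- A$siteId; freeB <- B$siteId
  if (nrow(A) && nrow(B)) {
    d <- outer(seq_len(nrow(A)), seq_len(nrow(B)), Vectorize(function(i, j)
      sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 + (A$z[i] - B$z[j])^2)))
    repeat {
      if (!length(freeA) || !length(freeB)) break
      sub <- d[match(freeA, A$siteId), match(freeB, B$siteId), drop = FALSE]
      if (min(sub) > matchRadius) break
      ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      ia <- freeA[ij[1]]; ib <- freeB[ij[2]]
      ra <- A[A$siteId == ia, ]; rb <- B[B$siteId == ib, ]
      matches <- rbind(matches, data.frame(
        idA = ia, idB = ib, dist = min(sub),
        dEww = rb$E_ww - ra$E_ww, dEsw = rb$E_sw - ra$E_sw,
        dEsurr = (rb$E_ww + rb$E_sw) - (ra$E_ww + ra$E_sw),
        dMinusTdS = rb$minusTdS - ra$minusTdS))
      freeA <- setdiff(freeA, ia); freeB <- setdiff(freeB, ib)
    }
  }
  sumOr0 <- function(x) if (length(x)) sum(x) else 0
  dispA <- A[A$siteId %in% freeA, ]; newB <- B[B$siteId %in% freeB, ]
  dEww <- sumOr0(matches$dEww) - sumOr0(dispA$E_ww) + sumOr0(newB$E_ww)
  dEpw <- sumOr0(matches$dEsw) - sumOr0(dispA$E_sw) + sumOr0(newB$E_sw)
  dTS <- sumOr0(matches$dMinusTdS) - sumOr0(dispA$minusTdS) + sumOr0(newB$minusTdS)
  new("NetworkComparison", matches = matches,
      displacedA = as.integer(freeA), onlyB = as.integer(freeB),
      totals = c(dEww = dEww, dEpw = dEpw, dEtotal = dEww + dEpw,
                 dMinusTdS = dTS))
}
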