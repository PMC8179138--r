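# Host-guest toy system with orientable pseudo-waters: the benchmark for the
# enthalpy decomposition and end-to-end conservation checks.

#' Create a host-guest system specification
#'
#' @param host data.frame with columns x, y, z, eps, sig, mu (fixed
#'   particles).  `mu` is a scalar dipole strength coupling to the water
#'   orientation along the solute-water axis.
#' @param guest data.frame with columns x, y, z, eps, sig, mu; the mobile
#'   guest in end state A.
#' @param guestB data.frame with columns eps, sig, mu giving the end state B
#'   parameters (defaults to state A: no alchemical change).
#' @param bonds data.frame with columns i, j (1-based guest indices), kA,
#'   r0A, kB, r0B; harmonic bonds between guest particles.
#' @param nWater number of pseudo-waters.
#' @param waterEps,waterSig,waterMu pseudo-water Lennard-Jones well depth
#'   (kcal/mol), diameter (Angstrom) and dipole strength.
#' @param sphereRadius confining sphere radius (Angstrom).
#' @param restraintConstant harmonic positional restraint on the guest to its
#'   initial coordinates, kcal/(mol A^2); 0 disables it.
#' @param temperature K.
#' @return A [HostGuestSpec-class].
#' @seealso [hostGuestBenchmark()] for a ready-made benchmark system.
#' @export
hostGuestSpec <- function(host, guest, guestB = NULL, bonds = NULL,
                          nWater = 12L, waterEps = 0.15, waterSig = 2.8,
                          waterMu = 2.0, sphereRadius = 7, restraintConstant = 0,
                          temperature = 300) {
  if (is.null(guestB)) guestB <- guest[, c("eps", "sig", "mu"), drop = FALSE]
  if (is.null(bonds))
    bonds <- data.frame(i = integer(), j = integer(), kA = numeric(),
                        r0A = numeric(), kB = numeric(), r0B = numeric())
  new("HostGuestSpec", host = host, guest = guest,
      guestB = guestB[, c("eps", "sig", "mu"), drop = FALSE], bonds = bonds,
      nWater = as.integer(nWater), waterEps = waterEps, waterSig = waterSig,
      waterMu = waterMu, sphereRadius = sphereRadius,
      restraintConstant = restraintConstant, temperature = temperature)
}

#' Standard host-guest benchmark system
#'
#' A small binding-pocket model: four fixed host particles around the origin,
#' a two-particle bonded guest inside the pocket, and a dozen orientable
#' pseudo-waters in a 7 Angstrom sphere.  The A-to-B transformation deepens
#' the guest's dispersion well, strengthens its dipole and stretches its bond
#' --- a caricature of a substituent change that shifts receptor-ligand,
#' ligand-water and strain energies at once.
#'
#' The bound-leg guest is held in the pocket by a soft positional restraint
#' (10 kcal/(mol A^2) by default), the analogue of restraining heavy atoms to
#' crystal coordinates; the restraint is independent of the coupling
#' parameter, so it cancels exactly in every perturbation energy.
#'
#' @param nWater number of pseudo-waters.
#' @param restraintConstant positional restraint on the guest (kcal/(mol A^2)).
#' @param temperature K.
#' @return A [HostGuestSpec-class].
#' @export
hostGuestBenchmark <- function(nWater = 12L, restraintConstant = 10,
                               temperature = 300) {
  a <- 3.4
  host <- data.frame(
    x = c(a, -a, 0, 0), y = c(0, 0, a, -a), z = c(-1.2, -1.2, -1.2, -1.2),
    eps = 0.25, sig = 3.0, mu = c(1.5, 0, 1.5, 0))
  guest <- data.frame(
    x = c(0, 0), y = c(0, 0), z = c(-0.6, 0.6),
    eps = c(0.20, 0.20), sig = c(2.9, 2.9), mu = c(1.0, 0.5))
  guestB <- data.frame(eps = c(0.60, 0.45), sig = c(2.9, 2.9), mu = c(2.6, 1.2))
  bonds <- data.frame(i = 1L, j = 2L, kA = 40, r0A = 1.2, kB = 40, r0B = 1.45)
  hostGuestSpec(host, guest, guestB, bonds, nWater = nWater,
                sphereRadius = 7, restraintConstant = restraintConstant,
                temperature = temperature)
}

#' Unbound-leg counterpart of a host-guest specification
#'
#' Removes the host particles, leaving the guest free in solvent; used as the
#' solvent leg of the thermodynamic cycle.  The pocket restraint is dropped
#' by default (the free ligand is unrestrained in solution).
#'
#' @param spec a [HostGuestSpec-class].
#' @param keepRestraint keep the guest positional restraint (default FALSE).
#' @return A [HostGuestSpec-class] without host particles.
#' @export
unboundSpec <- function(spec, keepRestraint = FALSE) {
  spec@host <- spec@host[0, , drop = FALSE]
  if (!keepRestraint) spec@restraintConstant <- 0
  spec
}

# random waters in the sphere, rejecting core overlap with anything placed
.initWaters <- function(spec) {
  solute <- rbind(as.matrix(spec@host[, c("x", "y", "z")]),
                  as.matrix(spec@guest[, c("x", "y", "z")]))
  rmin <- 0.85 * spec@waterSig
  pos <- matrix(NA_real_, spec@nWater, 3)
  placed <- solute
  for (i in seq_len(spec@nWater)) {
    for (try in 1:2000) {
      p <- runif(3, -1, 1) * spec@sphereRadius
      if (sum(p^2) > spec@sphereRadius^2) next
      if (nrow(placed) && min(sqrt(rowSums(sweep(placed, 2, p)^2))) < rmin) next
      pos[i, ] <- p
      placed <- rbind(placed, p)
      break
    }
    if (anyNA(pos[i, ])) stop("could not place waters without overlap; ",
                              "reduce nWater or enlarge sphereRadius")
  }
  u <- matrix(rnorm(3 * spec@nWater), ncol = 3)
  list(pos = pos, u = u / sqrt(rowSums(u^2)))
}

.checkSoluteOverlap <- function(spec) {
  xyz <- rbind(as.matrix(spec@host[, c("x", "y", "z")]),
               as.matrix(spec@guest[, c("x", "y", "z")]))
  sig <- c(spec@host$sig, spec@guest$sig)
  n <- nrow(xyz)
  nh <- nrow(spec@host)
  if (n < 2) return(invisible(TRUE))
  bonded <- matrix(FALSE, n, n)
  if (nrow(spec@bonds))
    for (b in seq_len(nrow(spec@bonds))) {
      i <- nh + spec@bonds$i[b]; j <- nh + spec@bonds$j[b]
      bonded[i, j] <- bonded[j, i] <- TRUE
    }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (bonded[i, j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < 0.5 * 0.5 * (sig[i] + sig[j]))
      stop(sprintf("overlapping particle initialization: particles %d and %d at %.2f A", i, j, d))
  }
  invisible(TRUE)
}

# one window chain; returns raw C++ output
.runHG <- function(spec, lambda, nSteps, nEquil, stride, trajStride,
                   guestPos, waterPos, waterU, transStep, rotStep) {
  mc_hostguest(as.matrix(spec@host[, c("x", "y", "z")]),
               spec@host$eps, spec@host$sig, spec@host$mu,
               guestPos, as.matrix(spec@guest[, c("x", "y", "z")]),
               spec@guest$eps, spec@guest$sig, spec@guest$mu,
               spec@guestB$eps, spec@guestB$sig, spec@guestB$mu,
               cbind(as.integer(spec@bonds$i) - 1L, as.integer(spec@bonds$j) - 1L),
               spec@bonds$kA, spec@bonds$r0A, spec@bonds$kB, spec@bonds$r0B,
               waterPos, waterU, spec@waterEps, spec@waterSig, spec@waterMu,
               spec@sphereRadius, spec@restraintConstant, spec@temperature,
               lambda, as.integer(nSteps), as.integer(nEquil),
               as.integer(stride), as.integer(trajStride), transStep, rotStep)
}

# lambda-resolved total energy from a component row
.hgTotal <- function(comp, lambda) {
  comp[["hh"]] + comp[["hw"]] + comp[["ww"]] + comp[["restr"]] +
    (1 - lambda) * (comp[["gh_A"]] + comp[["gw_A"]] + comp[["gg_A"]]) +
    lambda * (comp[["gh_B"]] + comp[["gw_B"]] + comp[["gg_B"]])
}

#' @describeIn sampleAlchemicalPath Metropolis sampling of the host-guest
#'   system.  `nSteps` counts sweeps (one attempted move per mobile particle).
#'   Under linear coupling the window energy difference is
#'   \eqn{(\lambda_{i+1}-\lambda_i)(U_B^{guest} - U_A^{guest})}.
#' @param stride record every `stride`-th sweep.
#' @param transStep,rotStep translation (Angstrom) and orientation proposal
#'   widths for the host-guest sampler.
#' @export
setMethod("sampleAlchemicalPath", "HostGuestSpec",
  function(spec, ladder = lambdaLadder(11L), nSteps = 10000L,
           equilFraction = 0.1, seed, stride = 2L, transStep = 0.35,
           rotStep = 0.4, ...) {
    .stopIfNot(nSteps > 0, "nSteps must be positive")
    .stopIfNot(!missing(seed), "seed is mandatory")
    validObject(spec); validObject(ladder)
    .checkSoluteOverlap(spec)
    set.seed(as.integer(seed))
    w0 <- .initWaters(spec)
    lam <- ladder@lambdas
    nw <- length(lam) - 1
    nEquil <- floor(equilFraction * nSteps)
    guestPos <- as.matrix(spec@guest[, c("x", "y", "z")])
    waterPos <- w0$pos; waterU <- w0$u
    out <- vector("list", nw)
    acc <- numeric(nw)
    for (i in seq_len(nw)) {
      r <- .runHG(spec, lam[i], nSteps, nEquil, stride, 0L,
                  guestPos, waterPos, waterU, transStep, rotStep)
      comp <- r$components
      dU <- (lam[i + 1] - lam[i]) *
        ((comp[, "gh_B"] + comp[, "gw_B"] + comp[, "gg_B"]) -
         (comp[, "gh_A"] + comp[, "gw_A"] + comp[, "gg_A"]))
      out[[i]] <- new("PerturbationSeries", windowIndex = i, lambda = lam[i],
                      lambdaNext = lam[i + 1], deltaU = as.numeric(dU),
                      temperature = spec@temperature)
      acc[i] <- r$acceptance
      guestPos <- r$guest_final; waterPos <- r$water_final; waterU <- r$orient_final
    }
    attr(out, "acceptance") <- acc
    out
  })

#' @describeIn sampleEndState End-state sampling of the host-guest system.
#'   Energies are tagged `receptor_ligand` (guest-host), `ligand_internal`
#'   (guest-guest nonbonded + bonds), `ligand_water`, `water_water`,
#'   `host_water` and `restraint`; `total` is their sum plus the constant
#'   host-host term.
#' @param stride record energies every `stride`-th sweep.
#' @param trajStride record a trajectory frame every `trajStride`-th sweep
#'   (0 = no trajectory).
#' @param transStep,rotStep proposal widths.
#' @export
setMethod("sampleEndState", "HostGuestSpec",
  function(spec, state = c("A", "B"), nSteps = 20000L, equilFraction = 0.1,
           seed, stride = 2L, trajStride = 0L, transStep = 0.35,
           rotStep = 0.4, ...) {
    state <- match.arg(state)
    .stopIfNot(!missing(seed), "seed is mandatory")
    validObject(spec)
    .checkSoluteOverlap(spec)
    set.seed(as.integer(seed))
    w0 <- .initWaters(spec)
    lambda <- if (state == "A") 0 else 1
    nEquil <- floor(equilFraction * nSteps)
    r <- .runHG(spec, lambda, nSteps, nEquil, stride, trajStride,
                as.matrix(spec@guest[, c("x", "y", "z")]), w0$pos, w0$u,
                transStep, rotStep)
    comp <- r$components
    X <- if (state == "A") "A" else "B"
    en <- data.frame(
      frame = seq_len(nrow(comp)),
      receptor_ligand = comp[, paste0("gh_", X)],
      ligand_internal = comp[, paste0("gg_", X)],
      ligand_water = comp[, paste0("gw_", X)],
      water_water = comp[, "ww"],
      host_water = comp[, "hw"],
      restraint = comp[, "restr"])
    en$total <- comp[, "hh"] + en$receptor_ligand + en$ligand_internal +
      en$ligand_water + en$water_water + en$host_water + en$restraint
    traj <- NULL
    if (trajStride > 0 && length(r$traj_water)) {
      solute <- rbind(as.matrix(spec@host[, c("x", "y", "z")]))
      frames <- lapply(seq_along(r$traj_water), function(k)
        list(solute = rbind(solute, r$traj_guest[[k]]),
             water = r$traj_water[[k]], orient = r$traj_orient[[k]]))
      traj <- new("Trajectory", frames = frames, regionCenter = c(0, 0, 0),
                  regionRadius = spec@sphereRadius + 1e-6,
                  temperature = spec@temperature)
    }
    list(energies = en, trajectory = traj, acceptance = r$acceptance,
         components = comp)
  })

#' Brute-force energy components of a host-guest configuration
#'
#' Recomputes every pairwise term of the host-guest Hamiltonian by direct
#' O(N^2) summation in R.  Used to validate the sampler's bookkeeping: the
#' per-frame components recorded during sampling must agree with this
#' function to accumulation tolerance.
#'
#' @param spec a [HostGuestSpec-class].
#' @param guestPos guest coordinates (n x 3).
#' @param waterPos water coordinates (m x 3).
#' @param waterU water orientation unit vectors (m x 3).
#' @return Named numeric of components: hh, hw, ww, gh_A, gh_B, gw_A, gw_B,
#'   gg_A, gg_B, restr.
#' @export
hostGuestEnergy <- function(spec, guestPos, waterPos, waterU) {
  lj <- function(e, s, r2) { s6 <- (s * s / r2)^3; 4 * e * (s6 * s6 - s6) }
  swPair <- function(p, e, s, mu, w) {
    dv <- waterPos[w, ] - p
    r2 <- sum(dv^2); r <- sqrt(r2)
    val <- lj(sqrt(e * spec@waterEps), 0.5 * (s + spec@waterSig), r2)
    if (mu != 0 && spec@waterMu != 0)
      val <- val - mu * spec@waterMu * (sum(waterU[w, ] * dv) / r) / r^3
    val
  }
  host <- as.matrix(spec@host[, c("x", "y", "z")])
  nh <- nrow(host); ng <- nrow(guestPos); nw <- nrow(waterPos)
  comp <- c(hh = 0, hw = 0, ww = 0, gh_A = 0, gh_B = 0, gw_A = 0, gw_B = 0,
            gg_A = 0, gg_B = 0, restr = 0)
  if (nh > 1) for (i in 1:(nh - 1)) for (j in (i + 1):nh)
    comp["hh"] <- comp["hh"] +
      lj(sqrt(spec@host$eps[i] * spec@host$eps[j]),
         0.5 * (spec@host$sig[i] + spec@host$sig[j]),
         sum((host[i, ] - host[j, ])^2))
  if (nh && nw) for (h in 1:nh) for (w in 1:nw)
    comp["hw"] <- comp["hw"] + swPair(host[h, ], spec@host$eps[h],
                                      spec@host$sig[h], spec@host$mu[h], w)
  if (nw > 1) for (i in 1:(nw - 1)) for (j in (i + 1):nw) {
    dv <- waterPos[i, ] - waterPos[j, ]
    r2 <- sum(dv^2); r <- sqrt(r2)
    e <- lj(spec@waterEps, spec@waterSig, r2)
    if (spec@waterMu != 0)
      e <- e - spec@waterMu^2 * sum(waterU[i, ] * waterU[j, ]) / r^3
    comp["ww"] <- comp["ww"] + e
  }
  pars <- list(A = spec@guest, B = cbind(spec@guest[, c("x", "y", "z")], spec@guestB))
  bonded <- matrix(FALSE, max(ng, 1), max(ng, 1))
  if (nrow(spec@bonds))
    for (b in seq_len(nrow(spec@bonds))) {
      bonded[spec@bonds$i[b], spec@bonds$j[b]] <- TRUE
      bonded[spec@bonds$j[b], spec@bonds$i[b]] <- TRUE
    }
  for (X in c("A", "B")) {
    gp <- pars[[X]]
    for (g in seq_len(ng)) {
      if (nh) for (h in 1:nh)
        comp[paste0("gh_", X)] <- comp[paste0("gh_", X)] +
          lj(sqrt(gp$eps[g] * spec@host$eps[h]), 0.5 * (gp$sig[g] + spec@host$sig[h]),
             sum((guestPos[g, ] - host[h, ])^2))
      if (nw) for (w in 1:nw)
        comp[paste0("gw_", X)] <- comp[paste0("gw_", X)] +
          swPair(guestPos[g, ], gp$eps[g], gp$sig[g], gp$mu[g], w)
    }
    if (ng > 1) for (i in 1:(ng - 1)) for (j in (i + 1):ng) {
      if (bonded[i, j]) next
      comp[paste0("gg_", X)] <- comp[paste0("gg_", X)] +
        lj(sqrt(gp$eps[i] * gp$eps[j]), 0.5 * (gp$sig[i] + gp$sig[j]),
           sum((guestPos[i, ] - guestPos[j, ])^2))
    }
    if (nrow(spec@bonds)) for (b in seq_len(nrow(spec@bonds))) {
      rb <- sqrt(sum((guestPos[spec@bonds$i[b], ] - guestPos[spec@bonds$j[b], ])^2))
      k <- if (X == "A") spec@bonds$kA[b] else spec@bonds$kB[b]
      r0 <- if (X == "A") spec@bonds$r0A[b] else spec@bonds$r0B[b]
      comp[paste0("gg_", X)] <- comp[paste0("gg_", X)] + 0.5 * k * (rb - r0)^2
    }
  }
  if (spec@restraintConstant > 0) {
    ref <- as.matrix(spec@guest[, c("x", "y", "z")])
    comp["restr"] <- 0.5 * spec@restraintConstant * sum((guestPos - ref)^2)
  }
  comp
}
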