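# S4 containers for the free-energy, van't Hoff, decomposition and hydration
# stages, plus the specifications of the synthetic benchmark systems.

#' Ladder of alchemical coupling parameters
#'
#' An ordered set of lambda values interpolating between end state A
#' (lambda = 0) and end state B (lambda = 1).  Consecutive pairs define the
#' perturbation windows of the free energy calculation.
#'
#' @slot lambdas strictly increasing numeric vector in [0, 1], starting at 0
#'   and ending at 1.
#' @seealso [lambdaLadder()]
#' @export
setClass("LambdaLadder", representation(lambdas = "numeric"))

setValidity("LambdaLadder", function(object) {
  l <- object@lambdas
  if (length(l) < 2) return("ladder needs at least 2 lambda values")
  if (any(!is.finite(l))) return("lambdas must be finite")
  if (l[1] != 0 || l[length(l)] != 1) return("ladder must start at 0 and end at 1")
  if (any(diff(l) <= 0)) return("lambdas must be strictly increasing")
  TRUE
})

#' Per-window energy-difference time series
#'
#' Per-frame potential energy differences \eqn{\Delta U = U_{\lambda_{i+1}} -
#' U_{\lambda_i}} evaluated on configurations sampled at \eqn{\lambda_i}, the
#' raw material of the Zwanzig estimator.
#'
#' @slot windowIndex integer window number (1-based along the ladder).
#' @slot lambda coupling value the window was sampled at.
#' @slot lambdaNext coupling value of the target state.
#' @slot deltaU numeric vector of per-frame energy differences (kcal/mol).
#' @slot temperature simulation temperature (K).
#' @seealso [perturbationSeries()], [zwanzigWindow()]
#' @export
setClass("PerturbationSeries",
         representation(windowIndex = "integer", lambda = "numeric",
                        lambdaNext = "numeric", deltaU = "numeric",
                        temperature = "numeric"))

setValidity("PerturbationSeries", function(object) {
  if (length(object@deltaU) < 1) return("deltaU must be non-empty")
  if (any(!is.finite(object@deltaU))) return("deltaU contains non-finite values")
  if (object@temperature <= 0) return("temperature must be positive")
  if (object@lambda < 0 || object@lambda > 1) return("lambda outside [0,1]")
  TRUE
})

#' Free energy of one alchemical leg
#'
#' The accumulated transformation free energy of one leg (bound or unbound)
#' of the thermodynamic cycle: per-window Zwanzig estimates, their sum, and
#' replicate statistics when independent repeats are available.
#'
#' @slot legLabel "bound" or "unbound".
#' @slot windowDGs per-window free energies (kcal/mol).
#' @slot windowSEMs per-window block-averaging standard errors.
#' @slot legDG sum of window free energies (kcal/mol).
#' @slot legSEM standard error of legDG (replicate SEM when replicates are
#'   present, otherwise quadrature over window SEMs).
#' @slot replicateDGs per-replicate leg free energies (length 0 when the leg
#'   is a single run).
#' @slot temperature K.
#' @export
setClass("FreeEnergyResult",
         representation(legLabel = "character", windowDGs = "numeric",
                        windowSEMs = "numeric", legDG = "numeric",
                        legSEM = "numeric", replicateDGs = "numeric",
                        temperature = "numeric"))

setValidity("FreeEnergyResult", function(object) {
  if (!object@legLabel %in% c("bound", "unbound"))
    return("legLabel must be 'bound' or 'unbound'")
  if (abs(object@legDG - sum(object@windowDGs)) > 1e-9)
    return("legDG must equal the sum of windowDGs (tolerance 1e-9)")
  if (object@legSEM < 0) return("legSEM must be >= 0")
  TRUE
})

#' Relative binding free energy from a thermodynamic cycle
#'
#' @slot ddG bound-leg minus unbound-leg transformation free energy (kcal/mol).
#' @slot sem standard error (replicate SEM or quadrature of leg SEMs).
#' @slot bound,unbound the two [FreeEnergyResult-class] legs.
#' @slot temperature K.
#' @seealso [cycleCombine()]
#' @export
setClass("RelativeBindingFreeEnergy",
         representation(ddG = "numeric", sem = "numeric",
                        bound = "FreeEnergyResult", unbound = "FreeEnergyResult",
                        temperature = "numeric"))

setValidity("RelativeBindingFreeEnergy", function(object) {
  if (abs(object@ddG - (object@bound@legDG - object@unbound@legDG)) > 1e-9 &&
      length(object@bound@replicateDGs) == 0)
    return("ddG must equal bound - unbound leg free energy")
  TRUE
})

#' van't Hoff enthalpy/entropy profile
#'
#' Result of regressing \eqn{\Delta G/T} on \eqn{1/T}: the slope is the
#' relative enthalpy \eqn{\Delta\Delta H}, minus the intercept is the relative
#' entropy \eqn{\Delta\Delta S}.
#'
#' @slot ddH slope of the regression: relative enthalpy (kcal/mol).
#' @slot ddS minus the intercept: relative entropy (kcal/(mol K)).
#' @slot minusTddS \eqn{-T_{ref}\Delta\Delta S} at the reference temperature.
#' @slot Tref reference temperature (K).
#' @slot ciDdH,ciMinusTddS 95% confidence intervals, length-2 (lo, hi).
#' @slot seDdH,seMinusTddS OLS standard errors.
#' @slot rSquared coefficient of determination of the fit.
#' @slot nTemperatures number of distinct temperatures entering the fit.
#' @slot fit the underlying \code{lm} object.
#' @seealso [fitVantHoff()], [bootstrapProfile()]
#' @export
setClass("VantHoffProfile",
         representation(ddH = "numeric", ddS = "numeric", minusTddS = "numeric",
                        Tref = "numeric", ciDdH = "numeric", ciMinusTddS = "numeric",
                        seDdH = "numeric", seMinusTddS = "numeric",
                        rSquared = "numeric", nTemperatures = "integer",
                        fit = "ANY"))

setValidity("VantHoffProfile", function(object) {
  if (object@nTemperatures < 3) return("need >= 3 temperatures")
  if (abs(object@minusTddS - (-object@Tref * object@ddS)) > 1e-9)
    return("minusTddS must equal -Tref * ddS")
  TRUE
})

#' Ligand contributions to the relative binding enthalpy
#'
#' Components of \eqn{\Delta\Delta U_L}: receptor-ligand interaction energy,
#' ligand internal (strain) energy, and the desolvation term assembled from
#' the bound- and unbound-state ligand-water interaction energies.
#'
#' @slot receptorLigand,ligandInternal,ligandWaterBound,ligandWaterUnbound
#'   component energies (kcal/mol), each a B-minus-A difference between the
#'   two compounds.
#' @slot desolvation ligandWaterBound - ligandWaterUnbound.
#' @slot ddUL receptorLigand + ligandInternal + desolvation.
#' @slot sems named numeric vector of standard errors per component.
#' @seealso [ligandEnergyComponents()], [ligandComponents()]
#' @export
setClass("LigandEnergyComponents",
         representation(receptorLigand = "numeric", ligandInternal = "numeric",
                        ligandWaterBound = "numeric", ligandWaterUnbound = "numeric",
                        desolvation = "numeric", ddUL = "numeric", sems = "numeric"))

setValidity("LigandEnergyComponents", function(object) {
  if (abs(object@desolvation -
          (object@ligandWaterBound - object@ligandWaterUnbound)) > 1e-9)
    return("desolvation must equal ligandWaterBound - ligandWaterUnbound")
  if (abs(object@ddUL - (object@receptorLigand + object@ligandInternal +
                         object@desolvation)) > 1e-9)
    return("ddUL must equal receptorLigand + ligandInternal + desolvation")
  TRUE
})

#' Ligand/surroundings split of the relative binding enthalpy
#'
#' \eqn{\Delta\Delta U_S = \Delta\Delta H - \Delta\Delta U_L}: the
#' surroundings term is obtained indirectly because it cannot be converged
#' from direct averaging.
#'
#' @slot ddH relative binding enthalpy (kcal/mol).
#' @slot ddUL ligand contribution (kcal/mol).
#' @slot ddUS surroundings contribution, ddH - ddUL.
#' @slot sems named numeric (ddH, ddUL, ddUS); ddUS propagated in quadrature.
#' @seealso [surroundingsEnergy()]
#' @export
setClass("EnthalpyDecomposition",
         representation(ddH = "numeric", ddUL = "numeric", ddUS = "numeric",
                        sems = "numeric"))

setValidity("EnthalpyDecomposition", function(object) {
  if (abs(object@ddUS - (object@ddH - object@ddUL)) > 1e-12)
    return("ddUS must equal ddH - ddUL")
  TRUE
})

#' Assembled thermodynamic profile
#'
#' Side-by-side \eqn{\Delta\Delta G}, \eqn{\Delta\Delta H} and
#' \eqn{-T\Delta\Delta S} with an internal-consistency flag: the free energy
#' is measured independently of the enthalpy/entropy split, so their
#' additivity is a diagnostic rather than an identity.
#'
#' @slot ddG,ddH,minusTddS kcal/mol at `temperature`.
#' @slot temperature K.
#' @slot discrepancy ddG - (ddH + minusTddS).
#' @slot combinedSEM quadrature SEM used to judge the discrepancy.
#' @slot flag TRUE when |discrepancy| exceeds the combined SEM.
#' @seealso [assembleProfile()]
#' @export
setClass("ThermodynamicProfile",
         representation(ddG = "numeric", ddH = "numeric", minusTddS = "numeric",
                        temperature = "numeric", discrepancy = "numeric",
                        combinedSEM = "numeric", flag = "logical"))

#' Particle trajectory with orientable waters
#'
#' A list of frames, each holding solute coordinates and water positions plus
#' unit orientation (dipole) vectors, confined to a spherical region.
#'
#' @slot frames list; each element is a list with elements `solute` (matrix
#'   n x 3, possibly 0-row), `water` (matrix m x 3) and `orient` (matrix
#'   m x 3 of unit vectors).
#' @slot regionCenter numeric length 3 (Angstrom).
#' @slot regionRadius numeric (Angstrom).
#' @slot temperature K.
#' @export
setClass("Trajectory",
         representation(frames = "list", regionCenter = "numeric",
                        regionRadius = "numeric", temperature = "numeric"))

setValidity("Trajectory", function(object) {
  if (length(object@frames) == 0) return("trajectory has no frames")
  for (f in object@frames) {
    if (nrow(f$water) == 0) next
    nrm <- sqrt(rowSums(f$orient^2))
    if (any(abs(nrm - 1) > 1e-6)) return("orientation vectors must be unit norm (1e-6)")
    d <- sqrt(rowSums(sweep(f$water, 2, object@regionCenter)^2))
    if (any(d > object@regionRadius + 1e-6)) return("water outside region")
  }
  TRUE
})

#' Set of hydration sites from clustering a trajectory
#'
#' @slot sites data.frame with one row per site: siteId, x, y, z, occupancy,
#'   nClaimed, and (after [siteEnergies()] / [siteEntropy()]) E_ww, E_sw,
#'   S_trans, S_orient, minusTdS.
#' @slot members data.frame mapping claimed water observations to sites:
#'   site, frame, water, x, y, z.
#' @slot siteRadius clustering radius (Angstrom).
#' @slot nFrames number of trajectory frames clustered.
#' @slot regionCenter,regionRadius region the trajectory lives in.
#' @slot temperature K.
#' @seealso [clusterSites()]
#' @export
setClass("HydrationSiteSet",
         representation(sites = "data.frame", members = "data.frame",
                        siteRadius = "numeric", nFrames = "integer",
                        regionCenter = "numeric", regionRadius = "numeric",
                        temperature = "numeric"))

setValidity("HydrationSiteSet", function(object) {
  s <- object@sites
  if (nrow(s) > 0 && (any(s$occupancy < 0) || any(s$occupancy > 1)))
    return("occupancy must be in [0,1]")
  TRUE
})

#' Cross-complex hydration-network comparison
#'
#' Differences (network B minus reference network A) in per-site energetics
#' after one-to-one greedy matching of site centers, with sites present only
#' in the reference flagged as displaced.
#'
#' @slot matches data.frame: idA, idB, dist, dEww, dEsw, dEsurr, dMinusTdS.
#' @slot displacedA integer site ids present in A only.
#' @slot onlyB integer site ids present in B only.
#' @slot totals named numeric: dEww, dEpw, dEtotal, dMinusTdS (dEtotal is
#'   exactly dEww + dEpw).
#' @seealso [compareNetworks()]
#' @export
setClass("NetworkComparison",
         representation(matches = "data.frame", displacedA = "integer",
                        onlyB = "integer", totals = "numeric"))

setValidity("NetworkComparison", function(object) {
  t <- object@totals
  if (all(is.finite(t[c("dEww", "dEpw", "dEtotal")])) &&
      abs(t[["dEtotal"]] - (t[["dEww"]] + t[["dEpw"]])) > 1e-9)
    return("dEtotal must equal dEww + dEpw")
  TRUE
})

#' Experimental binding affinity record
#'
#' @slot compound label.
#' @slot Ki inhibition constant in molar units (NA when only percent
#'   inhibition was measured).
#' @slot percentInhibition percent inhibition at a fixed concentration (NA
#'   when Ki is available); carries no free energy.
#' @slot temperature assay temperature (K).
#' @slot note free-text assay note.
#' @seealso [affinityRecord()], [kiToDeltaG()]
#' @export
setClass("AffinityRecord",
         representation(compound = "character", Ki = "numeric",
                        percentInhibition = "numeric", temperature = "numeric",
                        note = "character"))

setValidity("AffinityRecord", function(object) {
  if (!is.na(object@Ki) && object@Ki <= 0) return("Ki must be positive")
  if (object@temperature <= 0) return("temperature must be positive")
  TRUE
})

# ---- synthetic system specifications ---------------------------------------

#' Harmonic-oscillator mutation specification
#'
#' Two harmonic end states \eqn{U_X(x) = k_X |x - c_X|^2 / 2} in 1 or 3
#' dimensions, connected by linear alchemical coupling.  The transformation
#' free energy is known in closed form, which makes this the primary
#' validation system for the Zwanzig/cycle stages.
#'
#' @slot dimensionality 1 or 3.
#' @slot forceConstantA,forceConstantB kcal/(mol A^2), strictly positive.
#' @slot centerA,centerB numeric of length `dimensionality` (Angstrom).
#' @slot temperature K.
#' @seealso [harmonicSpec()], [harmonicFreeEnergy()]
#' @export
setClass("HarmonicSpec",
         representation(dimensionality = "integer", forceConstantA = "numeric",
                        forceConstantB = "numeric", centerA = "numeric",
                        centerB = "numeric", temperature = "numeric"))

setValidity("HarmonicSpec", function(object) {
  if (!object@dimensionality %in% c(1L, 3L)) return("dimensionality must be 1 or 3")
  if (object@forceConstantA <= 0 || object@forceConstantB <= 0)
    return("force constants must be strictly positive")
  if (length(object@centerA) != object@dimensionality ||
      length(object@centerB) != object@dimensionality)
    return("centers must have length = dimensionality")
  if (object@temperature <= 0) return("temperature must be positive")
  TRUE
})

#' Host-guest toy system specification
#'
#' Fixed host particles, mobile guest particles (with A and B end-state
#' nonbonded/bond parameters for alchemical transformations) and orientable
#' single-site pseudo-waters, all confined to a sphere.  Pair energies are
#' Lennard-Jones plus point-dipole terms; guests may carry harmonic bonds and
#' an optional positional restraint to their initial coordinates.
#'
#' @slot host data.frame: x, y, z, eps, sig, mu (fixed particles).
#' @slot guest data.frame: x, y, z, eps, sig, mu (state A parameters).
#' @slot guestB data.frame: eps, sig, mu (state B parameters; same coords).
#' @slot bonds data.frame: i, j (1-based guest indices), kA, r0A, kB, r0B.
#' @slot nWater number of pseudo-waters.
#' @slot waterEps,waterSig,waterMu pseudo-water LJ and dipole parameters.
#' @slot sphereRadius confining sphere radius (Angstrom).
#' @slot restraintConstant kcal/(mol A^2); 0 = unrestrained guests.
#' @slot temperature K.
#' @seealso [hostGuestSpec()], [hostGuestBenchmark()]
#' @export
setClass("HostGuestSpec",
         representation(host = "data.frame", guest = "data.frame",
                        guestB = "data.frame", bonds = "data.frame",
                        nWater = "integer", waterEps = "numeric",
                        waterSig = "numeric", waterMu = "numeric",
                        sphereRadius = "numeric", restraintConstant = "numeric",
                        temperature = "numeric"))

setValidity("HostGuestSpec", function(object) {
  ok <- function(df) all(df$eps >= 0) && all(df$sig >= 0)
  if (nrow(object@host) && !ok(object@host)) return("host eps/sig must be >= 0")
  if (nrow(object@guest) && !ok(object@guest)) return("guest eps/sig must be >= 0")
  if (object@waterEps < 0 || object@waterSig < 0)
    return("water eps/sig must be >= 0")
  if (object@restraintConstant < 0) return("restraintConstant must be >= 0")
  if (object@temperature <= 0) return("temperature must be positive")
  pos <- rbind(as.matrix(object@host[, c("x", "y", "z")]),
               as.matrix(object@guest[, c("x", "y", "z")]))
  if (nrow(pos) && any(sqrt(rowSums(pos^2)) > object@sphereRadius))
    return("all particles must start within sphereRadius of the origin")
  TRUE
})

#' Planted hydration-network specification
#'
#' Defines a synthetic water trajectory with known ground truth: hydration
#' sites of given center, positional spread, orientational concentration and
#' occupancy probability, over a uniform bulk background in a sphere.
#'
#' @slot sites data.frame: x, y, z (center), positionalSD (Angstrom),
#'   orientationalConcentration (von Mises-Fisher kappa, >= 0),
#'   occupancyProb in [0, 1], and mean orientation ux, uy, uz.
#' @slot bulkDensity waters per cubic Angstrom of background.
#' @slot regionRadius sphere radius (Angstrom), centered at the origin.
#' @slot nFrames frames to generate.
#' @slot seed RNG seed (mandatory).
#' @slot temperature K (carried into the trajectory).
#' @seealso [plantedNetworkSpec()], [generateWaterNetwork()]
#' @export
setClass("PlantedNetworkSpec",
         representation(sites = "data.frame", bulkDensity = "numeric",
                        regionRadius = "numeric", nFrames = "integer",
                        seed = "integer", temperature = "numeric"))

setValidity("PlantedNetworkSpec", function(object) {
  s <- object@sites
  if (any(s$occupancyProb < 0 | s$occupancyProb > 1))
    return("occupancyProb must be in [0,1]")
  if (any(s$orientationalConcentration < 0))
    return("orientationalConcentration must be >= 0")
  if (any(sqrt(s$x^2 + s$y^2 + s$z^2) > object@regionRadius))
    return("site centers must lie within regionRadius")
  if (object@bulkDensity < 0) return("bulkDensity must be >= 0")
  if (object@nFrames < 1) return("nFrames must be >= 1")
  TRUE
})

#' Synthetic van't Hoff table specification
#'
#' Free energies on the exact line \eqn{\Delta G(T) = \Delta H - T \Delta S}
#' plus i.i.d. Gaussian noise, replicated; the ground truth for validating
#' the regression and bootstrap stages.
#'
#' @slot deltaH kcal/mol.
#' @slot deltaS kcal/(mol K).
#' @slot temperatures numeric vector of at least 3 distinct temperatures (K).
#' @slot noiseSD Gaussian noise standard deviation (kcal/mol), >= 0.
#' @slot nReplicates replicates per temperature.
#' @slot seed RNG seed (mandatory).
#' @seealso [syntheticVantHoffSpec()], [generateVantHoffTable()]
#' @export
setClass("SyntheticVantHoffSpec",
         representation(deltaH = "numeric", deltaS = "numeric",
                        temperatures = "numeric", noiseSD = "numeric",
                        nReplicates = "integer", seed = "integer"))

setValidity("SyntheticVantHoffSpec", function(object) {
  if (length(unique(object@temperatures)) < 3)
    return("need at least 3 distinct temperatures")
  if (any(object@temperatures <= 0)) return("temperatures must be positive")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (object@nReplicates < 1) return("nReplicates must be >= 1")
  TRUE
})

#' Validated pipeline run configuration
#'
#' @slot config named list of stage parameters (see [readRunConfig()]).
#' @slot path source file path ("" when built in memory).
#' @slot hash FNV-1a hash of the canonicalized configuration, embedded in
#'   every output file for provenance.
#' @seealso [readRunConfig()], [runPipeline()]
#' @export
setClass("RunConfig",
         representation(config = "list", path = "character", hash = "character"))
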