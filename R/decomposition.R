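# Ligand/surroundings decomposition of the relative binding enthalpy and
# thermodynamic profile assembly.

#' Build ligand energy components from component values
#'
#' Assembles a [LigandEnergyComponents-class] from the four measured parts,
#' enforcing the bookkeeping identities
#' \eqn{desolvation = \Delta U_{LW}^{bound} - \Delta U_{LW}^{unbound}} and
#' \eqn{\Delta\Delta U_L = \Delta U_{RL} + \Delta U_{intra} + desolvation}.
#'
#' @param receptorLigand receptor-ligand interaction energy difference
#'   (kcal/mol).
#' @param ligandInternal ligand internal (strain) energy difference.
#' @param ligandWaterBound,ligandWaterUnbound ligand-water interaction energy
#'   differences in the bound and unbound states.
#' @param sems optional named numeric of standard errors for the four parts.
#' @return A [LigandEnergyComponents-class].
#' @examples
#' # receptor-ligand -3.6, internal -1.7, ligand-water 1.0 (bound), 6.5 (unbound)
#' comp <- ligandEnergyComponents(-3.6, -1.7, 1.0, 6.5)
#' comp@desolvation # -5.5
#' comp@ddUL        # -10.8
#' @export
ligandEnergyComponents <- function(receptorLigand, ligandInternal,
                                   ligandWaterBound, ligandWaterUnbound,
                                   sems = c(receptorLigand = 0, ligandInternal = 0,
                                            ligandWaterBound = 0,
                                            ligandWaterUnbound = 0)) {
  desolv <- ligandWaterBound - ligandWaterUnbound
  ddUL <- receptorLigand + ligandInternal + desolv
  semDesolv <- sqrt(sems[["ligandWaterBound"]]^2 + sems[["ligandWaterUnbound"]]^2)
  semDdUL <- sqrt(sems[["receptorLigand"]]^2 + sems[["ligandInternal"]]^2 +
                  semDesolv^2)
  new("LigandEnergyComponents", receptorLigand = receptorLigand,
      ligandInternal = ligandInternal, ligandWaterBound = ligandWaterBound,
      ligandWaterUnbound = ligandWaterUnbound, desolvation = desolv,
      ddUL = ddUL, sems = c(sems, desolvation = unname(semDesolv),
                            ddUL = unname(semDdUL)))
}

.checkTagged <- function(tab, need, who) {
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("%s table is missing tagged energy column(s): %s", who,
                 paste(miss, collapse = ", ")))
  invisible(tab)
}

#' Ligand energy components from per-frame tagged energy tables
#'
#' Computes \eqn{\Delta\Delta U_L} between compounds A and B from mean
#' per-frame energies.  Each bound-state table must tag frames with
#' `receptor_ligand`, `ligand_internal` and `ligand_water` columns; each
#' unbound-state table with `ligand_internal` and `ligand_water`.  The
#' components are B-minus-A differences of the state averages:
#' receptor-ligand from the bound state, ligand internal as the strain
#' difference (bound minus unbound), and desolvation from the bound and
#' unbound ligand-water terms.  SEMs come from block averaging and combine
#' in quadrature.
#'
#' @param boundA,boundB,unboundA,unboundB data.frames of per-frame tagged
#'   energies (as returned by [sampleEndState()]).
#' @param nBlocks blocks for the SEM.
#' @return A [LigandEnergyComponents-class].
#' @export
ligandComponents <- function(boundA, boundB, unboundA, unboundB,
                             nBlocks = 10L) {
  .checkTagged(boundA, c("receptor_ligand", "ligand_internal", "ligand_water"), "boundA")
  .checkTagged(boundB, c("receptor_ligand", "ligand_internal", "ligand_water"), "boundB")
  .checkTagged(unboundA, c("ligand_internal", "ligand_water"), "unboundA")
  .checkTagged(unboundB, c("ligand_internal", "ligand_water"), "unboundB")
  m <- function(tab, col) mean(tab[[col]])
  s <- function(tab, col) .blockSEM(tab[[col]], nBlocks)
  d <- function(col, A, B) m(B, col) - m(A, col)
  ds <- function(col, A, B) sqrt(s(A, col)^2 + s(B, col)^2)
  rl <- d("receptor_ligand", boundA, boundB)
  li <- d("ligand_internal", boundA, boundB) - d("ligand_internal", unboundA, unboundB)
  lwB <- d("ligand_water", boundA, boundB)
  lwU <- d("ligand_water", unboundA, unboundB)
  sems <- c(receptorLigand = ds("receptor_ligand", boundA, boundB),
            ligandInternal = sqrt(ds("ligand_internal", boundA, boundB)^2 +
                                  ds("ligand_internal", unboundA, unboundB)^2),
            ligandWaterBound = ds("ligand_water", boundA, boundB),
            ligandWaterUnbound = ds("ligand_water", unboundA, unboundB))
  ligandEnergyComponents(rl, li, lwB, lwU, sems)
}

#' Surroundings contribution to the relative binding enthalpy
#'
#' The surroundings term cannot be converged by direct averaging (it sums
#' over every receptor/water interaction), so it is obtained indirectly:
#' \eqn{\Delta\Delta U_S = \Delta\Delta H - \Delta\Delta U_L}.  SEMs add in
#' quadrature.
#'
#' @param ddH relative binding enthalpy (kcal/mol), or a
#'   [VantHoffProfile-class].
#' @param ddUL ligand contribution (kcal/mol), or a
#'   [LigandEnergyComponents-class].
#' @param semDdH,semDdUL standard errors (ignored when objects are supplied:
#'   the profile SE and component SEM are used).
#' @return An [EnthalpyDecomposition-class].
#' @examples
#' surroundingsEnergy(-11.6, -10.8)@ddUS # -0.8
#' surroundingsEnergy(-10.3, 4.3)@ddUS   # -14.6
#' @export
surroundingsEnergy <- function(ddH, ddUL, semDdH = 0, semDdUL = 0) {
  if (is(ddH, "VantHoffProfile")) {
    semDdH <- ddH@seDdH
    ddH <- ddH@ddH
  }
  if (is(ddUL, "LigandEnergyComponents")) {
    semDdUL <- ddUL@sems[["ddUL"]]
    ddUL <- ddUL@ddUL
  }
  .stopIfNot(is.finite(ddH) && is.finite(ddUL), "ddH and ddUL must be finite")
  ddUS <- ddH - ddUL
  new("EnthalpyDecomposition", ddH = ddH, ddUL = ddUL, ddUS = ddUS,
      sems = c(ddH = semDdH, ddUL = semDdUL,
               ddUS = sqrt(semDdH^2 + semDdUL^2)))
}

#' Assemble a thermodynamic profile
#'
#' Puts \eqn{\Delta\Delta G}, \eqn{\Delta\Delta H} and
#' \eqn{-T\Delta\Delta S} side by side.  Because the free energy is measured
#' independently of the enthalpy/entropy split, their additivity is a
#' consistency diagnostic: the profile is flagged when
#' \eqn{|\Delta\Delta G - (\Delta\Delta H - T\Delta\Delta S)|} exceeds the
#' combined SEM.
#'
#' @param ddG relative binding free energy (kcal/mol) or a
#'   [RelativeBindingFreeEnergy-class].
#' @param profile a [VantHoffProfile-class], or a numeric ddH when
#'   `minusTddS` is given.
#' @param minusTddS entropy term (kcal/mol) when `profile` is numeric.
#' @param semDdG,semDdH,semMinusTddS standard errors (taken from the objects
#'   when those are supplied).
#' @param temperature K; must match the profile's reference temperature.
#' @return A [ThermodynamicProfile-class].
#' @examples
#' assembleProfile(-6.8, -11.6, 4.8)@flag # FALSE: exact additivity
#' assembleProfile(-6.7, -11.6, 4.8)@flag # TRUE: 0.1 kcal/mol discrepancy
#' @export
assembleProfile <- function(ddG, profile = NULL, minusTddS = NULL,
                            semDdG = 0, semDdH = 0, semMinusTddS = 0,
                            temperature = 300) {
  if (is(ddG, "RelativeBindingFreeEnergy")) {
    semDdG <- ddG@sem
    temperature <- ddG@temperature
    ddG <- ddG@ddG
  }
  if (is(profile, "VantHoffProfile")) {
    if (abs(profile@Tref - temperature) > 1e-9)
      stop(sprintf("temperature mismatch: ddG at %g K, profile at Tref %g K",
                   temperature, profile@Tref))
    semDdH <- profile@seDdH
    semMinusTddS <- profile@seMinusTddS
    ddHv <- profile@ddH
    mts <- profile@minusTddS
  } else {
    ddHv <- profile
    mts <- minusTddS
  }
  disc <- ddG - (ddHv + mts)
  combined <- sqrt(semDdG^2 + semDdH^2 + semMinusTddS^2)
  new("ThermodynamicProfile", ddG = ddG, ddH = ddHv, minusTddS = mts,
      temperature = temperature, discrepancy = disc, combinedSEM = combined,
      flag = abs(disc) > max(combined, 1e-9))
}
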