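# Harmonic-oscillator toy system: the closed-form benchmark for the FEP and
# van't Hoff stages.

#' Create a harmonic mutation specification
#'
#' @param dimensionality 1 or 3.
#' @param forceConstantA,forceConstantB force constants (kcal/(mol A^2)).
#' @param centerA,centerB well centers (Angstrom); scalars are recycled to
#'   the dimensionality.
#' @param temperature K.
#' @return A [HarmonicSpec-class].
#' @examples
#' spec <- harmonicSpec(forceConstantA = 1, forceConstantB = 2)
#' harmonicFreeEnergy(spec) # (kB T / 2) ln 2
#' @export
harmonicSpec <- function(dimensionality = 1L, forceConstantA = 1,
                         forceConstantB = 2, centerA = 0, centerB = 0,
                         temperature = 300) {
  d <- as.integer(dimensionality)
  new("HarmonicSpec", dimensionality = d,
      forceConstantA = forceConstantA, forceConstantB = forceConstantB,
      centerA = rep_len(centerA, d), centerB = rep_len(centerB, d),
      temperature = temperature)
}

#' Closed-form transformation free energy of a harmonic mutation
#'
#' For \eqn{U_X = k_X |x - c_X|^2/2} the configurational partition function
#' is Gaussian, so \eqn{\Delta F = (d \, k_B T / 2) \ln(k_B/k_A)},
#' independent of the centers.
#'
#' @param spec a [HarmonicSpec-class].
#' @param temperature optional override of the spec temperature (K).
#' @return Free energy difference B minus A (kcal/mol).
#' @export
harmonicFreeEnergy <- function(spec, temperature = spec@temperature) {
  spec@dimensionality * .kB * temperature / 2 *
    log(spec@forceConstantB / spec@forceConstantA)
}

#' @describeIn sampleAlchemicalPath Metropolis sampling of the harmonic
#'   mutation with linear coupling \eqn{U_\lambda = (1-\lambda)U_A +
#'   \lambda U_B}.  `stepSize` defaults to the thermal width of the stiffer
#'   well, `keepPositions = TRUE` additionally returns per-window position
#'   samples.
#' @param stepSize Gaussian proposal standard deviation (Angstrom).
#' @param keepPositions logical; keep per-window position samples.
#' @export
setMethod("sampleAlchemicalPath", "HarmonicSpec",
  function(spec, ladder = lambdaLadder(), nSteps = 10000L, equilFraction = 0.1,
           seed, stepSize = NULL, keepPositions = FALSE, ...) {
    .stopIfNot(nSteps > 0, "nSteps must be positive")
    .stopIfNot(!missing(seed), "seed is mandatory")
    validObject(spec); validObject(ladder)
    if (is.null(stepSize))
      stepSize <- sqrt(.kB * spec@temperature /
                       max(spec@forceConstantA, spec@forceConstantB))
    set.seed(as.integer(seed))
    raw <- mc_harmonic_path(spec@dimensionality, spec@forceConstantA,
                            spec@forceConstantB, spec@centerA, spec@centerB,
                            spec@temperature, ladder@lambdas,
                            as.integer(nSteps), equilFraction, stepSize,
                            keepPositions)
    lam <- ladder@lambdas
    out <- lapply(seq_along(raw), function(i)
      new("PerturbationSeries", windowIndex = i, lambda = lam[i],
          lambdaNext = lam[i + 1], deltaU = raw[[i]]$delta_u,
          temperature = spec@temperature))
    attr(out, "acceptance") <- vapply(raw, `[[`, numeric(1), "acceptance")
    attr(out, "meanX2") <- vapply(raw, `[[`, numeric(1), "mean_x2")
    if (keepPositions)
      attr(out, "positions") <- lapply(raw, `[[`, "positions")
    out
  })
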