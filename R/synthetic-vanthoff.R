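# Synthetic free-energy-versus-temperature tables with known enthalpy and
# entropy: ground truth for the van't Hoff regression and bootstrap.

#' Create a synthetic van't Hoff table specification
#'
#' @param deltaH enthalpy (kcal/mol).
#' @param deltaS entropy (kcal/(mol K)).
#' @param temperatures at least 3 distinct temperatures (K); the default is
#'   eight temperatures from 280 to 315 K in 5 K steps.
#' @param noiseSD Gaussian noise on each replicate free energy (kcal/mol).
#' @param nReplicates replicates per temperature.
#' @param seed mandatory RNG seed.
#' @return A [SyntheticVantHoffSpec-class].
#' @export
syntheticVantHoffSpec <- function(deltaH = -11.6, deltaS = -0.016,
                                  temperatures = vantHoffTemperatures(),
                                  noiseSD = 0.2, nReplicates = 3L, seed) {
  .stopIfNot(!missing(seed), "seed is mandatory")
  new("SyntheticVantHoffSpec", deltaH = deltaH, deltaS = deltaS,
      temperatures = temperatures, noiseSD = noiseSD,
      nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

#' Default van't Hoff temperature set
#'
#' Eight temperatures, 280 to 315 K in 5 K steps.
#'
#' @return Numeric vector of 8 temperatures (K).
#' @export
vantHoffTemperatures <- function() seq(280, 315, by = 5)

#' Generate a replicated free-energy-versus-temperature table
#'
#' Draws \eqn{\Delta G(T, r) = \Delta H - T \Delta S + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2)}, for every temperature and replicate of
#' the specification.  Deterministic given the spec's seed.
#'
#' @param spec a [SyntheticVantHoffSpec-class].
#' @return data.frame with columns temperature, replicate, dG.
#' @examples
#' tab <- generateVantHoffTable(syntheticVantHoffSpec(noiseSD = 0, seed = 1))
#' all.equal(tab$dG, -11.6 - tab$temperature * (-0.016))
#' @export
generateVantHoffTable <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  tab <- expand.grid(replicate = seq_len(spec@nReplicates),
                     temperature = spec@temperatures)[, 2:1]
  tab$dG <- spec@deltaH - tab$temperature * spec@deltaS +
    rnorm(nrow(tab), 0, spec@noiseSD)
  tab[order(tab$temperature, tab$replicate), ]
}
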