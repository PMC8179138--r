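#' Sample an alchemical perturbation path
#'
#' Runs Metropolis Monte Carlo at every window of a lambda ladder and records,
#' for each retained frame, the energy difference to the next window --- the
#' input of the Zwanzig estimator.  One chain is run per window, seeded from
#' the final configuration of the previous window; the first
#' `equilFraction` of each chain is discarded.
#'
#' @param spec a [HarmonicSpec-class] or [HostGuestSpec-class].
#' @param ladder a [LambdaLadder-class].
#' @param nSteps Monte Carlo steps per window (sweeps for the host-guest
#'   system).
#' @param equilFraction fraction of steps discarded as equilibration.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @param ... method-specific arguments (step sizes, trajectory recording).
#' @return A list of [PerturbationSeries-class], one per window, with
#'   attributes `acceptance` (per-window acceptance rates) and, for the
#'   harmonic sampler, `meanX2` (per-window mean squared displacement,
#'   for equipartition checks).
#' @seealso [zwanzigWindow()], [accumulateLeg()]
#' @export
setGeneric("sampleAlchemicalPath",
           function(spec, ladder = lambdaLadder(), nSteps = 10000L,
                    equilFraction = 0.1, seed, ...)
             standardGeneric("sampleAlchemicalPath"))

#' Simulate one physical end state of a synthetic system
#'
#' Runs plain (non-alchemical) Metropolis sampling of end state A or B and
#' returns tagged per-frame energy components and, optionally, a water
#' trajectory for hydration-site analysis.
#'
#' @param spec a [HostGuestSpec-class].
#' @param state "A" or "B".
#' @param nSteps Monte Carlo sweeps.
#' @param equilFraction fraction discarded as equilibration.
#' @param seed integer RNG seed.
#' @param ... method-specific arguments.
#' @return A list with elements `energies` (data.frame of per-frame tagged
#'   components, kcal/mol), `trajectory` (a [Trajectory-class] or NULL) and
#'   `acceptance`.
#' @export
setGeneric("sampleEndState",
           function(spec, state = c("A", "B"), nSteps = 20000L,
                    equilFraction = 0.1, seed, ...)
             standardGeneric("sampleEndState"))

#' @name accessors
#' @title Accessors for ThermoFEP result objects
#' @description Small accessor generics shared across result classes: free
#'   energy (`ddG`), enthalpy (`ddH`), entropy term (`minusTddS`), leg free
#'   energy (`legDG`) and the per-site table of a hydration-site set
#'   (`siteTable`).
#' @param object a ThermoFEP result object.
#' @return A numeric scalar, or a data.frame for `siteTable`.
NULL

#' @rdname accessors
#' @export
setGeneric("ddG", function(object) standardGeneric("ddG"))
#' @rdname accessors
#' @export
setGeneric("ddH", function(object) standardGeneric("ddH"))
#' @rdname accessors
#' @export
setGeneric("minusTddS", function(object) standardGeneric("minusTddS"))
#' @rdname accessors
#' @export
setGeneric("legDG", function(object) standardGeneric("legDG"))
#' @rdname accessors
#' @export
setGeneric("siteTable", function(object) standardGeneric("siteTable"))
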