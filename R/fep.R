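# Zwanzig (exponential averaging) free energy perturbation, leg accumulation
# and thermodynamic-cycle combination.

#' Create a lambda ladder
#'
#' @param nWindows number of perturbation windows; the ladder holds
#'   `nWindows + 1` evenly spaced lambda values from 0 to 1.  The default of
#'   84 windows matches the intermediate-state count used for the receptor
#'   calculations this package models.
#' @param lambdas explicit lambda values (overrides `nWindows`).
#' @return A [LambdaLadder-class].
#' @examples
#' lambdaLadder(11)
#' lambdaLadder(lambdas = c(0, 0.5, 1))
#' @export
lambdaLadder <- function(nWindows = 84L, lambdas = NULL) {
  if (is.null(lambdas)) lambdas <- seq(0, 1, length.out = nWindows + 1)
  new("LambdaLadder", lambdas = lambdas)
}

#' Create a perturbation series
#'
#' @param deltaU per-frame energy differences (kcal/mol).
#' @param lambda,lambdaNext coupling values of the sampled and target states.
#' @param windowIndex window number along the ladder.
#' @param temperature K.
#' @return A [PerturbationSeries-class].
#' @export
perturbationSeries <- function(deltaU, lambda = 0, lambdaNext = 1,
                               windowIndex = 1L, temperature = 300) {
  new("PerturbationSeries", windowIndex = as.integer(windowIndex),
      lambda = lambda, lambdaNext = lambdaNext, deltaU = deltaU,
      temperature = temperature)
}

#' Zwanzig free energy estimate for one window
#'
#' Computes \eqn{\Delta F = -k_B T \ln \langle e^{-\Delta U / k_B T}
#' \rangle} with a numerically stable log-sum-exp.  The standard error comes
#' from block averaging (the free energy is re-estimated on `nBlocks`
#' contiguous blocks), and an overlap diagnostic reports how concentrated the
#' exponential average is: the fraction of total weight carried by the
#' top 5% of frames.  A warning is raised when more than half the weight
#' comes from fewer than 5% of frames, the signature of poor phase-space
#' overlap between adjacent windows.
#'
#' @param series a [PerturbationSeries-class] (>= 10 frames expected; fewer
#'   raises a warning).
#' @param nBlocks blocks for the SEM (default 10).
#' @return A list: `dG`, `sem`, `nFrames`, `overlap` (top-5% weight
#'   fraction), `flagged` (logical overlap warning).
#' @examples
#' zwanzigWindow(perturbationSeries(rep(0.5, 100)))$dG # exactly 0.5
#' @export
zwanzigWindow <- function(series, nBlocks = 10L) {
  validObject(series)
  dU <- series@deltaU
  if (length(dU) < 10)
    warning("fewer than 10 retained frames; estimate will be unreliable")
  kT <- .kB * series@temperature
  dG <- -kT * .logMeanExp(-dU / kT)
  n <- length(dU)
  nb <- min(nBlocks, n)
  idx <- cut(seq_len(n), breaks = nb, labels = FALSE)
  blockDG <- vapply(split(dU, idx), function(b) -kT * .logMeanExp(-b / kT),
                    numeric(1))
  sem <- if (length(blockDG) > 1) stats::sd(blockDG) / sqrt(length(blockDG)) else 0
  # weight concentration diagnostic
  w <- exp(-dU / kT - max(-dU / kT))
  w <- w / sum(w)
  k5 <- max(1L, floor(0.05 * n))
  overlap <- sum(sort(w, decreasing = TRUE)[seq_len(k5)])
  flagged <- overlap > 0.5
  if (flagged)
    warning(sprintf("window %d: %.0f%% of the exponential-average weight comes from the top %d frames (<5%%); poor overlap",
                    series@windowIndex, 100 * overlap, k5))
  list(dG = dG, sem = sem, nFrames = n, overlap = overlap, flagged = flagged)
}

#' Accumulate window free energies into a leg
#'
#' Sums the per-window Zwanzig estimates along the ladder into the leg
#' transformation free energy; window SEMs combine in quadrature.
#'
#' @param windows list of [zwanzigWindow()] results (ordered by lambda), or a
#'   numeric vector of window free energies.
#' @param label "bound" or "unbound".
#' @param temperature K.
#' @param ladder optional [LambdaLadder-class]; when given, the window count
#'   is checked against it.
#' @return A [FreeEnergyResult-class].
#' @examples
#' legDG(accumulateLeg(c(0.1, -0.2, 0.3), "bound")) # 0.2
#' @export
accumulateLeg <- function(windows, label = c("bound", "unbound"),
                          temperature = 300, ladder = NULL) {
  label <- match.arg(label)
  if (is.numeric(windows)) {
    dGs <- windows
    sems <- rep(0, length(windows))
  } else {
    dGs <- vapply(windows, `[[`, numeric(1), "dG")
    sems <- vapply(windows, `[[`, numeric(1), "sem")
  }
  if (!is.null(ladder) && length(dGs) != length(ladder@lambdas) - 1)
    stop(sprintf("window count (%d) does not match ladder (%d windows)",
                 length(dGs), length(ladder@lambdas) - 1))
  new("FreeEnergyResult", legLabel = label, windowDGs = dGs,
      windowSEMs = sems, legDG = sum(dGs), legSEM = sqrt(sum(sems^2)),
      replicateDGs = numeric(0), temperature = temperature)
}

#' Run one full FEP leg on a synthetic system
#'
#' Convenience wrapper: samples the alchemical path, applies the Zwanzig
#' estimator per window and accumulates the leg.
#'
#' @param spec a [HarmonicSpec-class] or [HostGuestSpec-class].
#' @param label "bound" or "unbound".
#' @param ladder a [LambdaLadder-class].
#' @param nSteps steps per window.
#' @param seed RNG seed.
#' @param ... passed to [sampleAlchemicalPath()].
#' @return A [FreeEnergyResult-class].
#' @export
fepLeg <- function(spec, label = c("bound", "unbound"),
                   ladder = lambdaLadder(), nSteps = 10000L, seed, ...) {
  label <- match.arg(label)
  series <- sampleAlchemicalPath(spec, ladder, nSteps = nSteps, seed = seed, ...)
  windows <- suppressWarnings(lapply(series, zwanzigWindow))
  accumulateLeg(windows, label, temperature = spec@temperature, ladder = ladder)
}

#' Combine replicate legs
#'
#' Aggregates independent-seed replicates of the same leg: the leg free
#' energy becomes the replicate mean and the SEM the standard error over
#' replicates (the error model used for production runs; three replicates by
#' default mirrors standard practice).
#'
#' @param legs list of [FreeEnergyResult-class] replicates of the same leg.
#' @return A [FreeEnergyResult-class] with `replicateDGs` filled.
#' @export
combineReplicates <- function(legs) {
  .stopIfNot(length(legs) >= 1, "need at least one replicate")
  lab <- unique(vapply(legs, function(l) l@legLabel, character(1)))
  .stopIfNot(length(lab) == 1, "replicates must share a leg label")
  temps <- unique(vapply(legs, function(l) l@temperature, numeric(1)))
  .stopIfNot(length(temps) == 1, "replicates must share a temperature")
  reps <- vapply(legs, function(l) l@legDG, numeric(1))
  nw <- length(legs[[1]]@windowDGs)
  wdg <- rowMeans(matrix(vapply(legs, function(l) l@windowDGs, numeric(nw)),
                         nrow = nw))
  sem <- if (length(reps) > 1) stats::sd(reps) / sqrt(length(reps)) else legs[[1]]@legSEM
  new("FreeEnergyResult", legLabel = lab, windowDGs = wdg,
      windowSEMs = rep(NA_real_, length(wdg)), legDG = mean(reps),
      legSEM = sem, replicateDGs = reps, temperature = temps)
}

#' Combine bound and unbound legs through the thermodynamic cycle
#'
#' \eqn{\Delta\Delta G = \Delta G_{bound} - \Delta G_{unbound}}.  When both
#' legs carry the same number of replicates, the estimate is the mean of the
#' per-replicate differences and the SEM the standard error over those
#' differences; otherwise leg SEMs combine in quadrature.
#'
#' @param bound,unbound [FreeEnergyResult-class] legs at equal temperature.
#' @return A [RelativeBindingFreeEnergy-class].
#' @examples
#' b <- accumulateLeg(-8, "bound"); u <- accumulateLeg(-2, "unbound")
#' ddG(cycleCombine(b, u)) # -6
#' @export
cycleCombine <- function(bound, unbound) {
  .stopIfNot(bound@legLabel == "bound" && unbound@legLabel == "unbound",
             "legs must be labelled 'bound' and 'unbound'")
  if (abs(bound@temperature - unbound@temperature) > 1e-9)
    stop("temperature mismatch between legs")
  nb <- length(bound@replicateDGs); nu <- length(unbound@replicateDGs)
  if (nb > 1 && nb == nu) {
    diffs <- bound@replicateDGs - unbound@replicateDGs
    dd <- mean(diffs)
    sem <- stats::sd(diffs) / sqrt(length(diffs))
  } else {
    dd <- bound@legDG - unbound@legDG
    sem <- sqrt(bound@legSEM^2 + unbound@legSEM^2)
  }
  new("RelativeBindingFreeEnergy", ddG = dd, sem = sem, bound = bound,
      unbound = unbound, temperature = bound@temperature)
}
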