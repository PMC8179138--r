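# Accessors and show methods.

#' @rdname accessors
#' @aliases ddG,RelativeBindingFreeEnergy-method
setMethod("ddG", "RelativeBindingFreeEnergy", function(object) object@ddG)
#' @rdname accessors
setMethod("ddG", "ThermodynamicProfile", function(object) object@ddG)
#' @rdname accessors
setMethod("ddH", "VantHoffProfile", function(object) object@ddH)
#' @rdname accessors
setMethod("ddH", "EnthalpyDecomposition", function(object) object@ddH)
#' @rdname accessors
setMethod("ddH", "ThermodynamicProfile", function(object) object@ddH)
#' @rdname accessors
setMethod("minusTddS", "VantHoffProfile", function(object) object@minusTddS)
#' @rdname accessors
setMethod("minusTddS", "ThermodynamicProfile", function(object) object@minusTddS)
#' @rdname accessors
setMethod("legDG", "FreeEnergyResult", function(object) object@legDG)
#' @rdname accessors
setMethod("siteTable", "HydrationSiteSet", function(object) object@sites)

.fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")

setMethod("show", "LambdaLadder", function(object) {
  cat("LambdaLadder:", length(object@lambdas) - 1, "windows,",
      length(object@lambdas), "lambda values in [0,1]\n")
})

setMethod("show", "PerturbationSeries", function(object) {
  cat(sprintf("PerturbationSeries window %d: lambda %.4f -> %.4f, %d frames, T = %g K\n",
              object@windowIndex, object@lambda, object@lambdaNext,
              length(object@deltaU), object@temperature))
})

setMethod("show", "FreeEnergyResult", function(object) {
  cat(sprintf("FreeEnergyResult [%s leg]: dG = %s +/- %s kcal/mol (%d windows",
              object@legLabel, .fmt(object@legDG), .fmt(object@legSEM),
              length(object@windowDGs)))
  if (length(object@replicateDGs) > 1)
    cat(sprintf(", %d replicates", length(object@replicateDGs)))
  cat(sprintf(") at %g K\n", object@temperature))
})

setMethod("show", "RelativeBindingFreeEnergy", function(object) {
  cat(sprintf("RelativeBindingFreeEnergy: ddG = %s +/- %s kcal/mol at %g K\n",
              .fmt(object@ddG), .fmt(object@sem), object@temperature))
})

setMethod("show", "VantHoffProfile", function(object) {
  cat(sprintf("VantHoffProfile (%d temperatures, R^2 = %.4f):\n",
              object@nTemperatures, object@rSquared))
  cat(sprintf("  ddH        = %s kcal/mol  [95%% CI %s, %s]\n",
              .fmt(object@ddH), .fmt(object@ciDdH[1]), .fmt(object@ciDdH[2])))
  cat(sprintf("  -T ddS     = %s kcal/mol at %g K  [95%% CI %s, %s]\n",
              .fmt(object@minusTddS), object@Tref,
              .fmt(object@ciMinusTddS[1]), .fmt(object@ciMinusTddS[2])))
  cat(sprintf("  ddG(Tref)  = %s kcal/mol (ddH - Tref*ddS)\n",
              .fmt(object@ddH + object@minusTddS)))
})

setMethod("show", "LigandEnergyComponents", function(object) {
  cat("LigandEnergyComponents (kcal/mol):\n")
  cat(sprintf("  receptor-ligand      %s\n", .fmt(object@receptorLigand)))
  cat(sprintf("  ligand internal      %s\n", .fmt(object@ligandInternal)))
  cat(sprintf("  ligand-water bound   %s\n", .fmt(object@ligandWaterBound)))
  cat(sprintf("  ligand-water unbound %s\n", .fmt(object@ligandWaterUnbound)))
  cat(sprintf("  desolvation          %s\n", .fmt(object@desolvation)))
  cat(sprintf("  ddU_L                %s\n", .fmt(object@ddUL)))
})

setMethod("show", "EnthalpyDecomposition", function(object) {
  cat(sprintf("EnthalpyDecomposition: ddH = %s = ddU_L (%s) + ddU_S (%s) kcal/mol\n",
              .fmt(object@ddH), .fmt(object@ddUL), .fmt(object@ddUS)))
})

setMethod("show", "ThermodynamicProfile", function(object) {
  cat(sprintf("ThermodynamicProfile at %g K (kcal/mol): ddG = %s, ddH = %s, -TddS = %s\n",
              object@temperature, .fmt(object@ddG), .fmt(object@ddH),
              .fmt(object@minusTddS)))
  cat(sprintf("  additivity discrepancy %s (%s)\n", .fmt(object@discrepancy),
              if (object@flag) "FLAGGED" else "consistent"))
})

setMethod("show", "Trajectory", function(object) {
  nw <- vapply(object@frames, function(f) nrow(f$water), integer(1))
  cat(sprintf("Trajectory: %d frames, %.1f waters/frame (mean), region radius %g A, T = %g K\n",
              length(object@frames), mean(nw), object@regionRadius,
              object@temperature))
})

setMethod("show", "HydrationSiteSet", function(object) {
  cat(sprintf("HydrationSiteSet: %d sites (radius %g A, %d frames)\n",
              nrow(object@sites), object@siteRadius, object@nFrames))
  if (nrow(object@sites)) print(object@sites, digits = 3)
})

setMethod("show", "NetworkComparison", function(object) {
  cat(sprintf("NetworkComparison: %d matched pairs, %d displaced (A only), %d new (B only)\n",
              nrow(object@matches), length(object@displacedA), length(object@onlyB)))
  t <- object@totals
  cat(sprintf("  totals (kcal/mol): dE_ww = %s, dE_pw = %s, dE_total = %s, d(-TdS) = %s\n",
              .fmt(t[["dEww"]]), .fmt(t[["dEpw"]]), .fmt(t[["dEtotal"]]),
              .fmt(t[["dMinusTdS"]])))
})

setMethod("show", "AffinityRecord", function(object) {
  if (is.na(object@Ki))
    cat(sprintf("AffinityRecord %s: %.0f%% inhibition (no Ki) at %g K\n",
                object@compound, object@percentInhibition, object@temperature))
  else
    cat(sprintf("AffinityRecord %s: Ki = %.3g M at %g K\n",
                object@compound, object@Ki, object@temperature))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig [%s] hash %s: stages %s\n",
              if (nzchar(object@path)) object@path else "<in-memory>",
              object@hash, paste(names(object@config$stages), collapse = ", ")))
})
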