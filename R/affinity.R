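# Conversion of experimental binding measurements to free energies.

#' Create an affinity record
#'
#' @param compound compound label.
#' @param Ki inhibition constant in molar units (omit when only percent
#'   inhibition is available).
#' @param percentInhibition percent inhibition at a fixed concentration;
#'   such records carry no free energy and are reported qualitatively only.
#' @param temperature assay temperature (K), default 298.15.
#' @param note free-text assay note.
#' @return An [AffinityRecord-class].
#' @examples
#' affinityRecord("adenosine", Ki = 45e-9)
#' @export
affinityRecord <- function(compound, Ki = NA_real_,
                           percentInhibition = NA_real_,
                           temperature = 298.15, note = "") {
  new("AffinityRecord", compound = compound, Ki = Ki,
      percentInhibition = percentInhibition, temperature = temperature,
      note = note)
}

#' Convert an inhibition constant to a binding free energy
#'
#' \eqn{\Delta G = RT \ln(K_i / 1\,M)} at a 1 M standard state; negative for
#' sub-molar \eqn{K_i}.
#'
#' @param record an [AffinityRecord-class], or a numeric Ki in molar units.
#' @param temperature K (used when `record` is numeric).
#' @return Binding free energy (kcal/mol).
#' @examples
#' kiToDeltaG(1)        # 0
#' kiToDeltaG(103e-9)   # about -9.5 kcal/mol
#' @export
kiToDeltaG <- function(record, temperature = 298.15) {
  if (is(record, "AffinityRecord")) {
    validObject(record)
    if (is.na(record@Ki))
      stop(sprintf("record '%s' has no Ki (percent inhibition only); no free energy",
                   record@compound))
    temperature <- record@temperature
    record <- record@Ki
  }
  .stopIfNot(all(record > 0), "Ki must be positive")
  .kB * temperature * log(record)
}

#' Relative binding free energy from two inhibition constants
#'
#' \eqn{\Delta\Delta G = RT \ln(K_i^A / K_i^B)}; antisymmetric under swapping
#' A and B, and identical to `kiToDeltaG(A) - kiToDeltaG(B)` to machine
#' precision.
#'
#' @param recordA,recordB [AffinityRecord-class] objects (or numeric Ki in
#'   molar) at equal temperatures.
#' @param temperature K (used when the records are numeric).
#' @return Relative binding free energy (kcal/mol).
#' @examples
#' ddgFromKi(affinityRecord("A", 45e-9), affinityRecord("B", 39e-6)) # -4.0
#' @export
ddgFromKi <- function(recordA, recordB, temperature = 298.15) {
  getKT <- function(r) {
    if (is(r, "AffinityRecord")) {
      if (is.na(r@Ki)) stop(sprintf("record '%s' has no Ki", r@compound))
      c(r@Ki, r@temperature)
    } else c(r, temperature)
  }
  a <- getKT(recordA); b <- getKT(recordB)
  if (abs(a[2] - b[2]) > 1e-9)
    stop(sprintf("temperature mismatch: %g K vs %g K", a[2], b[2]))
  .kB * a[2] * log(a[1] / b[1])
}
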