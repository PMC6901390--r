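#' Theoretical maximum lactic acid from mannose
#'
#' The cascade cleaves each C6 KDG into pyruvate and glyceraldehyde and
#' only the pyruvate half is reduced to lactate, so at most 1 mol LA forms
#' per mol mannose: 50% of the substrate carbon.
#'
#' @param mannose Mannose concentration (mM), `>= 0`.
#' @return Maximum LA titre (mM).
#' @export
theoretical_max_la <- function(mannose) {
  if (any(mannose < 0)) stop("mannose must be >= 0")
  mannose
}

#' Lactic acid yield as percent of the theoretical maximum
#'
#' @param la LA titre (mM).
#' @param mannose Initial mannose (mM), `> 0`.
#' @return Yield in percent of [theoretical_max_la].
#' @examples
#' percent_yield(3.78, 20)  # 18.9
#' @export
percent_yield <- function(la, mannose) {
  if (any(mannose <= 0)) stop("mannose must be > 0")
  100 * la / theoretical_max_la(mannose)
}

#' Titre implied by a percent yield
#'
#' @param yield_pct Yield in percent of the theoretical maximum, `>= 0`.
#' @param mannose Initial mannose (mM), `>= 0`.
#' @return LA titre (mM).
#' @examples
#' titre_from_yield(71.5, 5)  # 3.575 mM, tabulated as 3.6
#' @export
titre_from_yield <- function(yield_pct, mannose) {
  if (any(yield_pct < 0)) stop("yield must be >= 0")
  yield_pct / 100 * theoretical_max_la(mannose)
}

#' NADH concentration from 340 nm absorbance
#'
#' Beer-Lambert with the NADH extinction coefficient
#' epsilon_340 = 6.22 /mM/cm.
#'
#' @param A Absorbance (AU), `>= 0`.
#' @param path_cm Optical path length (cm), `> 0`.
#' @return NADH concentration (mM).
#' @export
nadh_from_absorbance <- function(A, path_cm = 1) {
  if (any(A < 0)) stop("absorbance must be >= 0")
  if (any(path_cm <= 0)) stop("path length must be > 0")
  A / (6.22 * path_cm)
}

#' KDG concentration from the thiobarbituric acid assay
#'
#' Beer-Lambert at 549 nm with the TBA-chromophore extinction coefficient
#' epsilon_549 = 67.8 /mM/cm.
#'
#' @inheritParams nadh_from_absorbance
#' @param A549 Absorbance at 549 nm (AU), `>= 0`.
#' @return KDG concentration (mM).
#' @export
kdg_from_absorbance <- function(A549, path_cm = 1) {
  if (any(A549 < 0)) stop("absorbance must be >= 0")
  if (any(path_cm <= 0)) stop("path length must be > 0")
  A549 / (67.8 * path_cm)
}

#' Recovery-corrected sugar content of hydrolysed biomass
#'
#' Dilute acid hydrolysis destroys part of the released sugar; a reducing
#' sugar standard run through the same procedure gives the recovered
#' fraction, and the true content is the measured content divided by it.
#'
#' @param measured Sugar measured in the hydrolysate (mg per 100 mg solid).
#' @param std_recovery Fractional recovery of the standard, in (0, 1].
#' @return Corrected content (mg per 100 mg solid).
#' @export
corrected_scg_content <- function(measured, std_recovery) {
  if (any(measured < 0)) stop("measured content must be >= 0")
  if (any(std_recovery <= 0) || any(std_recovery > 1))
    stop("std_recovery must be in (0, 1]")
  measured / std_recovery
}

#' Batch hydrolysate mass balance
#'
#' Applies [corrected_scg_content] and [theoretical_max_la] to a table of
#' hydrolysis batches.
#'
#' @param batches Data frame with columns `scg_mass_mg`,
#'   `measured_mg_per_100mg`, `std_recovery`, and optionally
#'   `mannose_mM` (hydrolysate mannose concentration used as cascade
#'   substrate).
#' @return The input with added columns `corrected_mg_per_100mg` and, where
#'   `mannose_mM` is present, `max_la_mM`.
#' @export
hydrolysis_mass_balance <- function(batches) {
  need <- c("scg_mass_mg", "measured_mg_per_100mg", "std_recovery")
  miss <- setdiff(need, names(batches))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  batches$corrected_mg_per_100mg <-
    corrected_scg_content(batches$measured_mg_per_100mg, batches$std_recovery)
  if ("mannose_mM" %in% names(batches))
    batches$max_la_mM <- theoretical_max_la(batches$mannose_mM)
  batches
}
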