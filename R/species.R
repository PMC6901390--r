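#' Canonical cascade species
#'
#' The cascade state is an ordered vector of concentrations (mM) over a fixed
#' species set: mannose (MAN), mannono-1,4-lactone (ML), mannonate (MA),
#' 2-keto-3-deoxygluconate (KDG), pyruvate (PYR), glyceraldehyde (GA),
#' glycerate (GLYA), lactic acid (LA) and the cofactor pair NADp/NADH.
#'
#' @format Character vector of the ten canonical species identifiers, in the
#'   order used by every state vector and time course in the package.
#' @export
CASCADE_SPECIES <- c("MAN", "ML", "MA", "KDG", "PYR", "GA", "GLYA", "LA",
                     "NADp", "NADH")

#' Carbon atoms per cascade species
#'
#' @format Named integer vector parallel to [CASCADE_SPECIES]; hexoses and
#'   hexose acids carry 6 carbons, the triose-derived species 3, and the
#'   nicotinamide cofactors are excluded from the carbon balance (0).
#' @export
CASCADE_CARBONS <- c(MAN = 6L, ML = 6L, MA = 6L, KDG = 6L, PYR = 3L,
                     GA = 3L, GLYA = 3L, LA = 3L, NADp = 0L, NADH = 0L)

#' Construct a cascade species vector
#'
#' Builds a full-length, canonically ordered state vector from named
#' concentrations; unspecified species default to 0 mM.
#'
#' @param ... Named concentrations in mM, e.g. `MAN = 5, NADp = 5`.
#' @return Named numeric vector over [CASCADE_SPECIES].
#' @examples
#' species_vector(MAN = 5, NADp = 5)
#' @export
species_vector <- function(...) {
  given <- c(...)
  if (length(given) == 0) given <- numeric(0)
  if (is.null(names(given)) && length(given) > 0)
    stop("species concentrations must be named")
  unknown <- setdiff(names(given), CASCADE_SPECIES)
  if (length(unknown) > 0)
    stop("unknown species: ", paste(unknown, collapse = ", "),
         "; valid species are: ", paste(CASCADE_SPECIES, collapse = ", "))
  if (any(given < 0)) stop("species concentrations must be >= 0")
  out <- stats::setNames(numeric(length(CASCADE_SPECIES)), CASCADE_SPECIES)
  out[names(given)] <- given
  out
}
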