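#' Kinetic parameters for one cascade enzyme
#'
#' @param name One of `"AldT"`, `"ManD"`, `"KDGA"`, `"LDH"`.
#' @param Km Named numeric vector of Michaelis constants (mM), one per
#'   substrate.  KDGA carries a single combined constant for pyruvate plus
#'   glyceraldehyde, measured in the aldol addition direction.
#' @param Vmax Specific activity at saturation (U/mg).
#' @param kcat Turnover number (1/s).
#' @param half_life Thermal half-life at the operating temperature (h);
#'   `Inf` for enzymes that show no measurable deactivation.
#' @param substrate,product Species identifiers (see [CASCADE_SPECIES]).
#' @return Object of class `enzyme_params`.
#' @export
enzyme_params <- function(name, Km, Vmax, kcat, half_life = Inf,
                          substrate, product) {
  stopifnot(is.character(name), length(name) == 1)
  if (any(Km <= 0)) stop("Km must be > 0")
  if (Vmax <= 0) stop("Vmax must be > 0")
  if (half_life <= 0) stop("half_life must be > 0 (Inf allowed)")
  bad <- setdiff(c(substrate, product), CASCADE_SPECIES)
  if (length(bad) > 0) stop("unknown species: ", paste(bad, collapse = ", "))
  structure(list(name = name, Km = Km, Vmax = Vmax, kcat = kcat,
                 half_life = half_life, substrate = substrate,
                 product = product),
            class = "enzyme_params")
}

#' @export
print.enzyme_params <- function(x, ...) {
  cat(sprintf("<enzyme_params> %s: Km = %s mM, Vmax = %.2f U/mg, kcat = %.2f /s, t1/2 = %s h\n",
              x$name, paste(signif(x$Km, 4), collapse = "/"), x$Vmax, x$kcat,
              ifelse(is.finite(x$half_life), format(x$half_life), "Inf")))
  invisible(x)
}

#' Reference enzyme parameter set for the cascade
#'
#' Kinetic constants measured at 50 degrees C, pH 7.0 in sodium phosphate
#' buffer for the four cascade enzymes, together with their operational
#' thermal half-lives at standard loading: AldT (aldohexose dehydrogenase,
#' mannose + NAD+ -> mannono-1,4-lactone + NADH), ManD (mannonate
#' dehydratase), KDGA (KDG aldolase, assayed in the aldol addition
#' direction with one combined Km for pyruvate + glyceraldehyde) and LDH
#' (L-lactate dehydrogenase).  LDH and KDGA show no measurable activity loss
#' over 20 h, so their half-lives are infinite.
#'
#' @return Named list of [enzyme_params] objects.
#' @examples
#' p <- cascade_enzymes()
#' catalytic_efficiency(p$AldT)
#' @export
cascade_enzymes <- function() {
  list(
    AldT = enzyme_params("AldT", Km = c(MAN = 9.73), Vmax = 5.20,
                         kcat = 2.51, half_life = 9.8,
                         substrate = c("MAN", "NADp"),
                         product = c("ML", "NADH")),
    ManD = enzyme_params("ManD", Km = c(MA = 5.37, ML = 4.90), Vmax = 2.39,
                         kcat = 1.67, half_life = 1.4,
                         substrate = "MA", product = "KDG"),
    KDGA = enzyme_params("KDGA", Km = c(PYR_GA = 8.07), Vmax = 17.04,
                         kcat = 10.51, half_life = Inf,
                         substrate = c("PYR", "GA"), product = "KDG"),
    LDH = enzyme_params("LDH", Km = c(PYR = 10.95), Vmax = 194.3,
                        kcat = 116.58, half_life = Inf,
                        substrate = c("PYR", "NADH"),
                        product = c("LA", "NADp"))
  )
}

#' Catalytic efficiency kcat/Km
#'
#' @param params An [enzyme_params] object.
#' @param substrate Which Km to use when several are recorded (defaults to
#'   the first).
#' @return kcat/Km in 1/(mM s).
#' @export
catalytic_efficiency <- function(params, substrate = NULL) {
  Km <- if (is.null(substrate)) params$Km[[1]] else params$Km[[substrate]]
  params$kcat / Km
}
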