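#' Michaelis-Menten rate
#'
#' Irreversible single-substrate rate `Vcap * S / (Km + S)`.  Capacities are
#' expressed as volumetric activities (U/ml), which are numerically mM/min:
#' one unit converts 1 umol substrate per minute.
#'
#' @param S Substrate concentration (mM), `>= 0`.
#' @param Km Michaelis constant (mM), `> 0`.
#' @param Vcap Rate capacity (U/ml == mM/min), `>= 0`.
#' @return Rate in mM/min, bounded by `Vcap` and nondecreasing in `S`.
#' @examples
#' michaelis_menten_rate(9.73, 9.73, 0.2)  # half-saturation: 0.1 mM/min
#' @export
michaelis_menten_rate <- function(S, Km, Vcap) {
  if (any(S < 0)) stop("substrate concentration must be >= 0")
  if (any(Km <= 0)) stop("Km must be > 0")
  if (any(Vcap < 0)) stop("Vcap must be >= 0")
  Vcap * S / (Km + S)
}

#' Aldol addition rate (pyruvate + glyceraldehyde -> KDG)
#'
#' Rapid-equilibrium random-order bi-substrate form with a single combined
#' Michaelis constant in both factors,
#' `Vcap * pyr * ga / ((Km + pyr) * (Km + ga))`.  Symmetric in the two
#' substrates and zero if either is absent.
#'
#' @param pyr,ga Substrate concentrations (mM), `>= 0`.
#' @param Km_comb Combined Michaelis constant (mM), `> 0`.
#' @param Vcap Rate capacity (U/ml == mM/min), `>= 0`.
#' @return Rate in mM/min, bounded by `Vcap`.
#' @export
aldol_addition_rate <- function(pyr, ga, Km_comb, Vcap) {
  if (any(pyr < 0) || any(ga < 0)) stop("substrate concentrations must be >= 0")
  if (any(Km_comb <= 0)) stop("Km_comb must be > 0")
  if (any(Vcap < 0)) stop("Vcap must be >= 0")
  Vcap * pyr * ga / ((Km_comb + pyr) * (Km_comb + ga))
}

#' Equilibrium constant from a standard Gibbs energy
#'
#' `Keq = exp(-dG * 1000 / (R * T))` with `R = 8.314` J/(mol K) and a 1 M
#' standard state.  For the aldol cleavage KDG <-> pyruvate + glyceraldehyde
#' the constant has units of M.
#'
#' @param dG Standard reaction Gibbs energy (kJ/mol), in the cleavage
#'   direction.
#' @param T Temperature (K), `> 0`.
#' @return Equilibrium constant (M for a 1:2 stoichiometry).
#' @examples
#' equilibrium_constant_from_dG(6.2, 323)  # ~0.0992 M
#' @export
equilibrium_constant_from_dG <- function(dG, T = 323) {
  if (any(T <= 0)) stop("temperature must be > 0")
  exp(-dG * 1000 / (8.314 * T))
}

#' Net aldol rate (positive = cleavage)
#'
#' Reversible uni-bi Michaelis-Menten rate for
#' KDG <-> pyruvate + glyceraldehyde, written in a single-denominator form
#' whose numerator vanishes exactly at the mass-action ratio
#' `pyr * ga / kdg = Keq` (Haldane consistency):
#' \deqn{v = s_{cl} V \frac{K - s_{rev}\, P G / K_{eq}'}{K_m + K + P G / K_{eq}'}}
#' where concentrations are in mM and `Keq' = 1000 * Keq` converts the 1 M
#' standard-state constant to the mM scale.  With `pyr = ga = 0` the form
#' reduces to plain Michaelis-Menten cleavage in KDG; with
#' `reverse_scale = 0` the reaction is irreversible cleavage (mechanism "A"
#' in [compare_kdg_mechanisms]).
#'
#' @param kdg,pyr,ga Concentrations (mM), `>= 0`.
#' @param Vcap Cleavage capacity (U/ml == mM/min).
#' @param Km_cleave Michaelis constant of the cleavage branch (mM); defaults
#'   to the combined addition Km in the cascade model.
#' @param Keq Cleavage equilibrium constant (M, 1 M standard state), e.g.
#'   from [equilibrium_constant_from_dG].
#' @param cleave_scale Dimensionless scale on the whole net rate (fittable).
#' @param reverse_scale Dimensionless scale on the reverse (addition) term;
#'   1 preserves the thermodynamic fixed point, 0 disables it.
#' @return Net rate in mM/min; positive in the cleavage direction, bounded
#'   in magnitude by `cleave_scale * Vcap`.
#' @export
net_aldol_rate <- function(kdg, pyr, ga, Vcap, Km_cleave, Keq,
                           cleave_scale = 1, reverse_scale = 1) {
  if (any(c(kdg, pyr, ga) < 0)) stop("concentrations must be >= 0")
  if (any(Km_cleave <= 0)) stop("Km_cleave must be > 0")
  keq_mM <- 1000 * Keq
  back <- pyr * ga / keq_mM
  cleave_scale * Vcap * (kdg - reverse_scale * back) / (Km_cleave + kdg + back)
}

#' Residual enzyme capacity after thermal deactivation
#'
#' First-order exponential decay to a zero plateau,
#' `loading0 * 2^(-t / half_life)`.
#'
#' @param loading0 Initial capacity (U/ml), `>= 0`.
#' @param half_life Half-life (h), `> 0`; `Inf` gives a constant capacity.
#' @param t Time since the enzyme was added (h), `>= 0`.
#' @return Residual capacity (U/ml).
#' @examples
#' active_capacity(0.2, 9.8, 20) / 0.2  # 24.3% residual
#' @export
active_capacity <- function(loading0, half_life, t) {
  if (any(loading0 < 0)) stop("loading0 must be >= 0")
  if (any(half_life <= 0)) stop("half_life must be > 0 (Inf allowed)")
  if (any(t < 0)) stop("t must be >= 0")
  if (is.infinite(half_life)) return(loading0 + 0 * t)
  loading0 * 2^(-t / half_life)
}

#' Spontaneous mannono-1,4-lactone hydrolysis rate
#'
#' First-order hydrolysis of the lactone to the free sugar acid at neutral
#' pH, `k_hyd * ml`.
#'
#' @param ml Lactone concentration (mM), `>= 0`.
#' @param k_hyd First-order constant (1/min), `>= 0`.
#' @return Rate in mM/min.
#' @export
lactone_hydrolysis_rate <- function(ml, k_hyd) {
  if (any(ml < 0)) stop("ml must be >= 0")
  if (any(k_hyd < 0)) stop("k_hyd must be >= 0")
  k_hyd * ml
}
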