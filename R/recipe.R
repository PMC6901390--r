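#' Enzyme loading with addition time
#'
#' @param enzyme Enzyme name (`"AldT"`, `"ManD"`, `"KDGA"`, `"LDH"`).
#' @param units Activity loading in U/ml (numerically mM/min capacity).
#' @param addition_time Time the enzyme is added (h); 0 for one-pot.
#' @return Object of class `loading`.
#' @export
loading <- function(enzyme, units, addition_time = 0) {
  if (!enzyme %in% c("AldT", "ManD", "KDGA", "LDH"))
    stop("unknown enzyme: ", enzyme)
  if (units < 0) stop("loading must be >= 0")
  if (addition_time < 0) stop("addition_time must be >= 0")
  structure(list(enzyme = enzyme, units = units,
                 addition_time = addition_time),
            class = "loading")
}

#' Reaction recipe for a cascade run
#'
#' Bundles the initial state, the enzyme loadings (with addition times for
#' sequential protocols), optional timed species spikes (e.g. supplementary
#' NADH), the operating temperature and buffer ionic strength.
#'
#' @param initial Named initial concentrations (mM); passed to
#'   [species_vector] if not already a full state vector.
#' @param loadings List of [loading] objects (at least one).
#' @param spikes Optional list of timed species additions, each a list with
#'   elements `time` (h) and `species` (named mM increments).
#' @param temperature Kelvin (default 323, i.e. 50 degrees C).
#' @param buffer_mM Buffer ionic strength (mM); recorded, not mechanistic.
#' @param label Free-text label.
#' @return Object of class `reaction_recipe`.
#' @export
reaction_recipe <- function(initial, loadings, spikes = list(),
                            temperature = 323, buffer_mM = 100,
                            label = "") {
  if (!is.numeric(initial) || is.null(names(initial)))
    stop("initial must be a named numeric vector")
  if (length(initial) != length(CASCADE_SPECIES) ||
      !identical(names(initial), CASCADE_SPECIES))
    initial <- do.call(species_vector, as.list(initial))
  if (any(initial < 0)) stop("initial concentrations must be >= 0")
  if (length(loadings) < 1) stop("at least one loading is required")
  if (!all(vapply(loadings, inherits, TRUE, "loading")))
    stop("loadings must be a list of loading() objects")
  if (temperature <= 0) stop("temperature must be > 0")
  for (sp in spikes) {
    if (is.null(sp$time) || is.null(sp$species))
      stop("each spike needs 'time' and 'species'")
    bad <- setdiff(names(sp$species), CASCADE_SPECIES)
    if (length(bad) > 0)
      stop("unknown species in spike: ", paste(bad, collapse = ", "))
  }
  names(loadings) <- vapply(loadings, `[[`, "", "enzyme")
  structure(list(initial = initial, loadings = loadings, spikes = spikes,
                 temperature = temperature, buffer_mM = buffer_mM,
                 label = label),
            class = "reaction_recipe")
}

#' @export
print.reaction_recipe <- function(x, ...) {
  cat(sprintf("<reaction_recipe> %s\n", x$label))
  nz <- x$initial[x$initial > 0]
  cat("  initial (mM):", paste(sprintf("%s=%g", names(nz), nz), collapse = ", "), "\n")
  for (l in x$loadings)
    cat(sprintf("  %s %g U/ml @ %g h\n", l$enzyme, l$units, l$addition_time))
  for (s in x$spikes)
    cat(sprintf("  spike @ %g h: %s\n", s$time,
                paste(sprintf("%s+=%g", names(s$species), s$species), collapse = ", ")))
  invisible(x)
}

#' Model options for the cascade rate system
#'
#' Tunable constants that are not part of the measured enzyme kinetics.
#'
#' @param k_hyd First-order lactone hydrolysis constant (1/min).
#' @param k_gaox Dimensionless scale of the glyceraldehyde oxidation side
#'   reaction relative to the AldT capacity; 0 disables it.
#' @param Km_cof Cofactor Michaelis constant (mM) used for the saturable
#'   NAD+ factor of AldT and the NADH factor of LDH.
#' @param cofactor_dependence If `FALSE` the cofactor factors are fixed at 1
#'   (useful for limiting-case analysis against closed-form solutions).
#' @param dG_cleave Standard Gibbs energy of aldol cleavage (kJ/mol).
#' @param cleave_scale Dimensionless scale on the net aldol rate (fittable).
#' @param reverse_scale Dimensionless scale on the aldol reverse (addition)
#'   term: 1 = thermodynamically consistent reversible step, 0 =
#'   irreversible cleavage.
#' @param Km_cleave Cleavage-branch Km (mM); `NULL` uses the combined
#'   addition Km of KDGA.
#' @param Km_gaox Glyceraldehyde Km of the oxidation side reaction (mM);
#'   `NULL` uses the mannose Km of AldT.
#' @param decay If `FALSE`, thermal enzyme deactivation is switched off.
#' @return Object of class `cascade_options`.
#' @export
cascade_options <- function(k_hyd = 0.05, k_gaox = 0.05, Km_cof = 0.05,
                            cofactor_dependence = TRUE, dG_cleave = 6.2,
                            cleave_scale = 1, reverse_scale = 1,
                            Km_cleave = NULL, Km_gaox = NULL, decay = TRUE) {
  if (k_hyd < 0 || k_gaox < 0) stop("k_hyd and k_gaox must be >= 0")
  if (Km_cof < 0) stop("Km_cof must be >= 0")
  if (cleave_scale < 0 || reverse_scale < 0)
    stop("aldol scales must be >= 0")
  structure(list(k_hyd = k_hyd, k_gaox = k_gaox, Km_cof = Km_cof,
                 cofactor_dependence = cofactor_dependence,
                 dG_cleave = dG_cleave, cleave_scale = cleave_scale,
                 reverse_scale = reverse_scale, Km_cleave = Km_cleave,
                 Km_gaox = Km_gaox, decay = decay),
            class = "cascade_options")
}

#' Assemble the cascade derivative function
#'
#' Builds the time-dependent right-hand side of the cascade ODE system over
#' the canonical species vector.  Reactions: AldT oxidizes MAN to ML with
#' NAD+ reduction; ML hydrolyses spontaneously to MA; ManD dehydrates MA to
#' KDG; KDGA interconverts KDG and PYR + GA (net reversible aldol, see
#' [net_aldol_rate]); LDH reduces PYR to LA with NADH oxidation; and an
#' optional slow AldT-mediated oxidation of GA to glycerate consuming NAD+.
#' All enzyme capacities decay thermally from each enzyme's own addition
#' time ([active_capacity]); an enzyme contributes nothing before it is
#' added.  States are clipped at 0 inside the evaluation so that stiff
#' integrators can transiently undershoot without generating spurious
#' fluxes.
#'
#' @param recipe A [reaction_recipe].
#' @param params Enzyme parameter list as from [cascade_enzymes].
#' @param options A [cascade_options] object.
#' @return Function `(t, state) -> d(state)/dt` with `t` in hours and
#'   derivatives in mM/h.
#' @export
build_rate_system <- function(recipe, params = cascade_enzymes(),
                              options = cascade_options()) {
  stopifnot(inherits(recipe, "reaction_recipe"))
  bad <- setdiff(names(recipe$loadings), names(params))
  if (length(bad) > 0)
    stop("no kinetic parameters for enzyme(s): ", paste(bad, collapse = ", "))

  Keq <- equilibrium_constant_from_dG(options$dG_cleave, recipe$temperature)
  Km_cleave <- if (is.null(options$Km_cleave))
    params$KDGA$Km[["PYR_GA"]] else options$Km_cleave
  Km_gaox <- if (is.null(options$Km_gaox))
    params$AldT$Km[["MAN"]] else options$Km_gaox
  Km_MAN <- params$AldT$Km[["MAN"]]
  Km_MA <- params$ManD$Km[["MA"]]
  Km_PYR <- params$LDH$Km[["PYR"]]

  cap <- function(enzyme, t) {
    l <- recipe$loadings[[enzyme]]
    if (is.null(l)) return(0)
    if (t < l$addition_time) return(0)
    hl <- if (options$decay) params[[enzyme]]$half_life else Inf
    active_capacity(l$units, hl, t - l$addition_time)
  }
  fcof <- function(C) {
    if (!options$cofactor_dependence) return(1)
    C / (options$Km_cof + C)
  }

  function(t, state) {
    s <- pmax(state, 0)
    v_aldt <- cap("AldT", t) * s[["MAN"]] / (Km_MAN + s[["MAN"]]) *
      fcof(s[["NADp"]])
    v_hyd <- options$k_hyd * s[["ML"]]
    v_mand <- cap("ManD", t) * s[["MA"]] / (Km_MA + s[["MA"]])
    v_ald <- net_aldol_rate(s[["KDG"]], s[["PYR"]], s[["GA"]],
                            Vcap = cap("KDGA", t), Km_cleave = Km_cleave,
                            Keq = Keq, cleave_scale = options$cleave_scale,
                            reverse_scale = options$reverse_scale)
    v_ldh <- cap("LDH", t) * s[["PYR"]] / (Km_PYR + s[["PYR"]]) *
      fcof(s[["NADH"]])
    v_gaox <- options$k_gaox * cap("AldT", t) *
      s[["GA"]] / (Km_gaox + s[["GA"]]) * fcof(s[["NADp"]])

    # mM/min -> mM/h
    60 * c(MAN = -v_aldt,
           ML = v_aldt - v_hyd,
           MA = v_hyd - v_mand,
           KDG = v_mand - v_ald,
           PYR = v_ald - v_ldh,
           GA = v_ald - v_gaox,
           GLYA = v_gaox,
           LA = v_ldh,
           NADp = -v_aldt + v_ldh - v_gaox,
           NADH = v_aldt - v_ldh + v_gaox)
  }
}
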