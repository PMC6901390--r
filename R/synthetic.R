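#' NMR-observable cascade species
#'
#' Species whose carbon-13 integrals are tracked in the real-time
#' experiment.  Pyruvate is excluded: it is drained so fast by LDH (and
#' potentially by the reverse aldol) that its chemical shifts never appear.
#'
#' @format Character vector.
#' @export
NMR_SPECIES <- c("MAN", "ML", "MA", "KDG", "GA", "GLYA", "LA")

#' Generate a synthetic NMR relative-integral time course
#'
#' Simulates the cascade, samples it on the NMR acquisition grid (every
#' 6.5 min over 16 h by default), normalizes each observable species to its
#' maximum, then adds homoscedastic Gaussian noise (expressed as a fraction
#' of the per-species maximum, i.e. directly on the relative scale) and
#' clips at zero.
#'
#' @param recipe A [reaction_recipe] (default: the real-time NMR recipe).
#' @param params,options Model inputs.
#' @param noise_sd Additive Gaussian noise sd on the relative scale.
#' @param seed RNG seed; fixed seeds give identical output.
#' @param t_end,dt_min Acquisition span (h) and cadence (min).
#' @return A relative-integral [timecourse] over [NMR_SPECIES].
#' @export
generate_nmr_timecourse <- function(recipe = cascade_recipe("nmr"),
                                    params = cascade_enzymes(),
                                    options = cascade_options(),
                                    noise_sd = 0.02, seed = 1,
                                    t_end = 16, dt_min = 6.5) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  grid <- seq(0, t_end, by = dt_min / 60)
  tc <- simulate_onepot(recipe, t_grid = grid, params = params,
                        options = options)
  vals <- tc$values[NMR_SPECIES, , drop = FALSE]
  for (i in seq_len(nrow(vals))) vals[i, ] <- normalize_to_max(vals[i, ])
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + matrix(stats::rnorm(length(vals), sd = noise_sd),
                          nrow = nrow(vals))
    vals <- pmax(vals, 0)
  }
  timecourse(grid, vals, kind = "relative_integral")
}

#' Generate synthetic HPLC concentration time courses
#'
#' Samples the simulated cascade at discrete sampling times and adds
#' independent Gaussian noise (mM) per replicate, clipping at zero.  By
#' default mannose and lactic acid are observed at the sampling times of
#' the hydrolysate conversion experiment (0, 1, 4, 8, 10, 18 h) in
#' triplicate.
#'
#' @param recipe A [reaction_recipe].
#' @param params,options Model inputs.
#' @param noise_sd Additive noise sd (mM).
#' @param timepoints Sampling times (h).
#' @param replicates Number of replicates (`>= 1`).
#' @param species Observed species.
#' @param seed RNG seed.
#' @return List of concentration [timecourse] objects, one per replicate.
#' @export
generate_hplc_timecourse <- function(recipe = cascade_recipe("onepot_standard"),
                                     params = cascade_enzymes(),
                                     options = cascade_options(),
                                     noise_sd = 0.1,
                                     timepoints = c(0, 1, 4, 8, 10, 18),
                                     replicates = 3,
                                     species = c("MAN", "LA"), seed = 1) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  grid <- sort(unique(c(0, timepoints)))
  tc <- simulate_sequential(recipe, t_grid = grid, params = params,
                            options = options)
  base <- tc$values[species, match(timepoints, grid), drop = FALSE]
  set.seed(seed)
  lapply(seq_len(replicates), function(r) {
    vals <- base
    if (noise_sd > 0)
      vals <- pmax(base + matrix(stats::rnorm(length(base), sd = noise_sd),
                                 nrow = nrow(base)), 0)
    timecourse(timepoints, vals, kind = "concentration_mM", replicate = r)
  })
}

#' Generate a synthetic residual-activity decay assay
#'
#' Exponential decay to a zero plateau, `2^(-t / half_life)`, with additive
#' Gaussian noise clipped at zero; emulates residual-activity measurements
#' of an enzyme incubated at operating temperature.
#'
#' @param half_life True half-life (h), `> 0` (`Inf` = stable enzyme).
#' @param timepoints Assay times (h); the default covers a 20 h incubation.
#' @param noise_sd Additive noise sd (fraction of initial activity).
#' @param seed RNG seed.
#' @return List with `times` and `activity` (fractions of initial).
#' @export
generate_decay_assay <- function(half_life,
                                 timepoints = c(0, 1, 2, 4, 6, 8, 16, 20),
                                 noise_sd = 0.05, seed = 1) {
  if (half_life <= 0) stop("half_life must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  truth <- if (is.infinite(half_life)) rep(1, length(timepoints))
           else 2^(-timepoints / half_life)
  act <- truth
  if (noise_sd > 0) {
    set.seed(seed)
    act <- pmax(truth + stats::rnorm(length(truth), sd = noise_sd), 0)
  }
  list(times = timepoints, activity = act)
}
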