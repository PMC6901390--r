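#' Normalize a series to its maximum
#'
#' Rescales so that the maximum equals 1, mirroring the reporting of NMR
#' peak integrals relative to the maximal integral occurring during the
#' reaction.  An all-zero series is returned unchanged with attribute
#' `all_zero = TRUE`.
#'
#' @param series Numeric vector, `>= 0`.
#' @return Rescaled vector with maximum 1 (or the input, flagged, if it has
#'   no positive maximum).
#' @export
normalize_to_max <- function(series) {
  m <- max(series)
  if (m <= 0) {
    attr(series, "all_zero") <- TRUE
    return(series)
  }
  series / m
}

#' Fit a thermal-deactivation half-life
#'
#' Least-squares fit of `A(t) = A0 * 2^(-t / t_half)` with the plateau
#' constrained to zero, as used for residual-activity assays of heat-labile
#' enzymes.  Non-decaying data yield `t_half = Inf` with a warning.
#'
#' @param times Assay times (h), at least 3 points.
#' @param activities Residual activities as fraction of initial, in
#'   `[0, 1.2]`.
#' @return List with `half_life` (h), `A0`, `residual_norm` and `converged`.
#' @examples
#' t <- 0:8
#' fit_half_life(t, 2^(-t / 2))$half_life  # 2
#' @export
fit_half_life <- function(times, activities) {
  if (length(times) < 3) stop("at least 3 time points are required")
  if (length(times) != length(activities)) stop("length mismatch")
  if (any(activities < 0) || any(activities > 1.2))
    stop("activities must be fractions of initial in [0, 1.2]")
  pos <- activities > 0
  slope <- if (sum(pos) >= 2)
    stats::coef(stats::lm(log(activities[pos]) ~ times[pos]))[2] else 0
  if (!is.finite(slope) || slope >= 0) {
    warning("activities do not decay; returning an infinite half-life")
    return(list(half_life = Inf, A0 = mean(activities),
                residual_norm = sqrt(sum((activities - mean(activities))^2)),
                converged = TRUE))
  }
  start <- c(A0 = max(activities), th = as.numeric(-log(2) / slope))
  fit <- minpack.lm::nls.lm(
    par = start,
    lower = c(1e-6, 1e-6), upper = c(2, 1e6),
    fn = function(p) activities - p[1] * 2^(-times / p[2]))
  list(half_life = unname(fit$par[2]), A0 = unname(fit$par[1]),
       residual_norm = sqrt(fit$deviance),
       converged = fit$info %in% 1:4)
}

# --- cascade parameter plumbing ---------------------------------------------

FREE_PARAM_NAMES <- c("Vcap_AldT", "Vcap_ManD", "Vcap_KDGA", "Vcap_LDH",
                      "Km_AldT", "Km_ManD", "Km_KDGA", "Km_LDH",
                      "k_hyd", "k_gaox", "cleave_scale", "reverse_scale",
                      "Km_cof", "half_life_AldT", "half_life_ManD")

default_bounds <- function(free) {
  lo <- c(Vcap_AldT = 0.005, Vcap_ManD = 0.005, Vcap_KDGA = 0.005,
          Vcap_LDH = 0.05, Km_AldT = 0.5, Km_ManD = 0.5, Km_KDGA = 0.5,
          Km_LDH = 0.5, k_hyd = 0.002, k_gaox = 0.002, cleave_scale = 0.05,
          reverse_scale = 1e-4, Km_cof = 0.001, half_life_AldT = 0.5,
          half_life_ManD = 0.1)
  hi <- c(Vcap_AldT = 2, Vcap_ManD = 2, Vcap_KDGA = 5, Vcap_LDH = 50,
          Km_AldT = 100, Km_ManD = 100, Km_KDGA = 100, Km_LDH = 100,
          k_hyd = 1, k_gaox = 1, cleave_scale = 20, reverse_scale = 20,
          Km_cof = 5, half_life_AldT = 50, half_life_ManD = 20)
  list(lower = lo[free], upper = hi[free])
}

#' Specification of a cascade fit
#'
#' @param free Character vector of free parameter names; any of the enzyme
#'   capacities (`Vcap_AldT` ... `Vcap_LDH`, U/ml), Michaelis constants
#'   (`Km_AldT` ...), the auxiliary rates `k_hyd` and `k_gaox`, the aldol
#'   scales `cleave_scale` and `reverse_scale`, the cofactor Km and the two
#'   finite half-lives.
#' @param lower,upper Named bounds (finite, positive); defaults cover
#'   physically plausible ranges per parameter.
#' @param n_starts Number of multi-starts; starting points are drawn
#'   log-uniformly within the bounds (the first start is the geometric
#'   mid-point of the bounds, so a single-start fit is deterministic even
#'   without a seed).
#' @param seed RNG seed for the multi-start draws.
#' @param species Species whose series enter the residuals; `NULL` = all
#'   species present in the data.
#' @return Object of class `fit_spec`.
#' @export
fit_spec <- function(free, lower = NULL, upper = NULL, n_starts = 5,
                     seed = 1, species = NULL) {
  if (length(free) < 1) stop("at least one free parameter is required")
  bad <- setdiff(free, FREE_PARAM_NAMES)
  if (length(bad) > 0)
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  b <- default_bounds(free)
  if (!is.null(lower)) b$lower[names(lower)] <- lower
  if (!is.null(upper)) b$upper[names(upper)] <- upper
  if (any(!is.finite(b$lower)) || any(!is.finite(b$upper)) ||
      any(b$lower <= 0) || any(b$upper <= b$lower))
    stop("bounds must be finite, positive and ordered")
  structure(list(free = free, lower = b$lower, upper = b$upper,
                 n_starts = n_starts, seed = seed, species = species),
            class = "fit_spec")
}

apply_free_params <- function(values, recipe, params, options) {
  for (nm in names(values)) {
    v <- values[[nm]]
    if (grepl("^Vcap_", nm)) {
      enz <- sub("^Vcap_", "", nm)
      if (is.null(recipe$loadings[[enz]]))
        recipe$loadings[[enz]] <- loading(enz, v)
      else recipe$loadings[[enz]]$units <- v
    } else if (grepl("^Km_", nm) && nm != "Km_cof") {
      enz <- sub("^Km_", "", nm)
      params[[enz]]$Km[[1]] <- v
    } else if (grepl("^half_life_", nm)) {
      enz <- sub("^half_life_", "", nm)
      params[[enz]]$half_life <- v
    } else {
      options[[nm]] <- v
    }
  }
  list(recipe = recipe, params = params, options = options)
}

#' Model prediction on a time grid
#'
#' Simulates the cascade and returns the trajectory restricted to the
#' requested species, optionally normalized per species to its maximum
#' (relative-integral scale).
#'
#' @param recipe,params,options Model inputs as for [simulate_sequential].
#' @param times Report times (h).
#' @param species Species subset (default: all).
#' @param kind Output scale.
#' @param solver_opts Solver overrides (fits use a slightly relaxed
#'   tolerance for speed).
#' @return A [timecourse].
#' @export
cascade_predict <- function(recipe, params = cascade_enzymes(),
                            options = cascade_options(), times,
                            species = CASCADE_SPECIES,
                            kind = c("concentration_mM", "relative_integral"),
                            solver_opts = list()) {
  kind <- match.arg(kind)
  grid <- if (times[1] > 0) c(0, times) else times
  tc <- simulate_sequential(recipe, t_grid = grid, params = params,
                            options = options, solver_opts = solver_opts)
  vals <- tc$values[species, match(times, grid), drop = FALSE]
  if (kind == "relative_integral") {
    for (i in seq_len(nrow(vals))) {
      m <- max(vals[i, ])
      if (m > 1e-12) vals[i, ] <- vals[i, ] / m
    }
  }
  timecourse(times, vals, kind = kind, replicate = tc$replicate)
}

#' Fit cascade parameters to a time course
#'
#' Bounded least squares (Levenberg-Marquardt) on the residuals between a
#' measured time course and the simulated cascade, with seeded multi-start
#' to guard against local minima.  For relative-integral data the model
#' prediction is normalized per species to its own maximum before the
#' residuals are formed, mirroring the fact that absolute NMR intensities
#' are not comparable across peaks.
#'
#' @param tc A [timecourse] (`concentration_mM` or `relative_integral`).
#' @param spec A [fit_spec].
#' @param recipe The [reaction_recipe] that generated (or models) the data.
#' @param params,options Fixed model inputs; free parameters override them.
#' @param solver_opts Solver settings for the fit simulations (default
#'   rtol 1e-6 / atol 1e-9).
#' @return Object of class `fit_result`: `estimates`, `se` (approximate
#'   standard errors from the residual Jacobian), `residual_norm`,
#'   `converged`, `at_bound`, `n_starts`, `seed`, `n_obs`.  Deterministic
#'   given the seed and data.
#' @export
fit_cascade_params <- function(tc, spec, recipe,
                               params = cascade_enzymes(),
                               options = cascade_options(),
                               solver_opts = list(rtol = 1e-6, atol = 1e-9)) {
  stopifnot(inherits(tc, "timecourse"), inherits(spec, "fit_spec"))
  species <- if (is.null(spec$species)) rownames(tc$values)
             else intersect(spec$species, rownames(tc$values))
  obs <- tc$values[species, , drop = FALSE]
  n_obs <- length(obs)

  # Observations are additive-noise draws clipped at zero, so near the
  # detection floor their mean is E[max(m + e, 0)] = m Phi(m/s) + s phi(m/s)
  # rather than m itself; fitting against the censored mean removes the
  # upward bias that plain residuals acquire on near-zero stretches.
  censored_mean <- function(m, s) {
    z <- m / s
    m * stats::pnorm(z) + s * stats::dnorm(z)
  }
  make_resid_fn <- function(sigma) function(p) {
    p <- stats::setNames(as.numeric(p), spec$free)
    mod <- apply_free_params(p, recipe, params, options)
    pred <- tryCatch(
      cascade_predict(mod$recipe, mod$params, mod$options, tc$times,
                      species = species, kind = tc$kind,
                      solver_opts = solver_opts)$values,
      error = function(e) NULL)
    if (is.null(pred)) return(rep(1e3, n_obs))
    if (sigma > 0) pred <- censored_mean(pred, sigma)
    as.vector(obs - pred)
  }
  resid_fn <- make_resid_fn(0)

  k <- length(spec$free)
  starts <- matrix(sqrt(spec$lower * spec$upper), nrow = 1)
  if (spec$n_starts > 1) {
    set.seed(spec$seed)
    draws <- matrix(stats::runif((spec$n_starts - 1) * k), ncol = k)
    extra <- exp(log(matrix(spec$lower, spec$n_starts - 1, k, byrow = TRUE)) +
                 draws * log(matrix(spec$upper / spec$lower,
                                    spec$n_starts - 1, k, byrow = TRUE)))
    starts <- rbind(starts, extra)
  }
  colnames(starts) <- spec$free

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = spec$lower,
                         upper = spec$upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(estimates = stats::setNames(rep(NA_real_, k), spec$free),
                          se = NULL, residual_norm = NA_real_,
                          converged = FALSE, at_bound = NULL,
                          n_starts = spec$n_starts, seed = spec$seed,
                          n_obs = n_obs),
                     class = "fit_result"))

  # refine against the censored mean once the noise scale is known
  sigma_hat <- sqrt(best$deviance / max(n_obs - k, 1))
  if (sigma_hat > 1e-6) {
    resid_fn <- make_resid_fn(sigma_hat)
    refined <- tryCatch(
      minpack.lm::nls.lm(par = best$par, lower = spec$lower,
                         upper = spec$upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(refined)) best <- refined
  }

  est <- stats::setNames(as.numeric(best$par), spec$free)
  se <- tryCatch({
    J <- numeric_jacobian(resid_fn, est)
    sigma2 <- best$deviance / max(n_obs - k, 1)
    sqrt(pmax(diag(sigma2 * solve(crossprod(J))), 0))
  }, error = function(e) rep(NA_real_, k))
  names(se) <- spec$free
  tol_b <- 1e-8 + 1e-6 * (spec$upper - spec$lower)
  at_bound <- est <= spec$lower + tol_b | est >= spec$upper - tol_b

  structure(list(estimates = est, se = se,
                 residual_norm = sqrt(best$deviance),
                 converged = best$info %in% 1:4, at_bound = at_bound,
                 n_starts = spec$n_starts, seed = spec$seed, n_obs = n_obs),
            class = "fit_result")
}

numeric_jacobian <- function(fn, par, rel_h = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- rel_h * max(abs(par[j]), 1e-8)
    p <- par; p[j] <- p[j] + h
    J[, j] <- (fn(p) - f0) / h
  }
  J
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (x$converged) "converged" else "NOT converged",
      sprintf("(residual norm %.4g, %d obs, %d starts, seed %s)\n",
              x$residual_norm, x$n_obs, x$n_starts, x$seed))
  for (nm in names(x$estimates))
    cat(sprintf("  %-14s %.5g (se %.3g)%s\n", nm, x$estimates[[nm]],
                x$se[[nm]], if (isTRUE(x$at_bound[[nm]])) " [at bound]" else ""))
  invisible(x)
}

#' Compare irreversible vs reversible aldol mechanisms for KDG
#'
#' Fits the biphasic KDG behaviour under two mechanisms: model A treats the
#' aldolase step as irreversible cleavage only (`reverse_scale = 0`), model
#' B keeps the thermodynamically constrained reverse aldol addition and
#' frees its scale.  Models are ranked by an AIC-style score
#' `n * log(SSR / n) + 2 k`; ties (within `1e-8`) go to the model with
#' fewer parameters, and at equal complexity to the irreversible model.
#'
#' @param tc A [timecourse] including a KDG series.
#' @param recipe,params,options Model inputs as for [fit_cascade_params].
#' @param free Additional free parameters shared by both mechanisms
#'   (default: the cleavage scale).
#' @param n_starts,seed Multi-start settings for both fits.
#' @return List with per-model `fit`, `ssr`, `k`, `aic`, and `selected`
#'   (`"A"` or `"B"`).
#' @export
compare_kdg_mechanisms <- function(tc, recipe, params = cascade_enzymes(),
                                   options = cascade_options(),
                                   free = "cleave_scale",
                                   n_starts = 1, seed = 1) {
  if (!"KDG" %in% rownames(tc$values))
    stop("time course must include a KDG series")
  free <- setdiff(free, "reverse_scale")
  opts_A <- options; opts_A$reverse_scale <- 0
  spec_A <- fit_spec(free, n_starts = n_starts, seed = seed)
  spec_B <- fit_spec(c(free, "reverse_scale"), n_starts = n_starts,
                     seed = seed)
  fit_A <- fit_cascade_params(tc, spec_A, recipe, params, opts_A)
  fit_B <- fit_cascade_params(tc, spec_B, recipe, params, options)

  n <- fit_A$n_obs
  score <- function(f) n * log(f$residual_norm^2 / n) + 2 * length(f$estimates)
  aic_A <- if (fit_A$converged || is.finite(fit_A$residual_norm)) score(fit_A) else Inf
  aic_B <- if (fit_B$converged || is.finite(fit_B$residual_norm)) score(fit_B) else Inf
  selected <- if (abs(aic_A - aic_B) < 1e-8) {
    if (length(fit_A$estimates) <= length(fit_B$estimates)) "A" else "B"
  } else if (aic_A < aic_B) "A" else "B"

  list(A = list(fit = fit_A, ssr = fit_A$residual_norm^2,
                k = length(fit_A$estimates), aic = aic_A),
       B = list(fit = fit_B, ssr = fit_B$residual_norm^2,
                k = length(fit_B$estimates), aic = aic_B),
       selected = selected)
}
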