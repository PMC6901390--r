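# Independent numerical oracles used to validate the ODE machinery.

# Implicit closed-form Michaelis-Menten progress curve for a single
# irreversible enzyme: Km * ln(S0/S) + (S0 - S) = Vcap_integrated(t).
# Solved for S by bisection at each requested time.
mm_progress_oracle <- function(S0, Km, Vcap_mM_min, t_h) {
  vapply(t_h, function(t) {
    rhs <- Vcap_mM_min * 60 * t
    if (rhs == 0) return(S0)
    f <- function(S) Km * log(S0 / S) + (S0 - S) - rhs
    stats::uniroot(f, lower = S0 * 1e-12, upper = S0, tol = 1e-13)$root
  }, 0)
}

# Fixed-step classical Runge-Kutta integrator over the cascade derivative
# function; reports the state at the requested grid times.
rk4_oracle <- function(rhs, y0, t_grid, dt = 0.001) {
  t <- t_grid[1]
  y <- y0
  out <- matrix(NA_real_, length(y0), length(t_grid),
                dimnames = list(names(y0), NULL))
  out[, 1] <- y
  for (i in seq_along(t_grid)[-1]) {
    while (t < t_grid[i] - 1e-12) {
      h <- min(dt, t_grid[i] - t)
      k1 <- rhs(t, y)
      k2 <- rhs(t + h / 2, y + h / 2 * k1)
      k3 <- rhs(t + h / 2, y + h / 2 * k2)
      k4 <- rhs(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[, i] <- y
  }
  out
}
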