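test_that("Michaelis-Menten rate matches hand arithmetic and its bounds", {
  expect_equal(michaelis_menten_rate(9.73, 9.73, 0.2), 0.1)
  expect_equal(michaelis_menten_rate(0, 9.73, 0.2), 0)
  expect_equal(michaelis_menten_rate(5, 9.73, 0.2), 0.2 * 5 / 14.73)
  # monotone nondecreasing in S, bounded by Vcap
  S <- seq(0, 200, by = 5)
  v <- michaelis_menten_rate(S, 9.73, 0.2)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= 0.2))
  expect_error(michaelis_menten_rate(-1, 9.73, 0.2), ">= 0")
  expect_error(michaelis_menten_rate(1, 0, 0.2), "> 0")
})

test_that("aldol addition rate is symmetric, zero without a co-substrate", {
  expect_equal(aldol_addition_rate(0, 10, 8.07, 0.4), 0)
  expect_equal(aldol_addition_rate(8.07, 8.07, 8.07, 0.4), 0.1)
  expect_equal(aldol_addition_rate(5, 5, 8.07, 0.4), 0.4 * 25 / 13.07^2)
  set.seed(42)
  for (i in 1:20) {
    p <- runif(1, 0, 40); g <- runif(1, 0, 40)
    expect_equal(aldol_addition_rate(p, g, 8.07, 0.4),
                 aldol_addition_rate(g, p, 8.07, 0.4))
    expect_lte(aldol_addition_rate(p, g, 8.07, 0.4), 0.4)
  }
})

test_that("equilibrium constant follows exp(-dG/RT) at the 1 M standard state", {
  expect_equal(equilibrium_constant_from_dG(0, 323), 1)
  expect_lt(equilibrium_constant_from_dG(500, 323), 1e-50)
  expect_equal(equilibrium_constant_from_dG(6.2, 323),
               exp(-6200 / (8.314 * 323)))
  expect_equal(equilibrium_constant_from_dG(6.2, 323), 0.0992,
               tolerance = 2e-3)
  expect_error(equilibrium_constant_from_dG(6.2, -1), "> 0")
})

test_that("net aldol rate vanishes exactly at the mass-action ratio Keq", {
  Keq <- equilibrium_constant_from_dG(6.2, 323)
  expect_equal(net_aldol_rate(0, 0, 0, 0.4, 8.07, Keq), 0)
  # pick states on the equilibrium manifold: pyr*ga/kdg = 1000*Keq (mM)
  set.seed(7)
  for (i in 1:20) {
    kdg <- runif(1, 0.01, 5); pyr <- runif(1, 0.01, 5)
    ga <- 1000 * Keq * kdg / pyr
    expect_equal(net_aldol_rate(kdg, pyr, ga, 0.4, 8.07, Keq), 0,
                 tolerance = 1e-12)
  }
  # sign agrees with the displacement from equilibrium; magnitude <= Vcap
  set.seed(8)
  for (i in 1:50) {
    kdg <- runif(1, 0, 5); pyr <- runif(1, 0, 5); ga <- runif(1, 0, 5)
    v <- net_aldol_rate(kdg, pyr, ga, 0.4, 8.07, Keq)
    expect_equal(sign(v), sign(kdg - pyr * ga / (1000 * Keq)))
    expect_lte(abs(v), 0.4)
  }
  # reverse_scale = 0 reduces to plain MM cleavage in KDG with pyr = ga = 0
  expect_equal(net_aldol_rate(3, 0, 0, 0.4, 8.07, Keq, reverse_scale = 0),
               michaelis_menten_rate(3, 8.07, 0.4))
})

test_that("thermal deactivation halves capacity every half-life, plateau zero", {
  expect_equal(active_capacity(0.2, 9.8, 0), 0.2)
  expect_equal(active_capacity(0.2, 9.8, 9.8), 0.1)
  expect_equal(active_capacity(0.2, 9.8, 20) / 0.2, 2^(-20 / 9.8))
  expect_equal(active_capacity(0.2, 9.8, 20) / 0.2, 0.243, tolerance = 1e-3)
  # stable enzymes keep constant capacity
  expect_equal(active_capacity(11.6, Inf, c(0, 10, 20)), rep(11.6, 3))
  expect_error(active_capacity(0.2, 9.8, -1), ">= 0")
  expect_error(active_capacity(0.2, 0, 1), "> 0")
})

test_that("lactone hydrolysis is first order", {
  expect_equal(lactone_hydrolysis_rate(0, 0.05), 0)
  expect_equal(lactone_hydrolysis_rate(2, 0), 0)
  expect_equal(lactone_hydrolysis_rate(2, 0.05), 0.1)
  expect_error(lactone_hydrolysis_rate(-1, 0.05), ">= 0")
})

test_that("catalytic efficiencies recompute from kcat and Km", {
  p <- cascade_enzymes()
  expect_equal(round(catalytic_efficiency(p$AldT), 2), 0.26)
  expect_equal(round(catalytic_efficiency(p$KDGA), 2), 1.30)
  expect_equal(round(catalytic_efficiency(p$LDH), 2), 10.65)
})
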