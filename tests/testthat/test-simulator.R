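std_grid <- seq(0, 18, by = 0.25)

test_that("zero loadings leave all species constant", {
  recipe <- reaction_recipe(species_vector(MAN = 5, NADp = 5),
                            list(loading("AldT", 0)), label = "blank")
  tc <- simulate_onepot(recipe, t_grid = std_grid,
                        options = cascade_options(k_hyd = 0))
  expect_equal(tc$values[, ncol(tc$values)], tc$values[, 1])
})

test_that("standard one-pot run respects stoichiometric bounds", {
  tc <- simulate_onepot(cascade_recipe("onepot_standard"), t_grid = std_grid)
  la18 <- tc_species(tc, "LA")[length(std_grid)]
  expect_gt(la18, 0)
  expect_lte(la18, 5)
  expect_lt(tc_species(tc, "MAN")[length(std_grid)], 5)
})

test_that("conservation, non-negativity and monotonicity hold on simulation", {
  tc <- simulate_onepot(cascade_recipe("onepot_standard"), t_grid = std_grid)
  cb <- carbon_balance(tc)
  nb <- nad_balance(tc)
  expect_lt(max(abs(cb - cb[1])) / cb[1], 1e-6)
  expect_lt(max(abs(nb - nb[1])) / nb[1], 1e-6)
  expect_true(all(tc$values >= 0))
  expect_true(all(diff(tc_species(tc, "LA")) >= -1e-8))
  expect_true(all(diff(tc_species(tc, "MAN")) <= 1e-8))
})

test_that("single-enzyme limit reproduces the closed-form progress curve", {
  # AldT alone, stable, cofactor-independent: mannose follows the implicit
  # Michaelis-Menten progress curve Km ln(S0/S) + S0 - S = Vcap t
  recipe <- reaction_recipe(species_vector(MAN = 10, NADp = 1000),
                            list(loading("AldT", 0.2)), label = "aldt-only")
  opts <- cascade_options(decay = FALSE, cofactor_dependence = FALSE,
                          k_gaox = 0)
  grid <- seq(0, 10, by = 0.25)
  tc <- simulate_onepot(recipe, t_grid = grid, options = opts)
  oracle <- mm_progress_oracle(10, 9.73, 0.2, grid)
  expect_equal(tc_species(tc, "MAN"), oracle, tolerance = 1e-6)
})

test_that("adaptive solution agrees with a fixed-step RK4 oracle", {
  recipe <- cascade_recipe("onepot_standard")
  grid <- seq(0, 18, by = 1)
  tc <- simulate_onepot(recipe, t_grid = grid)
  rhs <- build_rate_system(recipe)
  ref <- rk4_oracle(rhs, recipe$initial, grid, dt = 0.001)
  # relative to the overall concentration scale (5 mM substrate)
  expect_lt(max(abs(tc$values - ref)) / 5, 1e-4)
})

test_that("sequential run with a single t=0 event equals the one-pot run", {
  recipe <- cascade_recipe("onepot_standard")
  a <- simulate_onepot(recipe, t_grid = std_grid)
  b <- simulate_sequential(recipe, t_grid = std_grid)
  expect_equal(a$values, b$values)
})

test_that("sequential protocol honours addition times and NADH spike", {
  recipe <- cascade_recipe("sequential")
  grid <- seq(0, 18.5, by = 0.1)
  tc <- simulate_sequential(recipe, t_grid = grid)
  la <- tc_species(tc, "LA")
  kdg <- tc_species(tc, "KDG")
  # no LA before LDH is added at 17.5 h
  expect_true(all(la[grid < 17.5] == 0))
  expect_gt(la[length(grid)], 0)
  # KDG appears only after KDGA-independent production by ManD (1.5 h);
  # here production starts with ManD, so KDG stays 0 before 1.5 h
  expect_true(all(kdg[grid < 1.5] == 0))
  expect_gt(max(kdg[grid > 16.5]), 0)
  # cofactor total steps from 20 to 30 mM at the NADH spike and is
  # conserved between events
  nb <- nad_balance(tc)
  expect_equal(nb[grid < 17.5], rep(20, sum(grid < 17.5)), tolerance = 1e-6)
  expect_equal(nb[grid >= 17.5], rep(30, sum(grid >= 17.5)), tolerance = 1e-6)
})

test_that("events outside the simulated span are a configuration error", {
  recipe <- cascade_recipe("sequential")
  expect_error(simulate_sequential(recipe, t_grid = seq(0, 10, by = 0.5)),
               "outside the simulation span")
})

test_that("doubling capacities and rates while halving time rescales exactly", {
  recipe <- cascade_recipe("onepot_standard")
  opts <- cascade_options(decay = FALSE)
  tc1 <- simulate_onepot(recipe, t_grid = seq(0, 8, by = 0.5), options = opts)
  recipe2 <- recipe
  for (e in names(recipe2$loadings))
    recipe2$loadings[[e]]$units <- 2 * recipe2$loadings[[e]]$units
  opts2 <- cascade_options(decay = FALSE, k_hyd = 2 * opts$k_hyd)
  tc2 <- simulate_onepot(recipe2, t_grid = seq(0, 4, by = 0.25),
                         options = opts2)
  expect_equal(tc1$values, tc2$values, tolerance = 1e-7)
})

test_that("carbon and cofactor balances follow the carbon census", {
  tc <- timecourse(c(0, 1), matrix(c(5, 5, 0, 0), nrow = 2, byrow = TRUE,
                                   dimnames = list(c("MAN", "LA"), NULL)),
                   kind = "concentration_mM")
  expect_equal(carbon_balance(tc), c(30, 30))
  tc2 <- timecourse(c(0, 1), matrix(c(2, 2, 2, 2), nrow = 2,
                                    dimnames = list(c("PYR", "GA"), NULL)),
                    kind = "concentration_mM")
  expect_equal(carbon_balance(tc2), c(12, 12))
  rel <- timecourse(c(0, 1), matrix(c(1, 1), nrow = 1,
                                    dimnames = list("KDG", NULL)),
                    kind = "relative_integral")
  expect_error(carbon_balance(rel), "concentration")
})
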