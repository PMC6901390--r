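test_that("half-life fit is exact on noiseless exponential decay", {
  t <- 0:8
  fit <- fit_half_life(t, 2^(-t / 2))
  expect_equal(fit$half_life, 2, tolerance = 1e-6)
  expect_equal(fit$A0, 1, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("non-decaying activities yield an infinite half-life with warning", {
  expect_warning(fit <- fit_half_life(0:5, rep(1, 6)), "decay")
  expect_equal(fit$half_life, Inf)
  expect_error(fit_half_life(c(0, 1), c(1, 0.5)), "at least 3")
  expect_error(fit_half_life(0:3, c(1, 2, 1, 1)), "1.2")
})

test_that("half-life is recovered from a noisy synthetic assay", {
  assay <- generate_decay_assay(9.8, noise_sd = 0.05, seed = 2)
  fit <- fit_half_life(assay$times, assay$activity)
  expect_lt(abs(fit$half_life - 9.8) / 9.8, 0.15)
})

test_that("zero-noise cascade fit recovers the generating parameter", {
  tc <- generate_nmr_timecourse(noise_sd = 0)
  fit <- fit_cascade_params(tc, fit_spec("Vcap_ManD", n_starts = 1),
                            cascade_recipe("nmr"))
  expect_true(fit$converged)
  expect_equal(fit$estimates[["Vcap_ManD"]], 0.1, tolerance = 1e-3)
})

test_that("cascade fits are reproducible bit-for-bit under a fixed seed", {
  tc <- generate_nmr_timecourse(noise_sd = 0.02, seed = 31)
  sp <- fit_spec("Vcap_ManD", n_starts = 2, seed = 31)
  f1 <- fit_cascade_params(tc, sp, cascade_recipe("nmr"))
  f2 <- fit_cascade_params(tc, sp, cascade_recipe("nmr"))
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$residual_norm, f2$residual_norm)
})

test_that("a free parameter whose truth sits at a bound is flagged", {
  # data generated without the reverse aldol term under a low-LDH recipe
  # where reverse_scale is identifiable; its truth (0) lies below the lower
  # bound, so the fit must be driven onto the bound and flagged
  rec <- reaction_recipe(species_vector(MAN = 10, NADp = 10),
                         list(loading("AldT", 0.2), loading("ManD", 0.1),
                              loading("KDGA", 0.4), loading("LDH", 0.1)),
                         label = "low-ldh")
  opts0 <- cascade_options(reverse_scale = 0)
  tc <- generate_nmr_timecourse(rec, options = opts0, noise_sd = 0)
  sp <- fit_spec("reverse_scale", n_starts = 1)
  fit <- fit_cascade_params(tc, sp, rec)
  expect_true(fit$at_bound[["reverse_scale"]])
  expect_equal(fit$estimates[["reverse_scale"]], sp$lower[["reverse_scale"]])
})

test_that("parameter recovery on noisy synthetic truth is accurate", {
  rs <- get_recovery_study()
  expect_true(all(rs$converged))
  for (p in unique(rs$parameter)) {
    sub <- rs[rs$parameter == p, ]
    # mean bias below 10%
    expect_lt(abs(mean(sub$rel_error)), 0.10)
    # truth covered by +/- 2 SE in at least 80% of replicates
    expect_gte(mean(sub$covered), 0.80)
  }
})

test_that("mechanism selection prefers parsimony on equal fits", {
  # equal SSR and equal k would tie; the reported tie-break rule is fewer
  # parameters first, then the irreversible mechanism
  tc <- generate_nmr_timecourse(noise_sd = 0, seed = 1)
  cmp <- compare_kdg_mechanisms(tc, cascade_recipe("nmr"), n_starts = 1)
  expect_true(cmp$selected %in% c("A", "B"))
  expect_equal(cmp$B$k, cmp$A$k + 1)
  if (abs(cmp$A$aic - cmp$B$aic) < 1e-8) expect_equal(cmp$selected, "A")
})

test_that("mechanism comparison identifies the truth when reverse flux is material", {
  # with LDH lowered to 0.1 U/ml pyruvate accumulates to ~1.5 mM, so the
  # reverse aldol addition visibly reshapes the KDG trace and the two
  # mechanisms are distinguishable from a single noisy time course
  rec <- reaction_recipe(species_vector(MAN = 10, NADp = 10),
                         list(loading("AldT", 0.2), loading("ManD", 0.1),
                              loading("KDGA", 0.4), loading("LDH", 0.1)),
                         label = "low-ldh")
  tc_b <- generate_nmr_timecourse(rec, options = cascade_options(),
                                  noise_sd = 0.02, seed = 11)
  cmp_b <- compare_kdg_mechanisms(tc_b, rec, seed = 11)
  expect_equal(cmp_b$selected, "B")
  tc_a <- generate_nmr_timecourse(rec,
                                  options = cascade_options(reverse_scale = 0),
                                  noise_sd = 0.02, seed = 12)
  cmp_a <- compare_kdg_mechanisms(tc_a, rec, seed = 12)
  expect_equal(cmp_a$selected, "A")
})

test_that("mechanism comparison requires a KDG series", {
  tc <- timecourse(c(0, 1), matrix(c(5, 4), nrow = 1,
                                   dimnames = list("MAN", NULL)),
                   kind = "concentration_mM")
  expect_error(compare_kdg_mechanisms(tc, cascade_recipe("nmr")), "KDG")
})
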