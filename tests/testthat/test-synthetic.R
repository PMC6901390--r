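test_that("noise-free NMR generation equals the normalized simulation", {
  tc <- generate_nmr_timecourse(noise_sd = 0)
  sim <- simulate_onepot(cascade_recipe("nmr"),
                         t_grid = seq(0, 16, by = 6.5 / 60))
  for (sp in NMR_SPECIES) {
    ref <- tc_species(sim, sp)
    expect_equal(tc_species(tc, sp), as.numeric(normalize_to_max(ref)))
    expect_equal(max(tc_species(tc, sp)), 1)
  }
  expect_false("PYR" %in% rownames(tc$values))
  expect_equal(tc$kind, "relative_integral")
})

test_that("generators are deterministic under a fixed seed", {
  a <- generate_nmr_timecourse(noise_sd = 0.02, seed = 99)
  b <- generate_nmr_timecourse(noise_sd = 0.02, seed = 99)
  expect_identical(a$values, b$values)
  h1 <- generate_hplc_timecourse(seed = 7)
  h2 <- generate_hplc_timecourse(seed = 7)
  expect_identical(lapply(h1, `[[`, "values"), lapply(h2, `[[`, "values"))
  expect_length(h1, 3)
  expect_equal(vapply(h1, `[[`, 0L, "replicate"), 1:3)
})

test_that("NMR course shows fast mannose depletion and early LA rise", {
  tc <- generate_nmr_timecourse(noise_sd = 0)
  man <- tc_species(tc, "MAN")
  la <- tc_species(tc, "LA")
  # mannose mostly gone within the first 3 h
  expect_lt(man[which.min(abs(tc$times - 3))], 0.15)
  # steepest LA increase falls in the first 2 h
  rate <- diff(la) / diff(tc$times)
  expect_lt(tc$times[which.max(rate)], 2)
})

test_that("HPLC sampling stays within noise bounds of the simulation", {
  reps <- generate_hplc_timecourse(noise_sd = 0.1, replicates = 3, seed = 5)
  noiseless <- generate_hplc_timecourse(noise_sd = 0, replicates = 1)[[1]]
  for (r in reps) {
    expect_equal(r$times, c(0, 1, 4, 8, 10, 18))
    la18 <- tc_species(r, "LA")[6]
    expect_lt(abs(la18 - tc_species(noiseless, "LA")[6]), 3 * 0.1 + 1e-9)
  }
})

test_that("decay assays reproduce the exponential with zero plateau", {
  a <- generate_decay_assay(2, timepoints = c(0, 2), noise_sd = 0)
  expect_equal(a$activity, c(1, 0.5))
  b <- generate_decay_assay(Inf, noise_sd = 0)
  expect_true(all(b$activity == 1))
  # half-life 1.4 h leaves ~5% activity at 6 h, below assay sensitivity
  d <- generate_decay_assay(1.4, timepoints = 6, noise_sd = 0)
  expect_equal(d$activity, 0.0513, tolerance = 1e-3)
  expect_error(generate_decay_assay(-1), "> 0")
})

test_that("normalization to the maximum flags all-zero series", {
  expect_equal(normalize_to_max(c(0, 2, 4, 2)), c(0, 0.5, 1, 0.5))
  expect_equal(normalize_to_max(c(0, 0.5, 1)), c(0, 0.5, 1))
  z <- normalize_to_max(c(0, 0, 0))
  expect_true(attr(z, "all_zero"))
  expect_equal(as.numeric(z), c(0, 0, 0))
})
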