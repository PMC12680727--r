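w_axis <- default_axis()

test_that("pseudo-Voigt references peak at their tabulated centers", {
  one <- build_reference(band_table(638, fwhm = 20), w_axis)
  expect_equal(one$wavenumber[which.max(one$intensity)], 638)
  expect_error(band_table(numeric(0)), "at least one band")
  expect_error(build_reference(band_table(2100), w_axis), "outside the axis")

  two <- build_reference(band_table(c(638, 725), fwhm = 10,
                                    amplitude = c(1, 1)),
                         w_axis, normalize = FALSE)
  h638 <- two$intensity[two$wavenumber == 638]
  h725 <- two$intensity[two$wavenumber == 725]
  expect_equal(h638, h725, tolerance = 1e-9)
})

test_that("the default library encodes the serum band structure", {
  lib <- default_library()
  expect_equal(unname(sqrt(colSums(lib$spectra^2))), rep(1, 3),
               tolerance = 1e-12)
  in_win <- lib$wavenumber >= 1650 & lib$wavenumber <= 1660
  bound <- lib$spectra[, "uric_acid_hsa"]
  free <- lib$spectra[, "uric_acid_free"]
  # HSA-bound form: local maximum inside 1650-1660; free form: nothing
  expect_equal(lib$wavenumber[which.max(bound * in_win)], 1659)
  widew <- lib$wavenumber >= 1600 & lib$wavenumber <= 1750
  expect_lt(max(free[widew]), 0.05 * max(free))
  hypo <- lib$spectra[, "hypoxanthine"]
  expect_lte(abs(lib$wavenumber[which.max(hypo)] - 725), 1)
})

test_that("cohort generation is deterministic and linear in components", {
  lib <- default_library(components = "uric_acid")
  cfg <- cohort_config(n_donors = 6, seed = 5,
                       components = list(uric_acid = list(median = 280,
                                                          gsd = 1.3,
                                                          response = 1)),
                       baseline_range = NULL, noise_sd = 0, scale_gsd = 1)
  g1 <- generate_cohort(cfg, lib)
  g2 <- generate_cohort(cfg, lib)
  expect_identical(g1$set$intensity, g2$set$intensity)
  expect_identical(g1$truth, g2$truth)
  # single component, no baseline/noise: rows are exact multiples
  ref <- lib$spectra[, 1]
  for (i in 1:6) {
    expect_equal(g1$set$intensity[i, ],
                 g1$truth$conc_uric_acid[i] * ref, tolerance = 1e-12)
  }
})

test_that("component concentrations are drawn independently", {
  lib <- default_library(components = c("uric_acid", "hypoxanthine"))
  cfg <- cohort_config(n_donors = 200, components = serum_components(),
                       seed = 9)
  g <- generate_cohort(cfg, lib)
  rho <- cor(g$truth$conc_uric_acid, g$truth$conc_hypoxanthine,
             method = "spearman")
  expect_lt(abs(rho), 0.15)
})

test_that("generator seeding does not disturb the caller's RNG stream", {
  lib <- default_library(components = c("uric_acid", "hypoxanthine"))
  set.seed(123)
  draw_direct <- c(runif(1), runif(1))
  set.seed(123)
  r1 <- runif(1)
  invisible(generate_cohort(cohort_config(n_donors = 2,
                                          components = serum_components(),
                                          seed = 77), lib))
  expect_identical(c(r1, runif(1)), draw_direct)
})

test_that("spiking changes only the analyte contribution", {
  lib <- default_library(components = c("uric_acid", "hypoxanthine"))
  cfg <- cohort_config(components = serum_components(), seed = 4)
  base <- c(uric_acid = 280, hypoxanthine = 10)

  null_spike <- simulate_spike(base, "uric_acid", 0, cfg, lib)
  expect_identical(null_spike$unspiked$intensity,
                   null_spike$spiked$intensity)
  expect_error(simulate_spike(base, "uric_acid", -5, cfg, lib), ">= 0")
  expect_error(simulate_spike(base, "glucose", 10, cfg, lib),
               "not in the library")

  # noiseless, no baseline, analyte alone: doubling doubles everything
  cfg0 <- cohort_config(components = list(uric_acid = list(median = 280,
                                                           gsd = 1.3,
                                                           response = 1)),
                        baseline_range = NULL, noise_sd = 0,
                        scale_gsd = 1, seed = 4)
  lib1 <- default_library(components = "uric_acid")
  sp <- simulate_spike(c(uric_acid = 280), "uric_acid", 280, cfg0, lib1)
  expect_equal(sp$spiked$intensity, 2 * sp$unspiked$intensity,
               tolerance = 1e-12)
})

test_that("a two-fold uric-acid spike doubles the 638 band", {
  # noiseless serum-like mixture, true-model evaluation
  cfg <- cohort_config(components = serum_components(),
                       baseline_range = NULL, noise_sd = 0,
                       scale_gsd = 1, seed = 4)
  lib <- default_library(components = c("uric_acid", "hypoxanthine"))
  sp <- simulate_spike(c(uric_acid = 280, hypoxanthine = 10),
                       "uric_acid", 280, cfg, lib)
  at638 <- which(sp$unspiked$wavenumber == 638)
  ratio <- sp$spiked$intensity[at638] / sp$unspiked$intensity[at638]
  expect_equal(ratio, 2, tolerance = 0.01)
})

test_that("isotopologue substitution rewrites only the mapped centers", {
  tab <- default_band_table("uric_acid_hsa")
  expect_identical(isotopologue_bands(tab, numeric(0)), tab)

  shifted <- isotopologue_bands(tab, c("1659" = 1653))
  expect_equal(sum(shifted$center != tab$center), 1)
  expect_true(1653 %in% shifted$center)

  two <- isotopologue_bands(tab, c("1659" = 1653, "867" = 860))
  expect_equal(sum(two$center != tab$center), 2)
  expect_identical(two$fwhm, tab$fwhm)
  expect_identical(two$amplitude, tab$amplitude)
  expect_identical(two$eta, tab$eta)

  expect_error(isotopologue_bands(tab, c("999" = 990)), "does not match")
})
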