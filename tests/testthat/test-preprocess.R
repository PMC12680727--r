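test_that("cropping keeps the closed interval and rejects empty results", {
  s <- sers_spectrum(seq(350, 1900, by = 1), rexp(1551))
  cr <- crop(s, 400, 1800)
  expect_gte(min(cr$wavenumber), 400)
  expect_lte(max(cr$wavenumber), 1800)
  expect_true(all(c(400, 1800) %in% cr$wavenumber))  # closed interval
  expect_equal(crop(s, 350, 1900)$intensity, s$intensity)
  expect_error(crop(s, 2000, 2100), "fewer than 2")
})

test_that("modpoly reproduces polynomial-only and constant inputs", {
  w <- default_axis()
  u <- (w - 400) / 1400
  poly4 <- 200 + 80 * u - 50 * u^2 + 30 * u^3 - 60 * u^4
  res <- modpoly_baseline(sers_spectrum(w, poly4), degree = 4)
  expect_true(res$converged)
  expect_lt(max(abs(res$corrected)), 1e-6 * diff(range(poly4)))

  const <- modpoly_baseline(sers_spectrum(w, rep(5, 1401)), degree = 0)
  expect_equal(const$baseline, rep(5, 1401), tolerance = 1e-12)
  expect_equal(const$corrected, rep(0, 1401), tolerance = 1e-12)

  expect_error(modpoly_baseline(sers_spectrum(400:410, rep(1, 11)),
                                degree = 12), "exceed")
})

test_that("modpoly recovers a polynomial background under positive bands", {
  w <- default_axis()
  u <- (w - 400) / 1400
  true_base <- 150 + 60 * u - 90 * u^2
  peaks <- build_reference(band_table(c(640, 1000, 1450), fwhm = 14,
                                      amplitude = c(1, 0.6, 0.8)),
                           w, normalize = FALSE)$intensity * 80
  res <- modpoly_baseline(sers_spectrum(w, true_base + peaks), degree = 2)
  off_peak <- peaks < 0.01 * max(peaks)
  err <- res$baseline[off_peak] - true_base[off_peak]
  expect_lt(sqrt(mean(err^2)), 0.02 * sqrt(mean(true_base^2)))
  # baseline stays at/below the raw signal up to a small tolerance
  expect_lt(max(res$baseline - (true_base + peaks)),
            0.01 * diff(range(true_base + peaks)))
})

test_that("vector normalization has unit norm, idempotence and shape", {
  s <- vector_normalize(sers_spectrum(c(400, 401), c(3, 4)))
  expect_equal(s$intensity, c(0.6, 0.8))
  expect_equal(attr(s, "norm_factor"), 5)

  again <- vector_normalize(s)
  expect_equal(again$intensity, s$intensity, tolerance = 1e-12)

  set.seed(1)
  r <- sers_spectrum(400:499, rexp(100) + 0.1)
  nr <- vector_normalize(r)
  expect_equal(sqrt(sum(nr$intensity^2)), 1, tolerance = 1e-12)
  ratios_in <- r$intensity[-1] / r$intensity[-100]
  ratios_out <- nr$intensity[-1] / nr$intensity[-100]
  expect_equal(ratios_out, ratios_in, tolerance = 1e-12)

  expect_error(vector_normalize(sers_spectrum(400:402, rep(0, 3))),
               "all-zero")
})

test_that("the full chain is scale-invariant and recovers pure components", {
  w <- default_axis()
  lib <- default_library(components = "uric_acid")
  u <- (w - 400) / 1400
  base <- 60 - 20 * u + 15 * u^2
  y <- 280 * lib$spectra[, 1] + base
  raw <- sers_set(list(sers_spectrum(w, y, sample = "a"),
                       sers_spectrum(w, 3.7 * y, sample = "b")))
  pp <- preprocess_set(raw)
  expect_equal(unname(sqrt(rowSums(pp$intensity^2))), c(1, 1),
               tolerance = 1e-12)
  # scalar multiples map to the same preprocessed spectrum
  expect_equal(pp$intensity[2, ], pp$intensity[1, ], tolerance = 1e-8)
  # noiseless single-component mixture comes back as the reference.
  # Baseline correction removes the smooth pedestal formed by the
  # overlapping Lorentzian wings, so the right comparison is against
  # the identically preprocessed pure compound.
  expect_gt(sum(pp$intensity[1, ] * lib$spectra[, 1]), 0.99)
  pure <- preprocess_set(sers_set(list(
    sers_spectrum(w, 280 * lib$spectra[, 1], sample = "pure"))))
  expect_gt(sum(pp$intensity[1, ] * pure$intensity[1, ]), 0.999)
  expect_true(all(pp$meta$baseline_converged))
  expect_equal(pp$meta$norm_factor[2] / pp$meta$norm_factor[1], 3.7,
               tolerance = 1e-3)
})

test_that("preprocessing an empty set or a bad member behaves as promised", {
  empty <- sers_set(list())
  expect_equal(n_spectra(preprocess_set(empty)), 0)

  bad <- sers_set(list(sers_spectrum(400:410, rep(0, 11), sample = "z")))
  expect_error(preprocess_set(bad, lo = 400, hi = 410, degree = 2),
               "'z'")
})
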