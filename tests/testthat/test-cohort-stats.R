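make_two_component_cohort <- function(n = 81, seed = 9, snr = 50,
                                      baseline = TRUE, scale_gsd = 1.2) {
  lib <- default_library(components = c("uric_acid", "hypoxanthine"))
  cfg <- cohort_config(n_donors = n, components = serum_components(),
                       baseline_range = if (baseline)
                         default_baseline_range() else NULL,
                       snr = snr, scale_gsd = scale_gsd, seed = seed)
  g <- generate_cohort(cfg, lib)
  list(gen = g, lib = lib)
}

test_that("band intensities are extracted at or near the stated positions", {
  w <- default_axis()
  one <- build_reference(band_table(900, fwhm = 14), w)
  set <- sers_set(list(sers_spectrum(w, one$intensity, sample = "a")))
  m <- band_intensity_matrix(set, 900, tol = 3)
  expect_equal(m[1, 1], max(one$intensity))

  m0 <- band_intensity_matrix(set, c(890, 900), tol = 0)
  expect_equal(unname(m0[1, ]),
               one$intensity[match(c(890, 900), w)])

  expect_error(band_intensity_matrix(set, 2000), "outside the axis")
})

test_that("the 638-band column tracks true uric-acid concentration", {
  cc <- make_two_component_cohort(n = 40, seed = 17)
  corrected <- preprocess_set(cc$gen$set, normalize = FALSE)
  m <- band_intensity_matrix(corrected, 638, tol = 3)
  # raw-count heights carry scale * concentration; divide the known
  # per-donor enhancement factor out to isolate the concentration signal
  h <- m[, 1] / cc$gen$truth$scale
  expect_gt(cor(h, cc$gen$truth$conc_uric_acid), 0.9)
})

test_that("anchor correlation report follows rank-correlation identities", {
  set.seed(23)
  x <- matrix(rexp(60), nrow = 20,
              dimnames = list(NULL, c(600, 700, 800)))
  x[, 2] <- exp(x[, 1])          # monotone transform of the anchor
  class(x) <- c("band_intensity_matrix", class(x))
  rep <- spearman_with_anchor(x, anchor = 600, tau = 0.6)
  expect_equal(rep$rho[rep$band == 600], 1)
  expect_equal(rep$rho[rep$band == 700], 1)
  expect_true(rep$member[rep$band == 700])

  x[, 3] <- 5  # constant column: undefined, flagged, excluded
  expect_warning(rep2 <- spearman_with_anchor(x, anchor = 600), "constant")
  expect_true(is.na(rep2$rho[rep2$band == 800]))
  expect_false(rep2$member[rep2$band == 800])

  expect_error(spearman_with_anchor(x, anchor = 999), "not a matrix column")
})

test_that("membership is stable under donor permutation", {
  cc <- make_two_component_cohort(n = 30, seed = 29)
  corrected <- preprocess_set(cc$gen$set, normalize = FALSE)
  bands <- c(638, 725, 890, 1130)
  m <- band_intensity_matrix(corrected, bands)
  r1 <- spearman_with_anchor(m, 638)
  perm <- sample(nrow(m))
  m2 <- m[perm, , drop = FALSE]
  class(m2) <- class(m)
  r2 <- spearman_with_anchor(m2, 638)
  expect_equal(r2$member, r1$member)
  expect_equal(r2$rho, r1$rho, tolerance = 1e-12)
})

test_that("PCA handles degenerate, rank-1 and low-rank cohorts", {
  w <- 400:449
  flat <- sers_set(lapply(1:4, function(i) {
    sers_spectrum(w, rep(2, 50), sample = paste0("s", i))
  }))
  expect_error(run_pca(flat, 2), "degenerate")

  a <- rexp(50); b <- rexp(50)
  line <- sers_set(lapply(seq(0, 1, length.out = 6), function(t) {
    sers_spectrum(w, (1 - t) * a + t * b, sample = paste0("t", t))
  }))
  pc <- run_pca(line, 2)
  expect_equal(pc$explained[1], 1, tolerance = 1e-9)

  expect_error(run_pca(line, 6), "exceeds")

  cc <- make_two_component_cohort(n = 40, seed = 37, baseline = FALSE)
  pp <- preprocess_set(cc$gen$set)
  pc2 <- run_pca(pp, 5)
  expect_gte(pc2$cumulative[2], 0.95)
  # sign convention: dominant loading element positive
  for (j in 1:5) {
    expect_gt(pc2$loadings[which.max(abs(pc2$loadings[, j])), j], 0)
  }
})

test_that("full-rank PCA reconstructs the centered data", {
  set.seed(43)
  w <- 400:429
  set <- new_set_for_test(8, w)
  pc <- run_pca(set, n_components = 7)
  centered <- scale(set$intensity, center = pc$center, scale = FALSE)
  recon <- pc$scores %*% t(pc$loadings)
  expect_lt(max(abs(recon - centered)), 1e-8)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-9)
  # loadings are orthonormal
  expect_equal(crossprod(pc$loadings), diag(7), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("loadings are matched to components and contrasts by cosine", {
  lib <- default_library(components = c("uric_acid", "hypoxanthine"))
  w <- lib$wavenumber
  set.seed(47)
  # cohort of scalar multiples of one component plus noise
  one <- sers_set(lapply(1:12, function(i) {
    sers_spectrum(w, runif(1, 0.5, 2) * lib$spectra[, 1] +
                    rnorm(1401, 0, 1e-4), sample = paste0("s", i))
  }))
  pc <- run_pca(one, 2)
  ml <- match_loadings(pc, lib)
  expect_gte(abs(ml$components["PC1", "uric_acid"]), 0.95)

  orth <- list(explained = 1, cumulative = 1,
               loadings = matrix(rep(c(1, -1), length.out = 1401), ncol = 1),
               scores = matrix(0, 1, 1), wavenumber = w, center = rep(0, 1401))
  class(orth) <- "pca_result"
  # alternating sign vector is essentially orthogonal to smooth bands
  ml2 <- match_loadings(orth, lib)
  expect_lt(abs(ml2$components[1, "uric_acid"]), 0.05)
})
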