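test_that("sub-pixel shifting matches hand-computed interpolation", {
  w <- 400:499
  set.seed(3)
  y <- rexp(100)
  expect_identical(shift_component(y, w, 0), y)

  line <- 5 + 0.3 * w
  sh <- shift_component(line, w, 0.07)
  expect_equal(sh[-1], (5 + 0.3 * (w - 0.07))[-1], tolerance = 1e-12)

  # +0.1 on a 1 cm^-1 grid: interior points are 0.9 y[i] + 0.1 y[i-1]
  sh2 <- shift_component(y, w, 0.1)
  expect_equal(sh2[-1], 0.9 * y[-1] + 0.1 * y[-100], tolerance = 1e-12)

  expect_error(shift_component(y, w, 0.2, bound = 0.1), "exceeds")
})

test_that("the SSR objective agrees with a brute-force oracle", {
  lib <- toy_library(50)
  set.seed(11)
  target <- rexp(50)
  expect_equal(objective_ssr(c(0, 0), c(0, 0), target, lib),
               sum(target^2))
  exact <- drop(lib$spectra %*% c(2, 3))
  expect_equal(objective_ssr(c(2, 3), c(0, 0), exact, lib), 0,
               tolerance = 1e-20)
  for (i in 1:5) {
    a <- rexp(2); s <- runif(2, -0.1, 0.1)
    expect_equal(objective_ssr(a, s, target, lib),
                 brute_ssr(a, s, target, lib), tolerance = 1e-12)
  }
})

test_that("exact combinations are recovered to optimizer precision", {
  lib <- toy_library(60)
  target <- drop(lib$spectra %*% c(2, 3))
  fit <- fit_decomposition(target, lib)
  expect_equal(unname(fit$amplitudes), c(2, 3), tolerance = 1e-6)
  expect_true(all(abs(fit$shifts) <= 0.1))
  expect_gte(fit$r_squared, 0.999999)
  expect_true(fit$converged)
})

test_that("an orthogonal component gets amplitude zero (grid-search check)", {
  # comp2 far from the target's support: the non-negativity bound binds
  lib <- toy_library(50, centers = c(15, 40), width = 3)
  target <- 1.5 * lib$spectra[, 1]
  fit <- fit_decomposition(target, lib)
  expect_lt(fit$amplitudes[2], 1e-8)
  gs <- grid_search_fit(target, lib, 0.1, a_max = 3, n_a = 31, n_s = 5)
  expect_lte(fit$ssr, gs$value + 1e-10)
  expect_lt(abs(gs$amplitudes[2]), 0.11)  # grid step
})

test_that("an injected sub-pixel shift is recovered", {
  lib <- toy_library(60)
  shifted <- shift_component(lib$spectra[, 1], lib$wavenumber, 0.1)
  fit <- fit_decomposition(2 * shifted, lib)
  expect_equal(unname(fit$shifts[1]), 0.1, tolerance = 0.02)
  expect_gte(fit$r_squared, 0.9999)
})

test_that("the bounded optimizer is at least as good as exhaustive search", {
  set.seed(21)
  lib <- toy_library(55, centers = c(20, 38), width = 6)
  for (i in 1:3) {
    a_true <- runif(2, 0.5, 2)
    s_true <- runif(2, -0.08, 0.08)
    target <- a_true[1] *
      shift_component(lib$spectra[, 1], lib$wavenumber, s_true[1]) +
      a_true[2] *
      shift_component(lib$spectra[, 2], lib$wavenumber, s_true[2]) +
      rnorm(55, 0, 0.002)
    fit <- fit_decomposition(target, lib)
    gs <- grid_search_fit(target, lib, 0.1, a_max = 3, n_a = 31, n_s = 9)
    expect_lte(fit$ssr, gs$value + 1e-8)
  }
})

test_that("with shift bound zero the fit reduces to non-negative LS", {
  set.seed(31)
  lib <- toy_library(50)
  for (i in 1:5) {
    target <- rexp(50) - 0.3  # sign-indefinite so bounds activate
    fit <- fit_decomposition(target, lib, shift_bound = 0)
    oracle <- nnls_enumerate(lib$spectra, target)
    expect_equal(unname(fit$amplitudes), oracle$x, tolerance = 1e-8)
    expect_equal(fit$ssr, oracle$ssr, tolerance = 1e-8)
    expect_equal(unname(fit$shifts), c(0, 0))
  }
})

test_that("amplitudes scale linearly with the target", {
  lib <- toy_library(60)
  set.seed(41)
  target <- drop(lib$spectra %*% c(1.2, 0.7)) + rnorm(60, 0, 0.01)
  f1 <- fit_decomposition(target, lib)
  f5 <- fit_decomposition(5 * target, lib)
  expect_equal(unname(f5$amplitudes), unname(5 * f1$amplitudes),
               tolerance = 1e-4)
  expect_equal(f5$shifts, f1$shifts, tolerance = 1e-3)
  expect_equal(f5$r_squared, f1$r_squared, tolerance = 1e-9)
})

test_that("the optimum never degrades the NNLS initialization", {
  set.seed(51)
  lib <- toy_library(50)
  for (i in 1:5) {
    target <- rexp(50)
    fit <- fit_decomposition(target, lib)
    a0 <- pracma::lsqnonneg(lib$spectra, target)$x
    init_ssr <- objective_ssr(a0, c(0, 0), target, lib)
    expect_lte(fit$ssr, init_ssr + 1e-12)
  }
})

test_that("figures of merit match their definitions", {
  obs <- c(1, 2, 3, 4, 5, 4, 3)
  perfect <- figures_of_merit(obs, obs, n_params = 2)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$nrmse, 0)

  flat <- figures_of_merit(obs, rep(mean(obs), 7), n_params = 2,
                           noise_sd = 1)
  expect_equal(flat$r_squared, 0)

  expect_error(figures_of_merit(rep(2, 7), rep(2, 7), n_params = 2),
               "zero variance")
})

test_that("reduced chi-squared is calibrated on known-noise residuals", {
  set.seed(61)
  n <- 1000
  truth <- sin(seq(0, 6, length.out = n)) + 2
  sigma <- 0.05
  observed <- truth + rnorm(n, 0, sigma)
  fom <- figures_of_merit(observed, truth, n_params = 6, noise_sd = sigma)
  expect_gt(fom$red_chisq, 0.85)
  expect_lt(fom$red_chisq, 1.15)
})

test_that("bootstrap CIs are seeded, degenerate-safe and ordered", {
  expect_error(bootstrap_fom(0.9), "at least 2")

  same <- bootstrap_fom(rep(0.95, 20))
  expect_equal(same$lower, 0.95)
  expect_equal(same$upper, 0.95)

  set.seed(71)
  vals <- rnorm(81, 0.95, 0.01)
  ci1 <- bootstrap_fom(vals, B = 500, seed = 3)
  ci2 <- bootstrap_fom(vals, B = 500, seed = 3)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$median)
  expect_gte(ci1$upper, ci1$median)
})

test_that("cohort fitting of exact combinations gives perfect medians", {
  lib <- toy_library(60)
  set.seed(81)
  spectra <- lapply(1:5, function(i) {
    sers_spectrum(lib$wavenumber, drop(lib$spectra %*% rexp(2)),
                  sample = paste0("s", i))
  })
  cf <- fit_cohort(sers_set(spectra), lib, noise_sd = NA, B = 100, seed = 1)
  expect_equal(cf$summary$r_squared$median, 1, tolerance = 1e-9)
  expect_true(all(cf$table$converged))
  expect_true(is.na(cf$summary$red_chisq$median))  # noiseless: undefined
})
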