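# Independent oracles and fixture builders used across the tests.
# Everything here deliberately avoids the package's own computational
# paths (interpolation, optimizers), so agreement is evidence, not
# circularity.

# Brute-force sum of squared residuals with hand-rolled linear
# interpolation and explicit loops.
brute_ssr <- function(amplitudes, shifts, target, library) {
  w <- library$wavenumber
  n <- length(w)
  fitted <- numeric(n)
  for (k in seq_along(amplitudes)) {
    comp <- library$spectra[, k]
    for (i in seq_len(n)) {
      x <- w[i] - shifts[k]
      if (x <= w[1]) {
        v <- comp[1]
      } else if (x >= w[n]) {
        v <- comp[n]
      } else {
        j <- max(which(w <= x))
        f <- (x - w[j]) / (w[j + 1] - w[j])
        v <- (1 - f) * comp[j] + f * comp[j + 1]
      }
      fitted[i] <- fitted[i] + amplitudes[k] * v
    }
  }
  sum((target - fitted)^2)
}

# Hand-rolled linear interpolation of one component at axis - s.
brute_shift <- function(comp, w, s) {
  n <- length(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- w[i] - s
    if (x <= w[1]) {
      out[i] <- comp[1]
    } else if (x >= w[n]) {
      out[i] <- comp[n]
    } else {
      j <- max(which(w <= x))
      f <- (x - w[j]) / (w[j + 1] - w[j])
      out[i] <- (1 - f) * comp[j] + f * comp[j + 1]
    }
  }
  out
}

# Exhaustive grid search over (a1, a2, s1, s2) for 2-component toys.
# Shifted components are precomputed with brute_shift; the amplitude
# grid is then scanned with plain vector arithmetic.
grid_search_fit <- function(target, library, shift_bound,
                            a_max, n_a = 41, n_s = 11) {
  a_grid <- seq(0, a_max, length.out = n_a)
  s_grid <- if (shift_bound > 0) {
    seq(-shift_bound, shift_bound, length.out = n_s)
  } else 0
  w <- library$wavenumber
  sh1 <- lapply(s_grid, function(s) brute_shift(library$spectra[, 1], w, s))
  sh2 <- lapply(s_grid, function(s) brute_shift(library$spectra[, 2], w, s))
  best <- list(value = Inf)
  for (i1 in seq_along(s_grid)) for (i2 in seq_along(s_grid)) {
    c1 <- sh1[[i1]]; c2 <- sh2[[i2]]
    for (a1 in a_grid) {
      part <- target - a1 * c1
      for (a2 in a_grid) {
        v <- sum((part - a2 * c2)^2)
        if (v < best$value) {
          best <- list(value = v, amplitudes = c(a1, a2),
                       shifts = s_grid[c(i1, i2)])
        }
      }
    }
  }
  best
}

# Non-negative least squares by exhaustive KKT enumeration: for each of
# the 2^K active sets, solve the unconstrained LS on the free
# coordinates and keep the feasible solution with the smallest SSR.
# Exact for small K; independent of pracma and of the package optimizer.
nnls_enumerate <- function(A, b) {
  K <- ncol(A)
  best <- NULL
  for (mask in 0:(2^K - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
    x <- numeric(K)
    if (length(free) > 0) {
      Af <- A[, free, drop = FALSE]
      x[free] <- solve(crossprod(Af), crossprod(Af, b))
    }
    if (all(x >= -1e-12)) {
      ssr <- sum((b - A %*% pmax(x, 0))^2)
      if (is.null(best) || ssr < best$ssr) {
        best <- list(x = pmax(x, 0), ssr = ssr)
      }
    }
  }
  best
}

# Small toy library on a short axis (K pseudo-Voigt-free components:
# simple Gaussians so shapes are smooth but not the package defaults).
toy_library <- function(n = 50, centers = c(15, 35), width = 5) {
  w <- seq_len(n)
  refs <- sapply(centers, function(c0) exp(-(w - c0)^2 / (2 * width^2)))
  colnames(refs) <- paste0("comp", seq_along(centers))
  component_library(w, refs)
}

# Serum-like two-component mixture spectrum (uric acid + hypoxanthine)
# with optional noise, on the default axis.
serum_mixture <- function(conc_ua = 280, conc_hypo = 10, resp_hypo = 7,
                          snr = NULL, seed = 1) {
  lib <- default_library(components = c("uric_acid", "hypoxanthine"))
  y <- drop(lib$spectra %*% c(conc_ua, resp_hypo * conc_hypo))
  if (!is.null(snr)) {
    set.seed(seed)
    y <- y + rnorm(length(y), 0, sqrt(sum(y^2)) / (snr * sqrt(length(y))))
  }
  list(spectrum = sers_spectrum(lib$wavenumber, y), library = lib)
}
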