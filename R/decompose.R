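# Shift-tolerant non-negative spectral decomposition: a target spectrum
# is modeled as sum_k a_k * shift(ref_k, s_k) with a_k >= 0 and
# |s_k| <= shift_bound (sub-pixel, default 0.1 cm^-1), minimized by
# bounded quasi-Newton (L-BFGS-B) from a non-negative least squares
# start. Figures of merit: R^2, range-normalized RMSE, reduced chi^2.

#' Shift a component spectrum by a sub-pixel displacement
#'
#' Evaluates the component at `wavenumber - s` by linear interpolation
#' (so positive `s` moves features toward higher wavenumbers); the ends
#' are extended by holding the edge value.
#'
#' @param component Numeric intensity vector on `wavenumber`.
#' @param wavenumber Axis vector.
#' @param s Shift in cm^-1, `|s| <= bound`.
#' @param bound Maximum allowed |shift| (cm^-1).
#' @return Shifted intensity vector.
#' @export
shift_component <- function(component, wavenumber, s, bound = 0.1) {
  if (abs(s) > bound + 1e-12) {
    stop("|shift| = ", abs(s), " exceeds the bound ", bound)
  }
  if (s == 0) return(component)
  stats::approx(wavenumber, component, xout = wavenumber - s, rule = 2)$y
}

#' Sum of squared residuals of a shifted non-negative combination
#'
#' @param amplitudes Numeric vector, one non-negative amplitude per
#'   component.
#' @param shifts Numeric vector of per-component shifts (cm^-1).
#' @param target Numeric target intensity vector on the library axis.
#' @param library A [component_library].
#' @param shift_bound Maximum allowed |shift|.
#' @return Scalar sum of squared residuals.
#' @export
objective_ssr <- function(amplitudes, shifts, target, library,
                          shift_bound = 0.1) {
  stopifnot(inherits(library, "component_library"),
            length(amplitudes) == n_components(library),
            length(shifts) == n_components(library),
            length(target) == length(library$wavenumber))
  fitted <- reconstruct(amplitudes, shifts, library, shift_bound)
  sum((target - fitted)^2)
}

reconstruct <- function(amplitudes, shifts, library, shift_bound = 0.1) {
  K <- n_components(library)
  fitted <- numeric(length(library$wavenumber))
  for (k in seq_len(K)) {
    fitted <- fitted + amplitudes[k] *
      shift_component(library$spectra[, k], library$wavenumber, shifts[k],
                      bound = shift_bound)
  }
  fitted
}

#' Fit a spectrum as a shifted non-negative combination of components
#'
#' Minimizes the sum of squared residuals over amplitudes `a_k >= 0`
#' and shifts `|s_k| <= shift_bound` with `stats::optim` (L-BFGS-B).
#' Amplitudes are initialized by non-negative least squares at zero
#' shift; shifts are restarted from -shift_bound/2, 0 and
#' +shift_bound/2 and the best optimum kept.
#'
#' @param target A [sers_spectrum] on the library axis (typically
#'   preprocessed), or a bare intensity vector.
#' @param library A [component_library].
#' @param shift_bound Maximum |shift| per component in cm^-1 (default
#'   0.1; 0 disables shifting and reduces the fit to non-negative least
#'   squares).
#' @param noise_sd Noise sd for the reduced chi^2; `NULL` (default)
#'   estimates it with [estimate_noise_mad()] from the highest 100
#'   axis points of the target (assumed band-poor); `NA` declares the
#'   data noise-free and leaves the reduced chi^2 undefined.
#' @return Object of class `decomposition`: `amplitudes` (named),
#'   `shifts` (named), `fitted`, `residuals`, `r_squared`, `nrmse`,
#'   `red_chisq`, `noise_sd`, `ssr`, `iterations`, `converged`.
#' @export
fit_decomposition <- function(target, library, shift_bound = 0.1,
                              noise_sd = NULL) {
  stopifnot(inherits(library, "component_library"), shift_bound >= 0)
  y <- if (inherits(target, "sers_spectrum")) target$intensity else
    as.numeric(target)
  if (length(y) != length(library$wavenumber)) {
    stop("target is not on the library axis")
  }
  K <- n_components(library)
  a0 <- pracma::lsqnonneg(library$spectra, y)$x

  if (shift_bound == 0) {
    # amplitudes-only polish of the NNLS start
    fn <- function(par) objective_ssr(par, rep(0, K), y, library, 0)
    opt <- stats::optim(a0, fn, method = "L-BFGS-B",
                        lower = rep(0, K), upper = rep(Inf, K),
                        control = list(maxit = 500, factr = 1e4))
    best <- list(par = c(opt$par, rep(0, K)), value = opt$value,
                 counts = opt$counts[["function"]],
                 convergence = opt$convergence)
  } else {
    fn <- function(par) {
      objective_ssr(par[seq_len(K)], par[K + seq_len(K)], y, library,
                    shift_bound)
    }
    lower <- c(rep(0, K), rep(-shift_bound, K))
    upper <- c(rep(Inf, K), rep(shift_bound, K))
    best <- NULL
    for (s0 in c(-shift_bound / 2, 0, shift_bound / 2)) {
      par0 <- c(a0, rep(s0, K))
      opt <- stats::optim(par0, fn, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 500, factr = 1e4,
                                         parscale = c(pmax(a0, 1e-3),
                                                      rep(shift_bound, K))))
      cand <- list(par = opt$par, value = opt$value,
                   counts = opt$counts[["function"]],
                   convergence = opt$convergence)
      if (is.null(best) || cand$value < best$value) best <- cand
    }
  }
  amplitudes <- pmax(best$par[seq_len(K)], 0)
  shifts <- best$par[K + seq_len(K)]
  names(amplitudes) <- names(shifts) <- library$names
  fitted <- reconstruct(amplitudes, shifts, library, max(shift_bound, 1e-12))
  if (is.null(noise_sd)) {
    tail_idx <- seq.int(max(1L, length(y) - 99L), length(y))
    noise_sd <- estimate_noise_mad(y[tail_idx],
                                   library$wavenumber[tail_idx])
    if (noise_sd <= 1e-10 * diff(range(y))) {
      noise_sd <- NA_real_  # no measurable noise: chi^2 scale undefined
    }
  }
  fom <- figures_of_merit(y, fitted, n_params = 2L * K, noise_sd = noise_sd)
  # L-BFGS-B reports an abnormal line search (code 52) at numerically
  # perfect optima; a vanishing residual is convergence, not failure
  conv <- best$convergence == 0 || best$value <= 1e-10 * sum(y^2)
  structure(c(list(amplitudes = amplitudes, shifts = shifts,
                   fitted = fitted, residuals = y - fitted,
                   ssr = best$value, noise_sd = noise_sd,
                   iterations = best$counts,
                   converged = conv),
              fom),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat("<decomposition>\n")
  for (k in seq_along(x$amplitudes)) {
    cat(sprintf("  %-16s a = %.4g, s = %+.4f cm^-1\n",
                names(x$amplitudes)[k], x$amplitudes[k], x$shifts[k]))
  }
  cat(sprintf("  R^2 %.4f | nRMSE %.4f | red. chi^2 %.3g | converged: %s\n",
              x$r_squared, x$nrmse, x$red_chisq, x$converged))
  invisible(x)
}

#' Goodness-of-fit figures of merit
#'
#' R^2 = 1 - SS_res/SS_tot (SS_tot about the observed mean); nRMSE =
#' sqrt(SS_res/n) normalized by the observed max - min range; reduced
#' chi^2 = SS_res / (noise_sd^2 * (n - n_params)).
#'
#' @param observed,fitted Numeric vectors of equal length n.
#' @param n_params Number of fitted parameters (n > n_params).
#' @param noise_sd Noise sd used in the reduced chi^2 (`NA` to skip).
#' @return List: `r_squared`, `nrmse`, `red_chisq`.
#' @export
figures_of_merit <- function(observed, fitted, n_params, noise_sd = NA) {
  n <- length(observed)
  stopifnot(length(fitted) == n, n > n_params)
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed spectrum has zero variance; R^2 undefined")
  rng <- diff(range(observed))
  list(r_squared = 1 - ss_res / ss_tot,
       nrmse = sqrt(ss_res / n) / rng,
       red_chisq = if (!is.finite(noise_sd) || noise_sd <= 0) NA_real_ else
         ss_res / (noise_sd^2 * (n - n_params)))
}

#' Bootstrap confidence interval for a cohort median
#'
#' Non-parametric bootstrap over donors: the cohort values (one figure
#' of merit per spectrum) are resampled with replacement `B` times and
#' a percentile interval for the median is returned.
#'
#' @param values Numeric vector of per-spectrum values (length >= 2).
#' @param B Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for reproducibility.
#' @return List: `median`, `lower`, `upper`, `level`, `B`.
#' @export
bootstrap_fom <- function(values, B = 1000, level = 0.95, seed = 1L) {
  if (length(values) < 2L) stop("need at least 2 values to bootstrap")
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    # e.g. reduced chi^2 of a noiseless cohort: undefined, not an error
    return(list(median = NA_real_, lower = NA_real_, upper = NA_real_,
                level = level, B = B))
  }
  med <- stats::median(values)
  if (max(values) == min(values)) {
    return(list(median = med, lower = med, upper = med,
                level = level, B = B))
  }
  with_seed(seed, {
    bt <- boot::boot(values, function(d, i) stats::median(d[i]), R = B)
    ci <- boot::boot.ci(bt, conf = level, type = "perc")
    list(median = med, lower = ci$percent[4L], upper = ci$percent[5L],
         level = level, B = B)
  })
}

#' Fit every spectrum of a cohort and summarize
#'
#' Runs [fit_decomposition()] on each member of a (preprocessed) set
#' and reports per-spectrum amplitudes, shifts and figures of merit,
#' cohort medians with bootstrap confidence intervals, and plot-ready
#' median curves (component contributions, fit, residual).
#'
#' @param set A preprocessed [sers_set] on the library axis.
#' @param library A [component_library].
#' @param shift_bound,noise_sd Passed to [fit_decomposition()].
#' @param B,level,seed Bootstrap settings, see [bootstrap_fom()].
#' @return Object of class `cohort_fit`: `table` (one row per
#'   spectrum: sample, a_*, s_*, r_squared, nrmse, red_chisq,
#'   converged), `summary` (named list of bootstrap CIs for the median
#'   of each figure of merit), `medians` (list of median observed /
#'   fitted / residual / per-component curves), `fits` (list of
#'   [fit_decomposition()] results).
#' @export
fit_cohort <- function(set, library, shift_bound = 0.1, noise_sd = NULL,
                       B = 1000, level = 0.95, seed = 1L) {
  stopifnot(inherits(set, "sers_set"), n_spectra(set) >= 1)
  n <- n_spectra(set)
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    fits[[i]] <- tryCatch(
      fit_decomposition(set$intensity[i, ], library,
                        shift_bound = shift_bound, noise_sd = noise_sd),
      error = function(e) stop("fit failed for spectrum '",
                               set$meta$sample[i], "': ",
                               conditionMessage(e)))
  }
  K <- n_components(library)
  amp <- t(vapply(fits, `[[`, numeric(K), "amplitudes"))
  shf <- t(vapply(fits, `[[`, numeric(K), "shifts"))
  colnames(amp) <- paste0("a_", library$names)
  colnames(shf) <- paste0("s_", library$names)
  tab <- data.frame(sample = set$meta$sample, amp, shf,
                    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
                    nrmse = vapply(fits, `[[`, numeric(1), "nrmse"),
                    red_chisq = vapply(fits, `[[`, numeric(1), "red_chisq"),
                    converged = vapply(fits, `[[`, logical(1), "converged"),
                    check.names = FALSE)
  summary <- list(
    r_squared = bootstrap_fom(tab$r_squared, B = B, level = level,
                              seed = seed),
    nrmse = bootstrap_fom(tab$nrmse, B = B, level = level, seed = seed + 1L),
    red_chisq = bootstrap_fom(tab$red_chisq, B = B, level = level,
                              seed = seed + 2L)
  )
  comp_curves <- lapply(seq_len(K), function(k) {
    m <- t(vapply(fits, function(f) {
      f$amplitudes[k] * shift_component(library$spectra[, k],
                                        library$wavenumber, f$shifts[k],
                                        bound = max(shift_bound, 1e-12))
    }, numeric(length(library$wavenumber))))
    apply(m, 2L, stats::median)
  })
  names(comp_curves) <- library$names
  medians <- list(
    wavenumber = library$wavenumber,
    observed = apply(set$intensity, 2L, stats::median),
    fitted = apply(t(vapply(fits, `[[`,
                            numeric(length(library$wavenumber)), "fitted")),
                   2L, stats::median),
    residual = apply(t(vapply(fits, `[[`,
                              numeric(length(library$wavenumber)),
                              "residuals")),
                     2L, stats::median),
    components = comp_curves
  )
  structure(list(table = tab, summary = summary, medians = medians,
                 fits = fits),
            class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cohort_fit> %d spectra\n", nrow(x$table)))
  cat(sprintf("  median R^2      %.3f (%.3f-%.3f)\n",
              s$r_squared$median, s$r_squared$lower, s$r_squared$upper))
  cat(sprintf("  median nRMSE    %.4f (%.4f-%.4f)\n",
              s$nrmse$median, s$nrmse$lower, s$nrmse$upper))
  cat(sprintf("  median red.chi2 %.3g (%.3g-%.3g)\n",
              s$red_chisq$median, s$red_chisq$lower, s$red_chisq$upper))
  invisible(x)
}
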