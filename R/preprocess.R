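# Preprocessing chain for serum SERS spectra: crop to the analysis
# range, iterative modified-polynomial (modpoly) baseline subtraction,
# vector normalization.

#' Crop a spectrum to a wavenumber interval
#'
#' Retains the points with `lo <= shift <= hi` (closed interval). The
#' conventional working range for serum SERS with 785 nm excitation is
#' 400-1800 cm^-1.
#'
#' @param spectrum A [sers_spectrum].
#' @param lo,hi Interval endpoints in cm^-1, `lo < hi`.
#' @return The cropped [sers_spectrum].
#' @export
crop <- function(spectrum, lo = 400, hi = 1800) {
  stopifnot(inherits(spectrum, "sers_spectrum"), lo < hi)
  keep <- spectrum$wavenumber >= lo & spectrum$wavenumber <= hi
  if (sum(keep) < 2L) {
    stop("crop to [", lo, ", ", hi, "] leaves fewer than 2 points")
  }
  sers_spectrum(spectrum$wavenumber[keep], spectrum$intensity[keep],
                sample = spectrum$meta$sample,
                replicate = spectrum$meta$replicate,
                group = spectrum$meta$group)
}

#' Modified-polynomial (modpoly) baseline estimation
#'
#' Iterative polynomial baseline fitting: a least-squares polynomial of
#' the given degree is fitted to the spectrum; intensities exceeding the
#' fit are clamped to it; the fit is repeated until its relative L2
#' change drops below `tol` or `max_iter` is reached. Positive bands are
#' progressively excluded from the fit, so the polynomial settles under
#' the peaks onto the smooth background.
#'
#' @param spectrum A [sers_spectrum] (finite intensities).
#' @param degree Polynomial degree (default 4, the customary choice for
#'   serum SERS backgrounds).
#' @param tol Convergence threshold: iteration stops when the largest
#'   absolute change of the fitted baseline between iterations drops
#'   below `tol` times the peak-to-peak range of the input. (A change
#'   measured relative to the baseline's own norm is dominated by the
#'   large smooth offset and can report convergence while the fit is
#'   still descending under the bands.)
#' @param max_iter Maximum number of refit iterations.
#' @return List of class `baseline_result`: `baseline`, `corrected`
#'   (input minus baseline), `iterations`, `converged`.
#' @export
modpoly_baseline <- function(spectrum, degree = 4, tol = 1e-3,
                             max_iter = 100) {
  stopifnot(inherits(spectrum, "sers_spectrum"), degree >= 0, max_iter >= 1)
  y <- spectrum$intensity
  w <- spectrum$wavenumber
  if (length(y) <= degree + 1L) {
    stop("axis length must exceed degree + 1")
  }
  if (!all(is.finite(y))) stop("non-finite intensities")
  # Orthonormal polynomial basis: the LS fit is a fixed projection Q Q' y.
  u <- (w - min(w)) / diff(range(w))
  X <- cbind(1, if (degree > 0) stats::poly(u, degree = degree) else NULL)
  Q <- qr.Q(qr(X))
  fit_poly <- function(v) drop(Q %*% crossprod(Q, v))

  rng <- diff(range(y))
  work <- y
  fit <- fit_poly(work)
  converged <- FALSE
  iter <- 1L
  while (iter < max_iter) {
    work <- pmin(work, fit)
    new_fit <- fit_poly(work)
    delta <- max(abs(new_fit - fit))
    fit <- new_fit
    iter <- iter + 1L
    if (delta <= tol * max(rng, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    message("modpoly baseline did not converge in ", max_iter, " iterations")
  }
  structure(list(baseline = fit, corrected = y - fit,
                 iterations = iter, converged = converged),
            class = "baseline_result")
}

#' Subtract the modpoly baseline from a spectrum
#'
#' Convenience wrapper around [modpoly_baseline()] returning the
#' corrected spectrum. Small negative values arising from the
#' subtraction are retained (clipping would bias band-height
#' statistics).
#'
#' @inheritParams modpoly_baseline
#' @return The corrected [sers_spectrum].
#' @export
subtract_baseline <- function(spectrum, degree = 4, tol = 1e-3,
                              max_iter = 100) {
  res <- modpoly_baseline(spectrum, degree = degree, tol = tol,
                          max_iter = max_iter)
  sers_spectrum(spectrum$wavenumber, res$corrected,
                sample = spectrum$meta$sample,
                replicate = spectrum$meta$replicate,
                group = spectrum$meta$group)
}

#' Vector normalization
#'
#' Divides the spectrum by `sqrt(sum(x_i^2))` so its Euclidean norm is
#' 1, making spectra comparable across donors regardless of absolute
#' enhancement. Idempotent; scale-invariant (normalize(c x) =
#' normalize(x) for c > 0).
#'
#' @param spectrum A [sers_spectrum]; must not be all zero.
#' @return List-free: the normalized [sers_spectrum] with the applied
#'   factor stored as attribute `"norm_factor"`.
#' @export
vector_normalize <- function(spectrum) {
  stopifnot(inherits(spectrum, "sers_spectrum"))
  nrm <- sqrt(sum(spectrum$intensity^2))
  if (nrm == 0) stop("cannot normalize an all-zero spectrum")
  out <- sers_spectrum(spectrum$wavenumber, spectrum$intensity / nrm,
                       sample = spectrum$meta$sample,
                       replicate = spectrum$meta$replicate,
                       group = spectrum$meta$group)
  attr(out, "norm_factor") <- nrm
  out
}

#' Preprocess a whole spectrum set
#'
#' Applies the standard chain to each member: crop to `[lo, hi]`,
#' modpoly baseline subtraction, then (optionally) vector
#' normalization. The per-spectrum normalization factor and baseline
#' convergence flag are recorded in the output metadata (columns
#' `norm_factor`, `baseline_converged`), so fitted amplitudes can later
#' be mapped back to raw-count units.
#'
#' @param set A [sers_set].
#' @param lo,hi Crop interval (cm^-1).
#' @param degree,tol,max_iter Passed to [modpoly_baseline()].
#' @param normalize Apply [vector_normalize()] (default `TRUE`).
#' @return The preprocessed [sers_set].
#' @export
preprocess_set <- function(set, lo = 400, hi = 1800, degree = 4,
                           tol = 1e-3, max_iter = 100, normalize = TRUE) {
  stopifnot(inherits(set, "sers_set"))
  n <- n_spectra(set)
  if (n == 0L) return(set)
  out <- vector("list", n)
  norm_factor <- rep(NA_real_, n)
  converged <- rep(NA, n)
  for (i in seq_len(n)) {
    s <- tryCatch({
      s <- crop(get_spectrum(set, i), lo, hi)
      bl <- modpoly_baseline(s, degree = degree, tol = tol,
                             max_iter = max_iter)
      converged[i] <- bl$converged
      s <- sers_spectrum(s$wavenumber, bl$corrected,
                         sample = s$meta$sample,
                         replicate = s$meta$replicate,
                         group = s$meta$group)
      if (normalize) {
        s <- vector_normalize(s)
        norm_factor[i] <- attr(s, "norm_factor")
      }
      s
    }, error = function(e) {
      stop("preprocessing failed for spectrum '", set$meta$sample[i],
           "': ", conditionMessage(e))
    })
    out[[i]] <- s
  }
  res <- sers_set(out)
  res$meta$norm_factor <- norm_factor
  res$meta$baseline_converged <- converged
  res
}
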