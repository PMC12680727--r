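# Band-maximum detection: robust noise estimation (scaled MAD of the
# detrended signal), SuperSmoother-based smoothing, local-maximum search
# with an SNR threshold, and matching of detected peaks to reference
# band positions.

#' Robust noise-scale estimate (scaled MAD of the detrended signal)
#'
#' Detrends the signal by subtracting a smoother fit, then returns
#' `1.4826 * median(|r - median(r)|)` of the residual — a robust
#' estimate of the Gaussian noise sd that ignores bands and gross
#' outliers.
#'
#' @param intensity Numeric vector (length >= 3).
#' @param wavenumber Optional abscissa for the smoother (defaults to the
#'   point index).
#' @param method,span Passed to [smooth_spectrum()] for detrending.
#' @return Noise sd estimate (0 for an all-identical input).
#' @export
estimate_noise_mad <- function(intensity, wavenumber = seq_along(intensity),
                               method = "supsmu", span = NULL) {
  stopifnot(length(intensity) >= 3)
  if (length(unique(intensity)) == 1L) return(0)
  trend <- smooth_values(wavenumber, intensity, method = method, span = span)
  r <- intensity - trend
  stats::mad(r)
}

# Internal: smoothing on bare vectors.
smooth_values <- function(wavenumber, intensity, method = "supsmu",
                          span = NULL) {
  if (!method %in% c("supsmu", "fixed")) {
    stop("unknown smoothing method '", method,
         "'; available: supsmu, fixed")
  }
  if (method == "supsmu") {
    # Friedman's SuperSmoother: adaptive-span local linear regression.
    sp <- if (is.null(span)) 0 else span
    fit <- stats::supsmu(wavenumber, intensity, span = if (sp > 0) sp else "cv")
    out <- stats::approx(fit$x, fit$y, xout = wavenumber, rule = 2)$y
    return(out)
  }
  # Fixed-span local linear fallback (running least-squares line); gives
  # results identical to the adaptive smoother on exactly linear inputs.
  n <- length(intensity)
  k <- if (is.null(span)) max(5L, 2L * floor(0.025 * n / 2) + 1L) else {
    stopifnot(span > 0, span <= 1)
    max(5L, 2L * floor(span * n / 2) + 1L)
  }
  half <- k %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    x <- wavenumber[j] - wavenumber[i]
    y <- intensity[j]
    sx <- sum(x); sxx <- sum(x^2); sy <- sum(y); sxy <- sum(x * y)
    m <- length(j)
    det <- m * sxx - sx^2
    out[i] <- if (det > .Machine$double.eps * m * sxx + 1e-300) {
      (sxx * sy - sx * sxy) / det
    } else mean(y)
  }
  out
}

#' Smooth a spectrum
#'
#' `method = "supsmu"` uses Friedman's SuperSmoother (adaptive-span
#' local linear regression, the default); `method = "fixed"` is a
#' fixed-span local linear smoother. Both preserve a straight line
#' exactly.
#'
#' @param spectrum A [sers_spectrum].
#' @param method `"supsmu"` or `"fixed"`.
#' @param span Fraction of the points in the smoothing window; `NULL`
#'   for the method's default (cross-validated for `"supsmu"`).
#' @return The smoothed [sers_spectrum].
#' @export
smooth_spectrum <- function(spectrum, method = "supsmu", span = NULL) {
  stopifnot(inherits(spectrum, "sers_spectrum"))
  y <- smooth_values(spectrum$wavenumber, spectrum$intensity,
                     method = method, span = span)
  sers_spectrum(spectrum$wavenumber, y,
                sample = spectrum$meta$sample,
                replicate = spectrum$meta$replicate,
                group = spectrum$meta$group)
}

#' Detect band maxima
#'
#' Local maxima of the smoothed signal whose height exceeds
#' `snr_threshold` times the MAD-based noise estimate. The reported
#' position is refined to the argmax of the raw (unsmoothed) intensity
#' within `refine_window` points of the smoothed maximum, so smoothing
#' cannot bias band positions.
#'
#' @param spectrum A preprocessed [sers_spectrum] (baseline removed).
#' @param snr_threshold Minimum height / noise ratio (default 3).
#' @param method,span Smoother settings, see [smooth_spectrum()]. The
#'   default span 0.02 (about 28 points on the default axis) matches
#'   the typical SERS band width; the cross-validated adaptive span
#'   targets broad trends and oversmooths narrow Raman bands.
#' @param refine_window Half-width, in grid points, of the raw-argmax
#'   refinement window.
#' @return Data frame of class `peak_list` with columns `position`
#'   (cm^-1, strictly increasing), `height` (raw intensity at the
#'   position) and `snr`. May be empty.
#' @export
detect_peaks <- function(spectrum, snr_threshold = 3, method = "supsmu",
                         span = 0.02, refine_window = 5L) {
  stopifnot(inherits(spectrum, "sers_spectrum"), snr_threshold >= 0)
  w <- spectrum$wavenumber
  y <- spectrum$intensity
  s <- smooth_values(w, y, method = method, span = span)
  noise <- estimate_noise_mad(y, w, method = method, span = span)
  n <- length(s)
  # strict rise then non-rise, so flat plateaus do not spray maxima
  is_max <- which(diff(sign(diff(s))) < 0) + 1L
  is_max <- is_max[s[is_max] > 0]
  if (noise > 0) {
    is_max <- is_max[s[is_max] / noise >= snr_threshold]
  }
  if (length(is_max) == 0L) {
    return(empty_peak_list())
  }
  pos <- height <- numeric(length(is_max))
  for (k in seq_along(is_max)) {
    i <- is_max[k]
    j <- max(1L, i - refine_window):min(n, i + refine_window)
    jmax <- j[which.max(y[j])]
    pos[k] <- w[jmax]
    height[k] <- y[jmax]
  }
  keep <- !duplicated(pos)
  out <- data.frame(position = pos[keep], height = height[keep],
                    snr = if (noise > 0) height[keep] / noise else Inf)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

empty_peak_list <- function() {
  out <- data.frame(position = numeric(0), height = numeric(0),
                    snr = numeric(0))
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Match detected peaks to reference band positions
#'
#' Greedy nearest-neighbor matching: candidate (peak, reference) pairs
#' within `tol` are assigned in order of increasing absolute offset,
#' each peak and each reference at most once. Unmatched peaks are kept
#' with `ref = NA`.
#'
#' @param peaks A `peak_list` (from [detect_peaks()]) or numeric vector
#'   of detected positions.
#' @param reference Numeric vector of reference band centers (cm^-1).
#' @param tol Maximum |offset| for a match, > 0 (cm^-1).
#' @return Data frame: `position`, `ref`, `offset` (position - ref),
#'   `matched`.
#' @export
#' @examples
#' match_peaks(c(638, 1653), c(638, 1659), tol = 10)
match_peaks <- function(peaks, reference, tol = 3) {
  stopifnot(tol > 0)
  pos <- if (is.data.frame(peaks)) peaks$position else as.numeric(peaks)
  cand <- expand.grid(i = seq_along(pos), j = seq_along(reference))
  cand$offset <- pos[cand$i] - reference[cand$j]
  cand <- cand[abs(cand$offset) <= tol, , drop = FALSE]
  cand <- cand[order(abs(cand$offset)), , drop = FALSE]
  ref_of <- rep(NA_real_, length(pos))
  used_ref <- rep(FALSE, length(reference))
  used_peak <- rep(FALSE, length(pos))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_peak[i] && !used_ref[j]) {
      ref_of[i] <- reference[j]
      used_peak[i] <- TRUE
      used_ref[j] <- TRUE
    }
  }
  data.frame(position = pos, ref = ref_of, offset = pos - ref_of,
             matched = !is.na(ref_of))
}
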