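#' Single SERS/Raman spectrum
#'
#' A spectrum is a strictly increasing wavenumber axis (Raman shift, cm^-1)
#' with one intensity value (arbitrary-unit counts) per axis point, plus
#' free-text sample metadata.
#'
#' @param wavenumber Numeric vector of Raman shifts in cm^-1, strictly
#'   increasing, length >= 2, all finite.
#' @param intensity Numeric vector of intensities, same length as
#'   `wavenumber`, all finite.
#' @param sample Sample identifier (character).
#' @param replicate Replicate index (integer).
#' @param group Group label (character).
#'
#' @return An object of class `sers_spectrum`: a list with elements
#'   `wavenumber`, `intensity` and `meta` (one-row data frame).
#' @export
#' @examples
#' s <- sers_spectrum(400:410, runif(11), sample = "donor01")
#' s
sers_spectrum <- function(wavenumber, intensity,
                          sample = NA_character_,
                          replicate = NA_integer_,
                          group = NA_character_) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  validate_axis(wavenumber)
  if (length(intensity) != length(wavenumber)) {
    stop("intensity length (", length(intensity),
         ") does not match axis length (", length(wavenumber), ")")
  }
  if (!all(is.finite(intensity))) {
    stop("all intensities must be finite")
  }
  structure(
    list(
      wavenumber = wavenumber,
      intensity = intensity,
      meta = data.frame(sample = as.character(sample),
                        replicate = as.integer(replicate),
                        group = as.character(group),
                        stringsAsFactors = FALSE)
    ),
    class = "sers_spectrum"
  )
}

validate_axis <- function(wavenumber) {
  if (length(wavenumber) < 2L) {
    stop("wavenumber axis must have at least 2 points")
  }
  if (!all(is.finite(wavenumber))) {
    stop("wavenumber axis must be finite")
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("wavenumber axis must be strictly increasing")
  }
  invisible(wavenumber)
}

#' @export
print.sers_spectrum <- function(x, ...) {
  cat(sprintf("<sers_spectrum> %d points, %.1f-%.1f cm^-1",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  if (!is.na(x$meta$sample)) cat(", sample:", x$meta$sample)
  cat("\n")
  invisible(x)
}

#' Collection of spectra on one common axis
#'
#' Stores a cohort of spectra sharing a wavenumber axis as an
#' `n x p` intensity matrix (rows = spectra) with per-row metadata.
#' Every member's axis must equal the common axis exactly; use
#' [resample_spectra()] to harmonize heterogeneous axes first.
#'
#' @param spectra List of [sers_spectrum] objects sharing one axis.
#'
#' @return An object of class `sers_set`: list with `wavenumber`,
#'   `intensity` (matrix, one row per spectrum) and `meta` (data frame,
#'   one row per spectrum).
#' @export
sers_set <- function(spectra) {
  if (length(spectra) == 0L) {
    return(structure(list(wavenumber = numeric(0),
                          intensity = matrix(numeric(0), nrow = 0, ncol = 0),
                          meta = data.frame(sample = character(0),
                                            replicate = integer(0),
                                            group = character(0))),
                     class = "sers_set"))
  }
  stopifnot(all(vapply(spectra, inherits, logical(1), "sers_spectrum")))
  axis <- spectra[[1L]]$wavenumber
  for (i in seq_along(spectra)) {
    if (!identical(length(spectra[[i]]$wavenumber), length(axis)) ||
        !isTRUE(all(spectra[[i]]$wavenumber == axis))) {
      stop("spectrum ", i, " is not on the common axis; resample first")
    }
  }
  intensity <- do.call(rbind, lapply(spectra, `[[`, "intensity"))
  meta <- do.call(rbind, lapply(spectra, `[[`, "meta"))
  rownames(intensity) <- NULL
  rownames(meta) <- NULL
  new_sers_set(axis, intensity, meta)
}

new_sers_set <- function(wavenumber, intensity, meta = NULL) {
  intensity <- as.matrix(intensity)
  if (ncol(intensity) != length(wavenumber)) {
    stop("intensity matrix must have one column per axis point")
  }
  if (is.null(meta)) {
    meta <- data.frame(sample = paste0("s", seq_len(nrow(intensity))),
                       replicate = NA_integer_,
                       group = NA_character_,
                       stringsAsFactors = FALSE)
  }
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = intensity,
                 meta = meta),
            class = "sers_set")
}

#' @export
print.sers_set <- function(x, ...) {
  cat(sprintf("<sers_set> %d spectra x %d points", nrow(x$intensity),
              ncol(x$intensity)))
  if (ncol(x$intensity) > 0) {
    cat(sprintf(", %.1f-%.1f cm^-1", min(x$wavenumber), max(x$wavenumber)))
  }
  cat("\n")
  invisible(x)
}

#' Number of spectra in a set
#' @param set A [sers_set].
#' @return Integer count.
#' @export
n_spectra <- function(set) {
  stopifnot(inherits(set, "sers_set"))
  nrow(set$intensity)
}

#' Extract one spectrum from a set
#' @param set A [sers_set].
#' @param i Row index.
#' @return A [sers_spectrum].
#' @export
get_spectrum <- function(set, i) {
  stopifnot(inherits(set, "sers_set"), i >= 1L, i <= n_spectra(set))
  sers_spectrum(set$wavenumber, set$intensity[i, ],
                sample = set$meta$sample[i],
                replicate = set$meta$replicate[i],
                group = set$meta$group[i])
}

#' Resample spectra onto a common axis
#'
#' Linear interpolation of each spectrum onto a target axis. Values at
#' grid points shared between source and target axes are unchanged.
#' Extrapolation is refused: the target axis must lie within the span of
#' every source spectrum.
#'
#' @param spectra List of [sers_spectrum] objects (possibly on
#'   different axes).
#' @param wavenumber Target axis (strictly increasing numeric).
#' @return A [sers_set] on the target axis.
#' @export
resample_spectra <- function(spectra, wavenumber) {
  validate_axis(wavenumber)
  out <- lapply(spectra, function(s) {
    if (min(wavenumber) < min(s$wavenumber) ||
        max(wavenumber) > max(s$wavenumber)) {
      stop("target axis [", min(wavenumber), ", ", max(wavenumber),
           "] extends beyond source axis [", min(s$wavenumber), ", ",
           max(s$wavenumber), "]; refusing to extrapolate")
    }
    y <- stats::approx(s$wavenumber, s$intensity, xout = wavenumber)$y
    sers_spectrum(wavenumber, y,
                  sample = s$meta$sample,
                  replicate = s$meta$replicate,
                  group = s$meta$group)
  })
  sers_set(out)
}

#' Default analysis axis
#'
#' The working range used throughout: 400 to 1800 cm^-1 at 1 cm^-1
#' spacing (1401 points), matching the usual cropped range for serum
#' SERS spectra with 785 nm excitation.
#'
#' @param lo,hi Range endpoints in cm^-1.
#' @param step Grid spacing in cm^-1.
#' @return Numeric axis vector.
#' @export
default_axis <- function(lo = 400, hi = 1800, step = 1) {
  seq(lo, hi, by = step)
}
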