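#' Component library of unit-normalized reference spectra
#'
#' Holds named reference spectra (e.g. free uric acid, HSA-bound uric
#' acid, hypoxanthine) sharing one wavenumber axis, each normalized to
#' unit Euclidean norm, for use in spectral decomposition.
#'
#' @param wavenumber Common axis (strictly increasing).
#' @param spectra Numeric matrix, one column per component (or a named
#'   list of intensity vectors). Columns are renormalized to unit norm.
#' @param names Component names; defaults to column/list names.
#'
#' @return Object of class `component_library`: list with `wavenumber`,
#'   `spectra` (p x K matrix, unit-norm columns) and `names`.
#' @export
component_library <- function(wavenumber, spectra, names = NULL) {
  validate_axis(wavenumber)
  if (is.list(spectra) && !is.matrix(spectra)) {
    if (is.null(names)) names <- base::names(spectra)
    spectra <- do.call(cbind, spectra)
  }
  spectra <- as.matrix(spectra)
  if (is.null(names)) names <- colnames(spectra)
  if (is.null(names) || any(!nzchar(names))) {
    stop("components must be named")
  }
  if (nrow(spectra) != length(wavenumber)) {
    stop("reference spectra must have one value per axis point")
  }
  if (ncol(spectra) < 1L) stop("library needs at least one component")
  nrm <- sqrt(colSums(spectra^2))
  if (any(nrm == 0)) stop("zero reference spectrum in library")
  spectra <- sweep(spectra, 2L, nrm, "/")
  colnames(spectra) <- names
  structure(list(wavenumber = as.numeric(wavenumber),
                 spectra = spectra, names = names),
            class = "component_library")
}

#' @export
print.component_library <- function(x, ...) {
  cat("<component_library>", ncol(x$spectra), "components:",
      paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Number of components in a library
#' @param library A [component_library].
#' @return Integer count.
#' @export
n_components <- function(library) {
  stopifnot(inherits(library, "component_library"))
  ncol(library$spectra)
}
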