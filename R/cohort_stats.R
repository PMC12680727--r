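# Cohort-level band attribution: band-intensity extraction, Spearman
# correlation against an anchor band with thresholded grouping, and
# centered-unscaled PCA with loading-to-component matching.

#' Band-intensity matrix for a cohort
#'
#' For each spectrum and each nominal band position, the entry is the
#' maximum intensity within `tol` cm^-1 of the position (a small window
#' absorbs instrument-to-instrument shifts); `tol = 0` takes the value
#' at the nearest grid point.
#'
#' @param set A preprocessed [sers_set].
#' @param positions Numeric vector of band positions (cm^-1), strictly
#'   increasing.
#' @param tol Half-width of the extraction window in cm^-1 (default 3).
#' @return Numeric matrix (donors x bands) with the positions as column
#'   names; class `band_intensity_matrix`.
#' @export
band_intensity_matrix <- function(set, positions, tol = 3) {
  stopifnot(inherits(set, "sers_set"), tol >= 0)
  positions <- as.numeric(positions)
  if (any(diff(positions) <= 0)) stop("band positions must be strictly increasing")
  w <- set$wavenumber
  if (any(positions < min(w) | positions > max(w))) {
    stop("band position outside the axis span")
  }
  out <- vapply(positions, function(p) {
    idx <- which(abs(w - p) <= tol)
    if (length(idx) == 0L) idx <- which.min(abs(w - p))
    apply(set$intensity[, idx, drop = FALSE], 1L, max)
  }, numeric(n_spectra(set)))
  out <- matrix(out, nrow = n_spectra(set),
                dimnames = list(set$meta$sample, positions))
  class(out) <- c("band_intensity_matrix", class(out))
  out
}

#' Spearman correlation of every band with an anchor band
#'
#' Rank correlation of each column of the band-intensity matrix against
#' the anchor band's column. Bands with `rho > tau` are flagged as
#' co-varying with the anchor — in a cohort, bands that rise and fall
#' together across donors most likely share a molecular origin.
#'
#' @param matrix A [band_intensity_matrix()] (>= 3 donors).
#' @param anchor Anchor band position; must equal one of the matrix
#'   column positions.
#' @param tau Membership threshold on rho (default 0.6).
#' @return Data frame of class `correlation_report`: `band`, `rho`,
#'   `member` (`rho > tau`; `NA` rho excluded), plus attributes
#'   `anchor` and `tau`. Constant columns yield `rho = NA` with a
#'   warning.
#' @export
spearman_with_anchor <- function(matrix, anchor, tau = 0.6) {
  stopifnot(nrow(matrix) >= 3)
  bands <- as.numeric(colnames(matrix))
  j <- which(abs(bands - anchor) < 1e-8)
  if (length(j) != 1L) stop("anchor ", anchor, " is not a matrix column")
  a <- matrix[, j]
  rho <- vapply(seq_along(bands), function(k) {
    x <- matrix[, k]
    if (stats::sd(x) == 0 || stats::sd(a) == 0) return(NA_real_)
    stats::cor(a, x, method = "spearman")
  }, numeric(1))
  if (anyNA(rho)) {
    warning("constant band column(s): rho undefined at ",
            paste(bands[is.na(rho)], collapse = ", "))
  }
  out <- data.frame(band = bands, rho = rho,
                    member = !is.na(rho) & rho > tau)
  attr(out, "anchor") <- anchor
  attr(out, "tau") <- tau
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' Principal component analysis of a cohort
#'
#' PCA of the donors x wavenumber intensity matrix, centered but not
#' scaled. Loadings follow a deterministic sign convention: the element
#' of largest magnitude in each loading is positive.
#'
#' @param set A preprocessed [sers_set] (>= 2 donors with non-zero
#'   variance).
#' @param n_components Number of PCs to keep; at most `min(n - 1, p)`.
#' @return Object of class `pca_result`: `explained` (variance
#'   fraction per kept PC), `cumulative`, `loadings` (p x k matrix),
#'   `scores` (n x k), `wavenumber`, `center`.
#' @export
run_pca <- function(set, n_components = 10) {
  stopifnot(inherits(set, "sers_set"))
  n <- n_spectra(set)
  p <- ncol(set$intensity)
  if (n < 2L) stop("PCA needs at least 2 spectra")
  kmax <- min(n - 1L, p)
  if (n_components > kmax) {
    stop("n_components = ", n_components, " exceeds min(n - 1, p) = ", kmax)
  }
  if (sum(apply(set$intensity, 2L, stats::var)) == 0) {
    stop("degenerate cohort: total variance is zero")
  }
  pc <- stats::prcomp(set$intensity, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  frac <- var_all / sum(var_all)
  k <- n_components
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(explained = frac[seq_len(k)],
                 cumulative = cumsum(frac)[seq_len(k)],
                 loadings = loadings, scores = scores,
                 wavenumber = set$wavenumber, center = pc$center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>\n")
  for (j in seq_along(x$explained)) {
    cat(sprintf("  PC%d: %.1f%% (cum. %.1f%%)\n", j,
                100 * x$explained[j], 100 * x$cumulative[j]))
  }
  invisible(x)
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Match PCA loadings to library components
#'
#' Cosine similarity of each loading with each reference component and
#' with every signed pairwise contrast `comp_i - comp_j`: a loading
#' resembling a contrast indicates that the PC captures the relative
#' intensity ratio between two components across donors.
#'
#' @param pca A [run_pca()] result on the library axis.
#' @param library A [component_library].
#' @return List: `components` (PC x component cosine matrix),
#'   `contrasts` (PC x contrast cosine matrix, columns named
#'   `i-j`).
#' @export
match_loadings <- function(pca, library) {
  stopifnot(inherits(pca, "pca_result"),
            inherits(library, "component_library"))
  if (length(pca$wavenumber) != length(library$wavenumber)) {
    stop("PCA and library are not on the same axis")
  }
  k <- ncol(pca$loadings)
  K <- n_components(library)
  comp <- matrix(NA_real_, k, K,
                 dimnames = list(paste0("PC", seq_len(k)), library$names))
  for (j in seq_len(k)) {
    for (m in seq_len(K)) {
      comp[j, m] <- cosine(pca$loadings[, j], library$spectra[, m])
    }
  }
  pairs <- utils::combn(K, 2L)
  contr <- matrix(NA_real_, k, ncol(pairs),
                  dimnames = list(paste0("PC", seq_len(k)),
                                  apply(pairs, 2L, function(ij) {
                                    paste(library$names[ij], collapse = "-")
                                  })))
  for (cidx in seq_len(ncol(pairs))) {
    d <- library$spectra[, pairs[1L, cidx]] - library$spectra[, pairs[2L, cidx]]
    for (j in seq_len(k)) contr[j, cidx] <- cosine(pca$loadings[, j], d)
  }
  list(components = comp, contrasts = contr)
}
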