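# File I/O: two-column ASCII spectra (instrument export style) and
# sample x wavenumber CSV matrices, plus filename-metadata parsing.

#' Read a spectrum from two-column ASCII text
#'
#' Reads instrument-style exports: one Raman shift / intensity pair per
#' line, whitespace- or comma-delimited, with optional comment lines
#' starting with `#`. The first column must be strictly increasing.
#'
#' @param path Path to the text file.
#' @param meta_pattern Optional Perl regular expression with named groups
#'   `sample`, `replicate` and/or `group`, applied to the file's base name
#'   (extension stripped) to extract metadata. When the pattern does not
#'   match, metadata stay empty and a warning is emitted (never an error).
#' @return A [sers_spectrum].
#' @export
#' @examples
#' p <- tempfile(fileext = ".txt")
#' writeLines(c("# demo", "400 10", "401 12", "402 11"), p)
#' read_spectrum_txt(p)
read_spectrum_txt <- function(path, meta_pattern = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no data rows in ", path)
  parts <- strsplit(trimws(lines[idx]), "[,;[:space:]]+")
  n_fields <- lengths(parts)
  if (any(n_fields < 2L)) {
    bad <- idx[which(n_fields < 2L)[1L]]
    stop("parse error in ", path, " at line ", bad, ": fewer than 2 columns")
  }
  wn <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(wn) || anyNA(it)) {
    bad <- idx[which(is.na(wn) | is.na(it))[1L]]
    stop("parse error in ", path, " at line ", bad, ": non-numeric value")
  }
  if (any(diff(wn) <= 0)) {
    stop("axis error in ", path, ": wavenumber column is not strictly increasing")
  }
  meta <- parse_filename_meta(path, meta_pattern)
  sers_spectrum(wn, it, sample = meta$sample,
                replicate = meta$replicate, group = meta$group)
}

#' Write a spectrum as two-column ASCII text
#'
#' @param spectrum A [sers_spectrum].
#' @param path Output path.
#' @param digits Significant digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_spectrum_txt <- function(spectrum, path, digits = 10) {
  stopifnot(inherits(spectrum, "sers_spectrum"))
  fmt <- paste0("%.", digits, "g %.", digits, "g")
  writeLines(sprintf(fmt, spectrum$wavenumber, spectrum$intensity), path)
  invisible(path)
}

#' Parse sample metadata from a file name
#'
#' @param path File path; only the extension-stripped base name is matched.
#' @param meta_pattern Perl regex with named groups (`sample`, `replicate`,
#'   `group`), or `NULL` for no parsing (sample = base name).
#' @return List with `sample`, `replicate`, `group`.
#' @export
parse_filename_meta <- function(path, meta_pattern = NULL) {
  base <- sub("\\.[^.]*$", "", basename(path))
  out <- list(sample = base, replicate = NA_integer_, group = NA_character_)
  if (is.null(meta_pattern)) return(out)
  m <- regexpr(meta_pattern, base, perl = TRUE)
  if (m == -1L) {
    warning("filename '", base, "' does not match meta_pattern; metadata left empty")
    return(list(sample = NA_character_, replicate = NA_integer_,
                group = NA_character_))
  }
  starts <- attr(m, "capture.start")
  lens <- attr(m, "capture.length")
  nm <- attr(m, "capture.names")
  for (field in c("sample", "replicate", "group")) {
    j <- match(field, nm)
    if (!is.na(j) && starts[j] > 0L) {
      val <- substr(base, starts[j], starts[j] + lens[j] - 1L)
      out[[field]] <- if (field == "replicate") as.integer(val) else val
    }
  }
  out
}

#' Read a spectrum set from a CSV matrix
#'
#' Dialect: first column `id`, remaining column headers are numeric
#' wavenumbers; one row per spectrum.
#'
#' @param path CSV path.
#' @return A [sers_set].
#' @export
read_set_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- tryCatch(utils::count.fields(path, sep = ","),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (length(nf) == 0L) stop("parse error in ", path, ": empty file")
  if (length(unique(nf)) != 1L) {
    stop("parse error in ", path, ": ragged rows (",
         paste(unique(nf), collapse = "/"), " fields)")
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L || names(df)[1L] != "id") {
    stop("parse error in ", path, ": expected 'id' column plus wavenumber columns")
  }
  wn <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (anyNA(wn)) stop("parse error in ", path, ": non-numeric wavenumber header")
  validate_axis(wn)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  meta <- data.frame(sample = as.character(df$id),
                     replicate = NA_integer_, group = NA_character_,
                     stringsAsFactors = FALSE)
  new_sers_set(wn, m, meta)
}

#' Write a spectrum set as a CSV matrix
#'
#' Values are written with 17 significant digits so that a read-back
#' reproduces the doubles bit for bit.
#'
#' @param set A [sers_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_set_csv <- function(set, path) {
  stopifnot(inherits(set, "sers_set"))
  header <- paste(c("id", sprintf("%.17g", set$wavenumber)), collapse = ",")
  rows <- vapply(seq_len(n_spectra(set)), function(i) {
    paste(c(set$meta$sample[i], sprintf("%.17g", set$intensity[i, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
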