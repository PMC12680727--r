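# End-to-end orchestration: one config drives simulate -> preprocess ->
# peaks -> decompose -> cohort statistics, writing plain-text artifacts
# and a manifest with the config echo and seed.

#' Default pipeline configuration
#'
#' @param seed Integer seed used for every stochastic stage.
#' @param input Input source: list with `type = "synthetic"` and
#'   `scenario` (`"donors"` or `"serum"`), or `type = "csv"` with
#'   `path` to a matrix CSV, or `type = "dir"` with `path` to a
#'   directory of two-column ASCII files (plus optional
#'   `meta_pattern`).
#' @param n_donors Cohort size for synthetic input.
#' @param preprocess List: `lo`, `hi`, `degree`, `tol`, `max_iter`.
#' @param peaks List: `snr_threshold`.
#' @param decompose List: `shift_bound`, `B` (bootstrap resamples),
#'   `level`.
#' @param cohort List: `anchor` (anchor band, cm^-1), `tau`, `band_tol`,
#'   `n_pcs`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            input = list(type = "synthetic",
                                         scenario = "donors"),
                            n_donors = 81L,
                            preprocess = list(lo = 400, hi = 1800,
                                              degree = 4, tol = 1e-3,
                                              max_iter = 100),
                            peaks = list(snr_threshold = 3),
                            decompose = list(shift_bound = 0.1, B = 1000,
                                             level = 0.95),
                            cohort = list(anchor = 638, tau = 0.6,
                                          band_tol = 3, n_pcs = 10)) {
  structure(list(seed = as.integer(seed), input = input,
                 n_donors = as.integer(n_donors), preprocess = preprocess,
                 peaks = peaks, decompose = decompose, cohort = cohort),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; missing keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  for (nm in intersect(names(raw), names(defaults))) {
    if (is.list(defaults[[nm]]) && is.list(raw[[nm]])) {
      defaults[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      defaults[[nm]] <- raw[[nm]]
    }
  }
  defaults$seed <- as.integer(defaults$seed)
  defaults
}

pipeline_input <- function(config) {
  inp <- config$input
  if (identical(inp$type, "synthetic")) {
    scenario <- if (is.null(inp$scenario)) "donors" else inp$scenario
    if (scenario == "donors") {
      lib <- default_library()
      cfg <- cohort_config(n_donors = config$n_donors, seed = config$seed)
    } else if (scenario == "serum") {
      lib <- default_library(components = c("uric_acid", "hypoxanthine"))
      cfg <- cohort_config(n_donors = config$n_donors,
                           components = serum_components(),
                           seed = config$seed)
    } else stop("unknown synthetic scenario '", scenario, "'")
    gen <- generate_cohort(cfg, lib)
    list(set = gen$set, truth = gen$truth, library = lib)
  } else if (identical(inp$type, "csv")) {
    if (!file.exists(inp$path)) stop("input file not found: ", inp$path)
    list(set = read_set_csv(inp$path), truth = NULL,
         library = default_library())
  } else if (identical(inp$type, "dir")) {
    if (!dir.exists(inp$path)) stop("input directory not found: ", inp$path)
    files <- sort(list.files(inp$path, pattern = "\\.txt$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no .txt spectra in ", inp$path)
    spectra <- lapply(files, read_spectrum_txt,
                      meta_pattern = inp$meta_pattern)
    list(set = resample_spectra(spectra, default_axis()), truth = NULL,
         library = default_library())
  } else stop("unknown input type '", inp$type, "'")
}

#' Run the full pipeline
#'
#' Executes simulate/load, preprocessing, peak detection, cohort
#' decomposition and cohort statistics, writing all artifacts under
#' `out_dir`: raw and preprocessed matrices, the truth table (synthetic
#' input), a peak list, the per-spectrum decomposition table, a summary
#' JSON with bootstrap CIs, the anchor-band correlation report, PCA
#' variance and loading tables, and `MANIFEST.json` (config echo, seed,
#' package version, file list).
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (`set`, `preprocessed`, `peaks`, `cohort_fit`, `correlation`,
#'   `pca`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(name) {
    files <<- c(files, name)
    file.path(out_dir, name)
  }

  inp <- pipeline_input(config)
  write_set_csv(inp$set, put("spectra_raw.csv"))
  if (!is.null(inp$truth)) {
    utils::write.csv(inp$truth, put("truth.csv"), row.names = FALSE)
  }

  pp <- config$preprocess
  corrected <- preprocess_set(inp$set, lo = pp$lo, hi = pp$hi,
                              degree = pp$degree, tol = pp$tol,
                              max_iter = pp$max_iter, normalize = FALSE)
  normalized <- preprocess_set(inp$set, lo = pp$lo, hi = pp$hi,
                               degree = pp$degree, tol = pp$tol,
                               max_iter = pp$max_iter, normalize = TRUE)
  write_set_csv(normalized, put("spectra_preprocessed.csv"))

  lib <- inp$library
  if (!identical(lib$wavenumber, normalized$wavenumber)) {
    lib <- component_library(
      normalized$wavenumber,
      apply(lib$spectra, 2L, function(v) {
        stats::approx(lib$wavenumber, v, xout = normalized$wavenumber,
                      rule = 2)$y
      }),
      names = lib$names)
  }

  pk <- lapply(seq_len(n_spectra(normalized)), function(i) {
    p <- detect_peaks(get_spectrum(normalized, i),
                      snr_threshold = config$peaks$snr_threshold)
    if (nrow(p) > 0) cbind(sample = normalized$meta$sample[i], p)
  })
  peaks_df <- do.call(rbind, pk)
  utils::write.csv(peaks_df, put("peaks.csv"), row.names = FALSE)

  dc <- config$decompose
  cf <- fit_cohort(normalized, lib, shift_bound = dc$shift_bound,
                   B = dc$B, level = dc$level, seed = config$seed)
  utils::write.csv(cf$table, put("decomposition.csv"), row.names = FALSE)

  ch <- config$cohort
  band_pos <- sort(unique(unlist(lapply(lib$names, function(nm) {
    tab <- tryCatch(default_band_table(nm), error = function(e) NULL)
    if (is.null(tab)) NULL else tab$center
  }))))
  bim <- band_intensity_matrix(corrected, band_pos, tol = ch$band_tol)
  corr <- spearman_with_anchor(bim, anchor = ch$anchor, tau = ch$tau)
  utils::write.csv(corr, put("correlation.csv"), row.names = FALSE)

  n_pcs <- min(ch$n_pcs, n_spectra(normalized) - 1L)
  pca <- run_pca(normalized, n_components = n_pcs)
  utils::write.csv(data.frame(pc = seq_along(pca$explained),
                              explained = pca$explained,
                              cumulative = pca$cumulative),
                   put("pca_variance.csv"), row.names = FALSE)
  utils::write.csv(data.frame(wavenumber = pca$wavenumber, pca$loadings),
                   put("pca_loadings.csv"), row.names = FALSE)

  summary <- list(
    seed = config$seed,
    n_spectra = n_spectra(normalized),
    fit = lapply(cf$summary, function(s) {
      list(median = s$median, lower = s$lower, upper = s$upper)
    }),
    pca_explained = as.list(stats::setNames(pca$explained,
                                            paste0("PC",
                                                   seq_along(pca$explained)))),
    correlation_members = corr$band[corr$member]
  )
  jsonlite::write_json(summary, put("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)

  manifest <- list(
    package = "sersdecomp",
    version = as.character(utils::packageVersion("sersdecomp")),
    seed = config$seed,
    config = unclass(config),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(set = inp$set, truth = inp$truth,
                 preprocessed = normalized, corrected = corrected,
                 peaks = peaks_df, cohort_fit = cf, correlation = corr,
                 pca = pca, manifest = manifest))
}
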