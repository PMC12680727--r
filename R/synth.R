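# Synthetic serum-spectrum generator: pseudo-Voigt component references,
# donor cohorts with concentration/baseline/scale/noise variability, and
# the spiking and isotopologue scenarios used for band attribution.

#' Band table for synthesizing a reference spectrum
#'
#' @param center Band centers in cm^-1.
#' @param fwhm Full widths at half maximum in cm^-1 (recycled).
#' @param amplitude Relative amplitudes, > 0 (recycled).
#' @param eta Pseudo-Voigt Lorentzian fractions in \[0, 1\] (recycled).
#' @return A data frame of class `band_table`.
#' @export
band_table <- function(center, fwhm = 12, amplitude = 1, eta = 0.7) {
  n <- length(center)
  if (n == 0L) stop("band table must contain at least one band")
  tab <- data.frame(center = as.numeric(center),
                    fwhm = rep_len(as.numeric(fwhm), n),
                    amplitude = rep_len(as.numeric(amplitude), n),
                    eta = rep_len(as.numeric(eta), n))
  if (any(tab$fwhm <= 0)) stop("band widths must be > 0")
  if (any(tab$amplitude <= 0)) stop("band amplitudes must be > 0")
  if (any(tab$eta < 0 | tab$eta > 1)) stop("eta must lie in [0, 1]")
  class(tab) <- c("band_table", "data.frame")
  tab
}

# Pseudo-Voigt profile with unit peak height at the center.
pseudo_voigt <- function(w, center, fwhm, eta) {
  g <- fwhm / 2
  s <- fwhm / (2 * sqrt(2 * log(2)))
  eta * g^2 / ((w - center)^2 + g^2) +
    (1 - eta) * exp(-(w - center)^2 / (2 * s^2))
}

#' Build a unit-normalized reference spectrum from a band table
#'
#' Sums pseudo-Voigt profiles at the tabulated centers and vector
#' normalizes the result. The maximum of an isolated band falls on the
#' grid point nearest its tabulated center.
#'
#' @param bands A [band_table].
#' @param wavenumber Axis vector.
#' @param normalize Divide by the Euclidean norm (default `TRUE`).
#' @return A [sers_spectrum].
#' @export
build_reference <- function(bands, wavenumber, normalize = TRUE) {
  stopifnot(inherits(bands, "band_table"))
  validate_axis(wavenumber)
  if (any(bands$center < min(wavenumber) | bands$center > max(wavenumber))) {
    stop("band center outside the axis span")
  }
  y <- numeric(length(wavenumber))
  for (i in seq_len(nrow(bands))) {
    y <- y + bands$amplitude[i] *
      pseudo_voigt(wavenumber, bands$center[i], bands$fwhm[i], bands$eta[i])
  }
  if (normalize) y <- y / sqrt(sum(y^2))
  sers_spectrum(wavenumber, y, sample = "reference")
}

#' Default band tables for the serum components
#'
#' Band centers follow the positions reported for serum SERS spectra on
#' silver with 785 nm excitation: free uric acid dominated by the
#' 638 cm^-1 band; HSA-bound uric acid additionally carrying the intense
#' band at 1659 cm^-1 (absent from the free form) and C-N stretching
#' bands at 867, 1002, 1055, 1125 and 1192 cm^-1; hypoxanthine dominated
#' by the 725 cm^-1 band. Relative amplitudes, widths and lineshape
#' mixing are documented generator defaults, not claims about the true
#' compounds.
#'
#' @param component One of `"uric_acid_free"`, `"uric_acid_hsa"`,
#'   `"hypoxanthine"`. `"uric_acid"` is an alias for the free form.
#' @return A [band_table].
#' @export
default_band_table <- function(component = c("uric_acid_free", "uric_acid_hsa",
                                             "hypoxanthine", "uric_acid")) {
  component <- match.arg(component)
  switch(component,
    uric_acid = ,
    uric_acid_free = band_table(
      center    = c(638, 813, 890, 1008, 1130, 1205, 1438),
      amplitude = c(1.00, 0.35, 0.30, 0.25, 0.45, 0.30, 0.20)),
    uric_acid_hsa = band_table(
      center    = c(638, 867, 1002, 1055, 1125, 1192, 1659),
      amplitude = c(0.85, 0.25, 0.25, 0.20, 0.40, 0.30, 0.90)),
    hypoxanthine = band_table(
      center    = c(725, 1095, 1210, 1580),
      amplitude = c(1.00, 0.20, 0.15, 0.25))
  )
}

#' Default component library
#'
#' Unit-normalized references built from [default_band_table()] on the
#' given axis.
#'
#' @param wavenumber Axis vector (default [default_axis()]).
#' @param components Character vector of component names understood by
#'   [default_band_table()].
#' @return A [component_library].
#' @export
default_library <- function(wavenumber = default_axis(),
                            components = c("uric_acid_free", "uric_acid_hsa",
                                           "hypoxanthine")) {
  refs <- lapply(components, function(cmp) {
    build_reference(default_band_table(cmp), wavenumber)$intensity
  })
  names(refs) <- components
  component_library(wavenumber, refs)
}

#' Substitute band centers (isotopologue emulation)
#'
#' Isotopic substitution shifts vibrational band positions; this returns
#' a band table with selected centers replaced, all other fields kept.
#' The canonical case is the 1659 to 1653 cm^-1 downshift of the C6=O
#' stretching band of HSA-bound uric acid upon 13C/15N substitution.
#'
#' @param bands A [band_table].
#' @param shift_map Named numeric vector: names are existing centers,
#'   values are the replacement centers. A name matching no tabulated
#'   center is an error.
#' @return A [band_table] with substituted centers.
#' @export
#' @examples
#' isotopologue_bands(default_band_table("uric_acid_hsa"), c("1659" = 1653))
isotopologue_bands <- function(bands, shift_map) {
  stopifnot(inherits(bands, "band_table"))
  if (length(shift_map) == 0L) return(bands)
  old <- as.numeric(names(shift_map))
  if (anyNA(old)) stop("shift_map names must be numeric band centers")
  for (i in seq_along(old)) {
    j <- which(abs(bands$center - old[i]) < 1e-8)
    if (length(j) != 1L) {
      stop("shift_map center ", old[i], " does not match a tabulated band")
    }
    bands$center[j] <- as.numeric(shift_map[[i]])
  }
  bands
}

#' Cohort generator configuration
#'
#' Defines the statistical model a donor cohort is drawn from: per-donor
#' log-normal component concentrations, a per-donor smooth polynomial
#' baseline, additive Gaussian noise and a per-donor global intensity
#' factor emulating enhancement variability.
#'
#' @param n_donors Number of donors (>= 1).
#' @param components Named list; one entry per component with fields
#'   `median` (uM), `gsd` (geometric sd, >= 1) and `response` (counts per
#'   uM for the unit-norm reference). Defaults to
#'   [default_components()].
#' @param baseline_range 5 x 2 matrix of ranges (lo, hi) for the
#'   degree-4 baseline polynomial coefficients c0..c4, expressed on the
#'   unit interval of the axis. `NULL` disables the baseline.
#' @param snr Spectrum-wide signal-to-noise ratio, defined as the
#'   Euclidean norm of the noiseless mixture at median concentrations
#'   over the Euclidean norm of the noise vector. Used when `noise_sd`
#'   is `NULL`.
#' @param noise_sd Additive Gaussian noise sd in counts; overrides `snr`
#'   when non-`NULL` (0 disables noise).
#' @param scale_gsd Geometric sd of the per-donor global intensity
#'   factor (log-normal, median 1); 1 disables it.
#' @param seed Integer seed recorded in the output and used for all
#'   draws.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_donors = 81,
                          components = default_components(),
                          baseline_range = default_baseline_range(),
                          snr = 50,
                          noise_sd = NULL,
                          scale_gsd = 1.2,
                          seed = 1L) {
  stopifnot(n_donors >= 1, is.list(components), length(components) >= 1)
  if (is.null(names(components)) || any(!nzchar(names(components)))) {
    stop("components must be named")
  }
  for (cmp in components) {
    stopifnot(is.numeric(cmp$median), cmp$median > 0,
              is.numeric(cmp$gsd), cmp$gsd >= 1,
              is.numeric(cmp$response), cmp$response > 0)
  }
  if (!is.null(noise_sd)) stopifnot(noise_sd >= 0)
  stopifnot(is.null(snr) || snr > 0, scale_gsd >= 1)
  structure(list(n_donors = as.integer(n_donors), components = components,
                 baseline_range = baseline_range, snr = snr,
                 noise_sd = noise_sd, scale_gsd = scale_gsd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default component concentration model
#'
#' Physiological anchors: total serum uric acid around 280 uM split
#' between a free (190 uM) and an HSA-bound (90 uM) pool; hypoxanthine
#' 10 uM. Concentrations are log-normal with geometric sd 1.3 (serum
#' metabolite levels are right-skewed). The hypoxanthine response is
#' several-fold that of uric acid per mole, so that the 725 cm^-1 serum
#' band is a medium-intensity band while uric acid still dominates the
#' spectrum.
#'
#' @return Named list usable as `components` in [cohort_config()].
#' @export
default_components <- function() {
  list(
    uric_acid_free = list(median = 190, gsd = 1.3, response = 1),
    uric_acid_hsa  = list(median = 90,  gsd = 1.3, response = 1),
    hypoxanthine   = list(median = 10,  gsd = 1.3, response = 7)
  )
}

#' Two-component serum model (uric acid + hypoxanthine)
#'
#' Commercial-serum-like model with a single uric-acid pool at the
#' average physiological 280 uM, used for the spiking and band
#' attribution scenarios.
#'
#' @return Named list usable as `components` in [cohort_config()].
#' @export
serum_components <- function() {
  list(
    uric_acid    = list(median = 280, gsd = 1.3, response = 1),
    hypoxanthine = list(median = 10,  gsd = 1.3, response = 7)
  )
}

#' Default baseline coefficient ranges
#'
#' Degree-4 polynomial on the unit interval; the constant term sits at a
#' few hundred counts (broad fluorescence background larger than the
#' strongest band, as in raw SERS data) with gentler higher-order terms.
#'
#' @return 5 x 2 numeric matrix (rows c0..c4; columns lo, hi).
#' @export
default_baseline_range <- function() {
  cbind(lo = c(100, -80, -80, -80, -80),
        hi = c(300,  80,  80,  80,  80))
}

# Evaluate the random baseline polynomial on the axis.
baseline_poly <- function(coefs, wavenumber) {
  u <- (wavenumber - min(wavenumber)) / diff(range(wavenumber))
  drop(outer(u, 0:(length(coefs) - 1L), "^") %*% coefs)
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Noise sd giving the configured spectrum-wide SNR for this config/library.
config_noise_sd <- function(config, library) {
  if (!is.null(config$noise_sd)) return(config$noise_sd)
  med <- vapply(config$components, `[[`, numeric(1), "median")
  resp <- vapply(config$components, `[[`, numeric(1), "response")
  mix <- drop(library$spectra %*% (med * resp))
  sqrt(sum(mix^2)) / (config$snr * sqrt(length(mix)))
}

#' Generate a synthetic donor cohort
#'
#' Each spectrum is `(sum_k conc_k * response_k * reference_k + baseline
#' + noise) * scale`, with per-donor concentrations, baseline
#' coefficients, noise and global intensity factor drawn from the
#' configured distributions. A truth table with every drawn quantity is
#' returned for recovery tests. Identical seeds give identical output.
#'
#' @param config A [cohort_config()]. Component names must match the
#'   library.
#' @param library A [component_library].
#' @return List with `set` (a [sers_set]) and `truth` (data frame:
#'   donor id, per-component concentration `conc_*`, `scale`,
#'   `noise_sd`, `seed`).
#' @export
generate_cohort <- function(config, library) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(library, "component_library"))
  cmp_names <- names(config$components)
  if (!setequal(cmp_names, library$names)) {
    stop("config components (", paste(cmp_names, collapse = ", "),
         ") do not match library (", paste(library$names, collapse = ", "), ")")
  }
  refs <- library$spectra[, cmp_names, drop = FALSE]
  n <- config$n_donors
  p <- length(library$wavenumber)
  sdn <- config_noise_sd(config, library)

  with_seed(config$seed, {
    conc <- sapply(config$components, function(cmp) {
      cmp$median * exp(stats::rnorm(n, 0, log(cmp$gsd)))
    })
    conc <- matrix(conc, nrow = n,
                   dimnames = list(NULL, cmp_names))
    resp <- vapply(config$components, `[[`, numeric(1), "response")
    signal <- conc %*% diag(resp, length(resp)) %*% t(refs)
    base <- matrix(0, n, p)
    if (!is.null(config$baseline_range)) {
      br <- config$baseline_range
      for (i in seq_len(n)) {
        coefs <- stats::runif(nrow(br), br[, 1L], br[, 2L])
        base[i, ] <- baseline_poly(coefs, library$wavenumber)
      }
    }
    noise <- if (sdn > 0) matrix(stats::rnorm(n * p, 0, sdn), n, p) else
      matrix(0, n, p)
    scale <- if (config$scale_gsd > 1) {
      exp(stats::rnorm(n, 0, log(config$scale_gsd)))
    } else rep(1, n)
    intensity <- (signal + base + noise) * scale
    meta <- data.frame(sample = sprintf("donor%02d", seq_len(n)),
                       replicate = 1L, group = "synthetic",
                       stringsAsFactors = FALSE)
    truth <- data.frame(sample = meta$sample, conc, scale = scale,
                        noise_sd = sdn, seed = config$seed,
                        check.names = FALSE)
    names(truth)[seq_along(cmp_names) + 1L] <- paste0("conc_", cmp_names)
    list(set = new_sers_set(library$wavenumber, intensity, meta),
         truth = truth)
  })
}

#' Simulate a spike experiment
#'
#' Generates an (unspiked, spiked) pair of serum-like spectra sharing
#' the same baseline and noise realization, differing only in the
#' concentration of the spiked analyte — the in-silico analog of adding
#' a known amount of a metabolite to a serum aliquot and looking for
#' band growth.
#'
#' @param base_concentrations Named numeric vector of concentrations
#'   (uM) for every library component.
#' @param analyte Name of the spiked component (must be in the library).
#' @param added Added concentration in uM (>= 0).
#' @param config A [cohort_config()] supplying responses, baseline,
#'   noise and seed (its `n_donors` is ignored).
#' @param library A [component_library].
#' @return List with `unspiked` and `spiked` ([sers_spectrum] each) and
#'   `noise_sd`.
#' @export
simulate_spike <- function(base_concentrations, analyte, added, config,
                           library) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(library, "component_library"))
  if (!analyte %in% library$names) {
    stop("analyte '", analyte, "' is not in the library")
  }
  if (added < 0) stop("added concentration must be >= 0")
  cmp_names <- names(config$components)
  if (!setequal(names(base_concentrations), cmp_names)) {
    stop("base_concentrations must name every configured component")
  }
  resp <- vapply(config$components, `[[`, numeric(1), "response")
  names(resp) <- cmp_names
  refs <- library$spectra[, cmp_names, drop = FALSE]
  p <- length(library$wavenumber)
  sdn <- config_noise_sd(config, library)

  with_seed(config$seed, {
    coefs <- if (is.null(config$baseline_range)) rep(0, 5) else
      stats::runif(nrow(config$baseline_range),
                   config$baseline_range[, 1L], config$baseline_range[, 2L])
    noise <- if (sdn > 0) stats::rnorm(p, 0, sdn) else numeric(p)
    base <- baseline_poly(coefs, library$wavenumber)
    mk <- function(conc, label) {
      y <- drop(refs %*% (conc[cmp_names] * resp[cmp_names])) + base + noise
      sers_spectrum(library$wavenumber, y, sample = label, group = label)
    }
    spiked_conc <- base_concentrations
    spiked_conc[analyte] <- spiked_conc[analyte] + added
    list(unspiked = mk(base_concentrations, "unspiked"),
         spiked = mk(spiked_conc, "spiked"),
         noise_sd = sdn)
  })
}
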