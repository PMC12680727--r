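# sersdecomp

Tools for attributing the bands of surface-enhanced Raman (SERS)
spectra of human serum to their molecular origins. SERS intensities
reflect surface affinity rather than concentration, so serum spectra
on silver colloids are dominated by a few strongly adsorbing
metabolites — chiefly uric acid (free and HSA-bound, the latter
carrying the intense 1650–1660 cm⁻¹ band) and hypoxanthine
(725 cm⁻¹). This package implements the quantitative evidence chain
behind that attribution for spectroscopists working with biofluid
SERS cohorts:

* **Preprocessing** — crop to 400–1800 cm⁻¹, iterative
  modified-polynomial (modpoly, degree 4) baseline subtraction,
  vector normalization.
* **Peak detection** — SuperSmoother smoothing, scaled-MAD noise
  estimation, SNR-thresholded maxima with raw-grid position
  refinement, greedy matching to reference band positions.
* **Shift-tolerant non-negative decomposition** — each spectrum is
  fitted as

  y(w) ≈ Σₖ aₖ rₖ(w − sₖ),  aₖ ≥ 0, |sₖ| ≤ 0.1 cm⁻¹,

  by bounded L-BFGS-B from a non-negative least squares start, with
  R², range-normalized RMSE and reduced χ² per spectrum and
  bootstrap confidence intervals (1000 resamples) for cohort medians.
* **Cohort attribution statistics** — band-intensity Spearman
  correlation against an anchor band with a ρ > 0.6 membership rule,
  and centered–unscaled PCA with cosine matching of loadings to
  components and to component contrasts.
* **A synthetic serum-spectrum generator** — pseudo-Voigt component
  libraries at the serum band positions, donor cohorts with
  log-normal concentrations, polynomial backgrounds, enhancement
  variability and shot noise, plus spiking and isotopologue
  scenarios — so the whole chain is testable against known ground
  truth with no measured data.

## Worked example

Generate a small donor cohort, preprocess it, and decompose each
spectrum into the three serum components:

```r
library(sersdecomp)

lib <- default_library()           # free UA, HSA-bound UA, hypoxanthine
cohort <- generate_cohort(cohort_config(n_donors = 30, seed = 11), lib)
pp <- preprocess_set(cohort$set)   # crop + modpoly + vector normalize
fit <- fit_cohort(pp, lib, B = 200, seed = 11)
fit
#> <cohort_fit> 30 spectra
#>   median R^2      0.992 (0.991-0.992)
#>   median nRMSE    0.0086 (0.0085-0.0092)
#>   median red.chi2 20 (15.5-23.2)
```

Each spectrum is reconstructed almost perfectly (median R² 0.992 with
its bootstrap 95% CI); the reduced χ² far above 1 tells you the
residual is dominated by the baseline-recovery error rather than
noise — expected for very clean synthetic spectra, and discussed in
the vignette. Amplitudes track the generator's true concentrations
(Pearson r ≥ 0.999 per component once the recorded normalization and
enhancement factors are divided out).

Peak detection on the cohort's median spectrum labels the serum band
pattern:

```r
detect_peaks(sers_spectrum(pp$wavenumber, apply(pp$intensity, 2, median)))
#>    position height   snr
#> 1       638 0.2547 451.4
#> 2       725 0.0813 144.1
#> 3       813 0.0638 113.1
#> ...
#> 11     1659 0.0682 120.8
```

The full analysis lives in `analysis/01_simulate.R` …
`analysis/05_cohort_stats.R` — numbered drivers that generate the
cohorts, preprocess them, measure the 6 cm⁻¹ isotopologue downshift
of the 1659 cm⁻¹ band, decompose the 81-donor cohort, and run the
correlation/PCA attribution, writing all tables under `results/`.
`run_pipeline()` performs the same end-to-end run from a single
(optionally YAML) config with a manifest and reproducible seeding.

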