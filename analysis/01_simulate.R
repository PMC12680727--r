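#!/usr/bin/env Rscript
# Generate the synthetic datasets every later stage consumes:
#  - "donors": 81-donor cohort from the 3-component serum model
#    (free uric acid, HSA-bound uric acid, hypoxanthine), with
#    per-donor baselines, enhancement factors and shot noise;
#  - "serum": 81-sample 2-component cohort (one uric-acid pool +
#    hypoxanthine) used for the band-correlation attribution;
#  - a spike pair (uric acid +280 uM on a serum-like background);
#  - pure HSA-bound uric acid vs its isotopologue (1659 -> 1653 cm^-1).

library(sersdecomp)

seed <- 1L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

## 81-donor cohort, 3 components ---------------------------------------
lib3 <- default_library()
cfg3 <- cohort_config(n_donors = 81, seed = seed)
donors <- generate_cohort(cfg3, lib3)
write_set_csv(donors$set, "results/data/donors_raw.csv")
write.csv(donors$truth, "results/data/donors_truth.csv", row.names = FALSE)

## 81-sample 2-component serum cohort ----------------------------------
lib2 <- default_library(components = c("uric_acid", "hypoxanthine"))
cfg2 <- cohort_config(n_donors = 81, components = serum_components(),
                      seed = seed + 1L)
serum <- generate_cohort(cfg2, lib2)
write_set_csv(serum$set, "results/data/serum_raw.csv")
write.csv(serum$truth, "results/data/serum_truth.csv", row.names = FALSE)

## spike pair (noiseless, fixed enhancement) ---------------------------
cfg_spike <- cohort_config(components = serum_components(), noise_sd = 0,
                           scale_gsd = 1, seed = seed + 2L)
sp <- simulate_spike(c(uric_acid = 280, hypoxanthine = 10), "uric_acid",
                     added = 280, cfg_spike, lib2)
write_set_csv(sers_set(list(sp$unspiked, sp$spiked)),
              "results/data/spike_pair.csv")

## isotopologue pair ----------------------------------------------------
tab <- default_band_table("uric_acid_hsa")
iso_tab <- isotopologue_bands(tab, c("1659" = 1653))
w <- default_axis()
set.seed(seed + 3L)
noise <- function() rnorm(length(w), 0, 1 / (50 * sqrt(length(w))))
pair <- sers_set(list(
  sers_spectrum(w, build_reference(tab, w)$intensity + noise(),
                sample = "ua_hsa"),
  sers_spectrum(w, build_reference(iso_tab, w)$intensity + noise(),
                sample = "ua_hsa_isotopologue")))
write_set_csv(pair, "results/data/isotopologue_pair.csv")

cat("donors cohort:", n_spectra(donors$set), "spectra;",
    "noise sd", signif(donors$truth$noise_sd[1], 3), "counts\n")
cat("serum cohort: ", n_spectra(serum$set), "spectra\n")
cat("wrote results/data/{donors,serum}_raw.csv, *_truth.csv,",
    "spike_pair.csv, isotopologue_pair.csv\n")
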