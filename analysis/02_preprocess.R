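#!/usr/bin/env Rscript
# Preprocess both cohorts: crop to 400-1800 cm^-1, modpoly (degree 4)
# baseline subtraction, vector normalization. The corrected-but-not-
# normalized matrices are kept as well: band-correlation work uses
# them, because normalizing a closed low-rank mixture removes most of
# the concentration covariation that correlation analysis relies on.

library(sersdecomp)

dir.create("results", showWarnings = FALSE)

for (name in c("donors", "serum")) {
  raw <- read_set_csv(sprintf("results/data/%s_raw.csv", name))
  corrected <- preprocess_set(raw, normalize = FALSE)
  normalized <- preprocess_set(raw, normalize = TRUE)
  write_set_csv(corrected, sprintf("results/%s_corrected.csv", name))
  write_set_csv(normalized, sprintf("results/%s_preprocessed.csv", name))
  cat(sprintf(
    "%s: %d spectra; baseline converged for all: %s; norm factors %.0f-%.0f\n",
    name, n_spectra(raw), all(normalized$meta$baseline_converged),
    min(normalized$meta$norm_factor), max(normalized$meta$norm_factor)))
}
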