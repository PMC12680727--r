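#!/usr/bin/env Rscript
# Cohort attribution statistics:
#  - Spearman correlation of every tabulated band against the
#    638 cm^-1 anchor across the 2-component serum cohort, on
#    baseline-corrected intensities (uric-acid bands co-vary; the
#    hypoxanthine 725 cm^-1 band does not);
#  - centered, unscaled PCA of the normalized donors cohort with
#    loading-to-component matching.

library(sersdecomp)

## band correlation ------------------------------------------------------
serum <- read_set_csv("results/serum_corrected.csv")
ua_bands <- default_band_table("uric_acid")$center
hx_bands <- default_band_table("hypoxanthine")$center
bands <- sort(c(ua_bands, hx_bands))
bim <- band_intensity_matrix(serum, bands, tol = 3)
rep638 <- spearman_with_anchor(bim, anchor = 638, tau = 0.6)
rep725 <- spearman_with_anchor(bim, anchor = 725, tau = 0.6)
write.csv(rep638, "results/correlation_anchor638.csv", row.names = FALSE)
write.csv(rep725, "results/correlation_anchor725.csv", row.names = FALSE)

cat("bands with rho > 0.6 against 638 cm^-1:",
    paste(rep638$band[rep638$member], collapse = ", "), "\n")
cat("  (uric-acid table: ", paste(ua_bands, collapse = ", "), ")\n", sep = "")
cat("rho(725, 638) =", round(rep638$rho[rep638$band == 725], 3), "\n")
cat("bands with rho > 0.6 against 725 cm^-1:",
    paste(rep725$band[rep725$member], collapse = ", "), "\n")

## PCA --------------------------------------------------------------------
donors <- read_set_csv("results/donors_preprocessed.csv")
pca <- run_pca(donors, n_components = 10)
print(pca)
write.csv(data.frame(pc = seq_along(pca$explained),
                     explained = pca$explained,
                     cumulative = pca$cumulative),
          "results/pca_variance.csv", row.names = FALSE)
write.csv(data.frame(wavenumber = pca$wavenumber, pca$loadings),
          "results/pca_loadings.csv", row.names = FALSE)

ml <- match_loadings(pca, default_library())
cat("PC1-3 cosine similarity to components:\n")
print(round(ml$components[1:3, ], 3))
cat("PC1-3 cosine similarity to component contrasts:\n")
print(round(ml$contrasts[1:3, ], 3))
write.csv(ml$components, "results/pca_loading_component_match.csv")
write.csv(ml$contrasts, "results/pca_loading_contrast_match.csv")
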