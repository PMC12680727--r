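#!/usr/bin/env Rscript
# Band detection: locate the maxima of the median preprocessed donor
# spectrum (the serum band pattern), and measure the isotopologue
# downshift of the 1659 cm^-1 HSA-bound uric-acid band by detecting
# peaks in both spectra and matching them.

library(sersdecomp)

pp <- read_set_csv("results/donors_preprocessed.csv")
median_spec <- sers_spectrum(pp$wavenumber,
                             apply(pp$intensity, 2, median),
                             sample = "median_donor")
pk <- detect_peaks(median_spec)
write.csv(pk, "results/donor_median_peaks.csv", row.names = FALSE)
cat("median donor spectrum:", nrow(pk), "bands detected\n")
print(pk, digits = 3)

known <- sort(unique(c(default_band_table("uric_acid_free")$center,
                       default_band_table("uric_acid_hsa")$center,
                       default_band_table("hypoxanthine")$center)))
m <- match_peaks(pk, known, tol = 3)
cat(sum(m$matched), "of", nrow(pk),
    "detected bands match a tabulated component band within 3 cm^-1\n")

## isotopologue shift ---------------------------------------------------
pair <- read_set_csv("results/data/isotopologue_pair.csv")
p_ref <- detect_peaks(get_spectrum(pair, 1))
p_iso <- detect_peaks(get_spectrum(pair, 2))
band_1659 <- p_ref$position[which.min(abs(p_ref$position - 1659))]
mm <- match_peaks(p_iso, band_1659, tol = 10)
shift <- mm$offset[mm$matched][1]
cat(sprintf("C6=O stretching band: %g -> %g cm^-1 (downshift %g cm^-1)\n",
            band_1659, band_1659 + shift, -shift))
write.csv(data.frame(band = band_1659, shifted_to = band_1659 + shift,
                     downshift = -shift),
          "results/isotopologue_shift.csv", row.names = FALSE)
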