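# Random spectrum-set fixture on a given axis.
new_set_for_test <- function(n, wavenumber) {
  m <- matrix(rexp(n * length(wavenumber)) * 100, nrow = n)
  spectra <- lapply(seq_len(n), function(i) {
    sers_spectrum(wavenumber, m[i, ], sample = sprintf("s%02d", i))
  })
  sers_set(spectra)
}
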