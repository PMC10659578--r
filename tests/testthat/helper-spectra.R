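# small spectra and analytic band evaluation used across tests

band_eps <- function(lambda, center, fwhm, peak) {
  peak * exp(-4 * log(2) * (lambda - center)^2 / fwhm^2)
}

# asymmetric bands so the crossing does not fall on a grid point; the grid
# stops at 640 nm so band tails stay above the 1e-12 coincidence tolerance
two_band_pair <- function(grid = seq(350, 640, by = 1)) {
  a <- build_species_spectrum(gaussian_bands(450, 40, 80), grid, "a", "ferric")
  b <- build_species_spectrum(gaussian_bands(523, 36, 70), grid, "b", "ferrous")
  list(a = a, b = b)
}
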