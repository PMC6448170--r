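# Shared fixtures, built once per test run. Everything is generated in code;
# no stored binary data.

XS <- load_attenuation()

# 120 kV filtered fallback beam at isocenter distance (62.56 cm)
SPEC_UNFILTERED <- fallback_spectrum(kv = 120)
SPEC_FILTERED <- apply_filtration(
  SPEC_UNFILTERED,
  list(filter_layer("carbon", 3.6), filter_layer("aluminum", 9.3)), XS)
SPEC_ISO <- rescale_distance(SPEC_FILTERED, 62.56)

# fitted scanner model (synthetic bowtie + 80 mm heel profile)
build_scanner <- function(collimation_mm = 80) {
  bt <- fit_bowtie_thickness(synthetic_bowtie_measurement(SPEC_ISO, XS),
                             SPEC_ISO, XS)
  scan <- synthetic_beam_profile_scan(collimation_mm = collimation_mm)
  bp <- beam_profile(scan$z_mm, scan$normalized_intensity)
  scanner_model(bt, bp, source_geometry(625.6))
}
SCANNER80 <- build_scanner(80)

# static-tube in-air protocol used by several transport tests
PROT_STATIC <- scan_protocol("axial", kv = 120, mA = 300,
                             collimation_mm = 80, rotating = FALSE)

# uniform single-material phantom helper (hu constant everywhere)
uniform_phantom <- function(hu, extent_mm = c(400, 400, 400),
                            spacing_mm = c(8, 8, 8)) {
  dims <- as.integer(ceiling(extent_mm / spacing_mm))
  origin <- -(dims - 1) / 2 * spacing_mm
  voxel_phantom(array(as.integer(hu), dim = dims), spacing_mm, origin)
}

# monoenergetic single-bin spectrum centred on `energy`
mono_spectrum <- function(energy, fluence = 1, distance = 100) {
  energy_spectrum(c(energy - 0.5, energy + 0.5), fluence, distance,
                  kv = energy + 0.5)
}

# Klein-Nishina quadrature oracle: moments of the scattered-energy fraction
kn_quadrature <- function(energy_keV) {
  alpha <- energy_keV / 510.999
  f <- function(mu) {
    r <- 1 / (1 + alpha * (1 - mu))
    r^2 * (r + 1 / r - 1 + mu^2)
  }
  norm <- stats::integrate(f, -1, 1, rel.tol = 1e-10)$value
  mean_r <- stats::integrate(function(mu) f(mu) / (1 + alpha * (1 - mu)),
                             -1, 1, rel.tol = 1e-10)$value / norm
  list(mean_fraction = mean_r, transfer_fraction = 1 - mean_r)
}
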