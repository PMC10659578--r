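# Canonical species spectra and the named experiment fixtures.
#
# Band positions follow the spectral landmarks of b-type low-spin hemes in
# STEAP proteins: ferric Soret at 413 nm with a broad Q band near 550 nm;
# ferrous Soret at 427 nm with alpha/beta bands resolved at 560/532 nm.
# Peak molar absorptivities are NOT experimentally determined values: they
# are synthetic placeholders (Soret ~100, Q/alpha/beta ~10 mM^-1 cm^-1,
# typical magnitudes for b hemes) and are flagged as such in provenance.

#' Canonical synthetic species spectra
#'
#' Gaussian-band spectra for the redox species appearing in the fixtures:
#' ferric/ferrous STEAP heme, oxidized/reduced flavin (FAD), and
#' oxidized/reduced cytochrome b5 reductase (dominated by its bound flavin).
#' Peak absorptivities are synthetic placeholders, not measured extinction
#' coefficients.
#'
#' @param grid_nm Wavelength grid.
#' @return A [species_library()] with species `heme_ferric`, `heme_ferrous`,
#'   `flavin_ox`, `flavin_red`, `b5r_ox`, `b5r_red`.
#' @export
canonical_spectra <- function(grid_nm = default_grid_nm()) {
  species_library(
    build_species_spectrum(
      gaussian_bands(c(413, 550), c(28, 90), c(100, 10)),
      grid_nm, "heme_ferric", "ferric"),
    build_species_spectrum(
      gaussian_bands(c(427, 560, 532), c(24, 14, 14), c(110, 13, 11)),
      grid_nm, "heme_ferrous", "ferrous"),
    build_species_spectrum(
      gaussian_bands(c(450, 380), c(55, 35), c(11, 10)),
      grid_nm, "flavin_ox", "oxidized_flavin"),
    build_species_spectrum(
      gaussian_bands(c(450, 380), c(55, 35), c(1.2, 3)),
      grid_nm, "flavin_red", "reduced_flavin"),
    build_species_spectrum(
      gaussian_bands(c(461, 386), c(55, 35), c(10.5, 9.5)),
      grid_nm, "b5r_ox", "oxidized_flavin"),
    build_species_spectrum(
      gaussian_bands(c(461, 386), c(55, 35), c(1.1, 2.8)),
      grid_nm, "b5r_red", "reduced_flavin")
  )
}

# composite spectrum: elementwise sum of library species (equimolar mixture
# treated as one kinetic species)
composite_spectrum <- function(library, parts, name) {
  eps <- rep(0, nrow(library))
  for (p in parts) eps <- eps + library[[p]]
  out <- tibble(wavelength_nm = library$wavelength_nm, epsilon = eps)
  attr(out, "name") <- name
  attr(out, "redox_state") <- "other"
  class(out) <- c("species_spectrum", class(out))
  out
}

# epsilon of a library species at a wavelength (nearest grid point)
eps_at <- function(library, species, wavelength_nm) {
  j <- which.min(abs(library$wavelength_nm - wavelength_nm))
  library[[species]][j]
}

fixture_defs <- function() {
  list(
    fig2A_fadh_steap1 = list(
      type = "timecourse",
      description = "Biphasic A427 rise: 1.1 uM ferric STEAP1 reduced by 4.5 uM FADH-; k_obs 7.7 and 0.67 s^-1, 60%/40% amplitude split, 20 s window."),
    fig2B_inset_titration = list(
      type = "titration",
      description = "Hyperbolic k_obs vs [FADH-] for WT STEAP1, fast phase: Vmax 12 s^-1, KM 4.7 uM; 5 log-spaced points 1-20 uM."),
    fig2C_mixture = list(
      type = "rapid_scan",
      description = "Two-species NADPH-driven reduction of a 1.1 uM STEAP2 + 0.9 uM STEAP1 mixture (2.2 uM FAD, 60 uM NADPH); rate 5.5e-4 s^-1, 1 h window."),
    fig2s1_L230G = list(
      type = "titration",
      description = "Hyperbolic k_obs vs [FADH-] for L230G STEAP1, fast phase: Vmax 2 s^-1, KM 3.6 uM; 5 log-spaced points 1-20 uM."),
    fig3A_b5r = list(
      type = "rapid_scan",
      description = "Three-species reduction of 1.5 uM STEAP1 by 1.5 uM b5R + 10 uM NADH; A->B 177.9 s^-1, B->C 0.13 s^-1, 20 s window."),
    fig4s1_steap2_nadph = list(
      type = "rapid_scan",
      description = "Two-species NADPH-driven reduction of 2.3 uM STEAP2 (2.5 uM FAD); rate 1.2e-3 s^-1, 1 h window."),
    fig4s1_steap2_fadh = list(
      type = "timecourse",
      description = "Biphasic A427 rise: STEAP2 reduced by 4.5 uM FADH-; k_obs 2.9 (16%) and 0.069 s^-1 (84%)."),
    fig5_steap1_nta = list(
      type = "oxidation_series",
      description = "Ferrous 1.1 uM STEAP1 oxidized by 25-175 uM Fe3+-NTA; two populations (85%/15%) with k_on 1.5e5/7.6e3 M^-1 s^-1, k_off 7.5/0.2 s^-1."),
    fig5_steap2_nta = list(
      type = "oxidation_series",
      description = "Ferrous 1.1 uM STEAP2 oxidized by 75-175 uM Fe3+-NTA; two populations with k_on 1.1e4/3.5e3 M^-1 s^-1, k_off 2.2/0.3 s^-1; 2 s analysis window."),
    bli_b5r = list(
      type = "bli",
      description = "BLI dose-response of b5R binding immobilized STEAP1; K_D 5.9 uM at analyte 20, 10, 5, 2.5, 1.3, 0.6 uM.")
  )
}

#' Catalog of named experiment fixtures
#'
#' Each fixture encodes the concentrations, rate constants and observation
#' windows of one characterized STEAP kinetics experiment, so that generated
#' data carry a known ground truth for round-trip testing of the fits.
#'
#' @return Tibble with columns `name`, `type`, `description`.
#' @export
fixture_catalog <- function() {
  defs <- fixture_defs()
  tibble(name = names(defs),
         type = vapply(defs, `[[`, "", "type"),
         description = vapply(defs, `[[`, "", "description"))
}

#' Generate a named fixture dataset
#'
#' @param name Fixture name; see [fixture_catalog()].
#' @param seed Integer seed for the noise (or `NULL`).
#' @param sigma_AU Photometric noise sd (AU); 0 gives noiseless data.
#' @return The generated dataset; its class depends on the fixture type
#'   (`heme_timecourse`, `rapid_scan`, `titration`, `bli_series`, or a list
#'   of time courses for the oxidation series). Generator truth is always in
#'   the `provenance` attribute/field.
#' @examples
#' tc <- hemekin_fixture("fig2A_fadh_steap1", seed = 1)
#' fit_multiexponential(tc, n_phases = 2, direction = "rise")
#' @export
hemekin_fixture <- function(name, seed = NULL, sigma_AU = 0.002) {
  defs <- fixture_defs()
  if (!name %in% names(defs)) {
    stopf("unknown fixture '%s'; see fixture_catalog().", name)
  }
  lib <- canonical_spectra()
  noise <- noise_model(sigma_AU = sigma_AU, seed = seed)
  titr_s <- logspace(1, 20, 5)  # [FADH-] series, uM (values not published)
  switch(name,
    fig2A_fadh_steap1 = {
      d_eps <- eps_at(lib, "heme_ferrous", 427) - eps_at(lib, "heme_ferric", 427)
      total <- d_eps * 1.1 / 1000  # 1.1 uM STEAP1, 1 cm
      generate_timecourse(
        phases = tibble(k_obs = c(7.7, 0.67), amplitude = total * c(0.6, 0.4)),
        offset = eps_at(lib, "heme_ferric", 427) * 1.1 / 1000,
        direction = "rise", noise = noise,
        time_s = default_time_grid(20), wavelength_nm = 427)
    },
    fig2B_inset_titration = generate_titration(
      "hyperbolic", list(vmax = 12, km = 4.7), titr_s,
      noise_frac = if (sigma_AU > 0) 0.05 else 0, seed = seed),
    fig2s1_L230G = generate_titration(
      "hyperbolic", list(vmax = 2, km = 3.6), titr_s,
      noise_frac = if (sigma_AU > 0) 0.05 else 0, seed = seed),
    fig2C_mixture = {
      lib2 <- species_library(
        composite_spectrum(lib, c("heme_ferric", "flavin_ox"), "A"),
        composite_spectrum(lib, c("heme_ferrous", "flavin_red"), "B"))
      generate_rapid_scan(
        sequential_model(c("A", "B"), 5.5e-4), lib2,
        experiment_conditions(enzyme_uM = 2.0, substrate_uM = 60),
        noise = noise, time_s = default_time_grid(3600, t_min = 0.1))
    },
    fig3A_b5r = {
      lib3 <- species_library(
        composite_spectrum(lib, c("heme_ferric", "b5r_ox"), "A"),
        composite_spectrum(lib, c("heme_ferric", "b5r_red"), "B"),
        composite_spectrum(lib, c("heme_ferrous", "b5r_red"), "C"))
      generate_rapid_scan(
        sequential_model(c("A", "B", "C"), c(177.9, 0.13)), lib3,
        experiment_conditions(enzyme_uM = 1.5, substrate_uM = 10,
                              dead_time_s = 1.5e-3),
        noise = noise,
        # log grid from 2 ms: >= 5 points inside the first 30 ms
        time_s = default_time_grid(20, t_min = 2e-3))
    },
    fig4s1_steap2_nadph = {
      lib2 <- species_library(
        composite_spectrum(lib, c("heme_ferric", "flavin_ox"), "A"),
        composite_spectrum(lib, c("heme_ferrous", "flavin_red"), "B"))
      generate_rapid_scan(
        sequential_model(c("A", "B"), 1.2e-3), lib2,
        experiment_conditions(enzyme_uM = 2.3, substrate_uM = 60),
        noise = noise, time_s = default_time_grid(3600, t_min = 0.1))
    },
    fig4s1_steap2_fadh = {
      d_eps <- eps_at(lib, "heme_ferrous", 427) - eps_at(lib, "heme_ferric", 427)
      total <- d_eps * 1.1 / 1000
      generate_timecourse(
        phases = tibble(k_obs = c(2.9, 0.069), amplitude = total * c(0.16, 0.84)),
        offset = eps_at(lib, "heme_ferric", 427) * 1.1 / 1000,
        direction = "rise", noise = noise,
        time_s = default_time_grid(120), wavelength_nm = 427)
    },
    fig5_steap1_nta = oxidation_series_fixture(
      lib, model = two_population_model(c(0.85, 0.15), c(1.5e5, 7.6e3), c(7.5, 0.2)),
      substrate_uM = c(25, 75, 125, 175), e0 = 1.1, t_max = 20,
      window_s = NULL, noise = noise),
    fig5_steap2_nta = oxidation_series_fixture(
      lib, model = two_population_model(c(0.5, 0.5), c(1.1e4, 3.5e3), c(2.2, 0.3)),
      substrate_uM = c(75, 125, 175), e0 = 1.1, t_max = 20,
      window_s = c(0, 2), noise = noise),
    bli_b5r = generate_bli(
      kd_uM = 5.9, rmax = 1, analyte_uM = c(20, 10, 5, 2.5, 1.3, 0.6),
      sigma = if (sigma_AU > 0) 0.005 else 0,
      req_noise_frac = if (sigma_AU > 0) 0.02 else 0, seed = seed)
  )
}

# A427 decay traces for ferrous heme oxidation by Fe3+-NTA, one per
# substrate concentration. The phase fractions of the STEAP2 populations are
# not published; equal fractions are used there (see the methods vignette).
oxidation_series_fixture <- function(lib, model, substrate_uM, e0, t_max,
                                     window_s, noise) {
  d_eps <- eps_at(lib, "heme_ferrous", 427) - eps_at(lib, "heme_ferric", 427)
  amp_total <- d_eps * e0 / 1000
  offset <- eps_at(lib, "heme_ferric", 427) * e0 / 1000
  tcs <- purrr::map(seq_along(substrate_uM), function(i) {
    k_obs <- model$k_on * substrate_uM[i] * 1e-6 + model$k_off
    seed_i <- if (is.null(noise$seed)) NULL else noise$seed + i - 1L
    generate_timecourse(
      phases = tibble(k_obs = k_obs, amplitude = amp_total * model$fractions),
      offset = offset, direction = "decay",
      noise = noise_model(noise$sigma_AU, seed_i),
      time_s = default_time_grid(t_max, t_min = 1e-3), wavelength_nm = 427)
  })
  names(tcs) <- paste0("S_", substrate_uM, "uM")
  structure(list(timecourses = tcs, substrate_uM = substrate_uM,
                 model = model, e0_uM = e0, window_s = window_s,
                 provenance = list(generator = "oxidation_series",
                                   k_on = model$k_on, k_off = model$k_off,
                                   fractions = model$fractions,
                                   sigma_AU = noise$sigma_AU, seed = noise$seed)),
            class = "oxidation_series")
}
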