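Package: hemekin
Title: Pre-Steady-State Kinetics of Heme and Flavin Redox Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of time-resolved absorbance data from
    stopped-flow and rapid-scan experiments on membrane-bound hemoproteins
    such as the STEAP metalloreductases. Provides a Gaussian-band spectral
    forward model with Beer-Lambert mixture composition, simulators for
    sequential first-order kinetic chains (closed-form Bateman solutions with
    a stiff ODE fallback), two-population pseudo-first-order heme oxidation,
    and a diffusible-flavin electron-shuttle mechanism; seeded synthetic-data
    generators for single-wavelength time courses, rapid-scan time-by-
    wavelength matrices, rate-saturation titrations, and bio-layer
    interferometry (BLI) dose-response series; multi-exponential time-course
    fitting with multistart variable projection, hyperbolic (Michaelis-
    Menten-type) saturation fits, linear k_obs-versus-substrate fits yielding
    k_on, k_off and K_D, and BLI binding fits; and SVD rank estimation plus
    variable-projection global deconvolution of rapid-scan matrices into
    sequential spectral species and interconversion rate constants. All
    user-facing functions take data frames and return tibbles, with broom-
    style tidy() and glance() methods and ggplot2 autoplot() methods for
    every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    minpack.lm,
    withr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
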