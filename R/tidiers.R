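# broom-style tidiers for the fitted objects

#' Tidy a multi-exponential fit
#'
#' @param x A `multiexp_fit`.
#' @param ... Unused.
#' @return One row per phase: `phase`, `k_obs`, `k_obs_se`, `amplitude`,
#'   `amplitude_se`, `fraction_pct` (fractions sum to 100).
#' @method tidy multiexp_fit
#' @export
tidy.multiexp_fit <- function(x, ...) {
  x$phases[, c("phase", "k_obs", "k_obs_se", "amplitude", "amplitude_se",
               "fraction_pct")]
}

#' @rdname tidy.multiexp_fit
#' @method glance multiexp_fit
#' @export
glance.multiexp_fit <- function(x, ...) {
  tibble(n_phases = nrow(x$phases), offset = x$offset, offset_se = x$offset_se,
         direction = x$direction, n_points = x$n_points,
         residual_sse = x$residual_sse, sigma = x$sigma, aic = x$aic,
         window_min_s = x$window_s[1], window_max_s = x$window_s[2],
         converged = x$convergence == 0)
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat("<multiexp_fit> ", nrow(x$phases), "-phase ", x$direction, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a hyperbolic saturation fit
#'
#' @param x A `hyperbolic_fit`.
#' @param ... Unused.
#' @return Rows `vmax` (s^-1) and `km` (uM) with estimates and standard
#'   errors.
#' @method tidy hyperbolic_fit
#' @export
tidy.hyperbolic_fit <- function(x, ...) {
  tibble(term = c("vmax", "km"), estimate = c(x$vmax, x$km),
         std.error = c(x$vmax_se, x$km_se))
}

#' @rdname tidy.hyperbolic_fit
#' @method glance hyperbolic_fit
#' @export
glance.hyperbolic_fit <- function(x, ...) {
  tibble(residual_sse = x$residual_sse, n = x$n)
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat("<hyperbolic_fit> Vmax = ", signif(x$vmax, 4), " s^-1, KM = ",
      signif(x$km, 4), " uM\n", sep = "")
  invisible(x)
}

#' Tidy a linear k_obs-vs-substrate fit
#'
#' @param x A `linear_kobs_fit`.
#' @param ... Unused.
#' @return Rows `k_on` (M^-1 s^-1), `k_off` (s^-1), `kd_uM` (uM).
#' @method tidy linear_kobs_fit
#' @export
tidy.linear_kobs_fit <- function(x, ...) {
  tibble(term = c("k_on", "k_off", "kd_uM"),
         estimate = c(x$k_on, x$k_off, x$kd_uM),
         std.error = c(x$k_on_se, x$k_off_se, x$kd_uM_se))
}

#' @rdname tidy.linear_kobs_fit
#' @method glance linear_kobs_fit
#' @export
glance.linear_kobs_fit <- function(x, ...) {
  tibble(residual_sse = x$residual_sse, n = x$n)
}

#' @export
print.linear_kobs_fit <- function(x, ...) {
  cat("<linear_kobs_fit> k_on = ", signif(x$k_on, 4), " M^-1 s^-1, k_off = ",
      signif(x$k_off, 4), " s^-1, K_D = ", signif(x$kd_uM, 4), " uM\n", sep = "")
  invisible(x)
}

#' Tidy a BLI dose-response fit
#'
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return Rows `kd_uM` and `rmax` with estimates and standard errors.
#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(term = c("kd_uM", "rmax"), estimate = c(x$kd_uM, x$rmax),
         std.error = c(x$kd_uM_se, x$rmax_se))
}

#' @rdname tidy.dose_response_fit
#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(residual_sse = x$residual_sse, n = nrow(x$req))
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> K_D = ", signif(x$kd_uM, 4), " uM, Rmax = ",
      signif(x$rmax, 4), "\n", sep = "")
  invisible(x)
}

#' Tidy a deconvolution result
#'
#' @param x A `deconvolution`.
#' @param what `"rates"` (default), `"spectra"` or `"profiles"`.
#' @param ... Unused.
#' @return A tibble in long format for spectra/profiles, or one row per
#'   interconversion step for rates.
#' @method tidy deconvolution
#' @export
tidy.deconvolution <- function(x, what = c("rates", "spectra", "profiles"), ...) {
  what <- match.arg(what)
  switch(what,
    rates = tibble(step = paste0("species_", seq_along(x$rates), " -> species_",
                                 seq_along(x$rates) + 1L),
                   rate_s1 = x$rates),
    spectra = tidyr::pivot_longer(x$species_spectra, -"wavelength_nm",
                                  names_to = "species", values_to = "absorbance"),
    profiles = tidyr::pivot_longer(x$concentration_profiles, -"time_s",
                                   names_to = "species", values_to = "fraction"))
}

#' @rdname tidy.deconvolution
#' @method glance deconvolution
#' @export
glance.deconvolution <- function(x, ...) {
  tibble(n_species = x$n_species, residual_norm = x$residual_norm,
         nonneg_spectra = x$nonneg_spectra, converged = x$convergence == 0,
         n_times = x$dims[1], n_wavelengths = x$dims[2])
}
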