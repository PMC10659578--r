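# ggplot2 autoplot methods

#' Plot a time course
#'
#' @param object A `heme_timecourse`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot heme_timecourse
#' @export
autoplot.heme_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$absorbance)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = "absorbance (AU)")
}

#' Plot selected spectra of a rapid-scan dataset
#'
#' @param object A `rapid_scan`.
#' @param n_times Number of (log-spaced) time slices to draw.
#' @param ... Unused.
#' @return A ggplot of absorbance vs wavelength coloured by time.
#' @method autoplot rapid_scan
#' @export
autoplot.rapid_scan <- function(object, n_times = 8, ...) {
  idx <- unique(round(seq(1, length(object$time_s), length.out = n_times)))
  df <- tidy.rapid_scan(object)
  df <- df[df$time_s %in% object$time_s[idx], ]
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$absorbance,
                                   colour = factor(signif(.data$time_s, 3)))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance (AU)", colour = "t (s)")
}

#' Plot a multi-exponential fit over its data
#'
#' @param object A `multiexp_fit`.
#' @param ... Unused.
#' @return A ggplot with the data points and the fitted curve.
#' @method autoplot multiexp_fit
#' @export
autoplot.multiexp_fit <- function(object, ...) {
  t <- object$data$time_s
  X <- exp_design(object$phases$k_obs, t, object$direction)
  fitted <- as.vector(X %*% c(object$offset, object$phases$amplitude))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_s, .data$absorbance)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(data = tibble(time_s = t, absorbance = fitted),
                       colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = "absorbance (AU)")
}

#' Plot a titration with its fitted law
#'
#' @param object A `hyperbolic_fit` or `linear_kobs_fit`.
#' @param ... Unused.
#' @return A ggplot of k_obs vs substrate with the fitted curve.
#' @method autoplot hyperbolic_fit
#' @export
autoplot.hyperbolic_fit <- function(object, ...) {
  s_grid <- seq(0, max(object$data$substrate_uM), length.out = 200)
  curve <- tibble(substrate_uM = s_grid,
                  k_obs = object$vmax * s_grid / (object$km + s_grid))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$substrate_uM, .data$k_obs)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(x = "[S] (uM)", y = "k_obs (s^-1)")
}

#' @rdname autoplot.hyperbolic_fit
#' @method autoplot linear_kobs_fit
#' @export
autoplot.linear_kobs_fit <- function(object, ...) {
  s_grid <- c(0, max(object$data$substrate_uM))
  curve <- tibble(substrate_uM = s_grid,
                  k_obs = object$k_on * 1e-6 * s_grid + object$k_off)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$substrate_uM, .data$k_obs)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(x = "[S] (uM)", y = "k_obs (s^-1)")
}

#' Plot a deconvolution result
#'
#' @param object A `deconvolution`.
#' @param what `"spectra"` or `"profiles"`.
#' @param ... Unused.
#' @return A ggplot of the recovered species spectra or of the
#'   concentration-fraction profiles.
#' @method autoplot deconvolution
#' @export
autoplot.deconvolution <- function(object, what = c("spectra", "profiles"), ...) {
  what <- match.arg(what)
  if (what == "spectra") {
    df <- tidy.deconvolution(object, "spectra")
    ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$absorbance,
                                     colour = .data$species)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "wavelength (nm)", y = "absorbance (AU)")
  } else {
    df <- tidy.deconvolution(object, "profiles")
    ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$fraction,
                                     colour = .data$species)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "time (s)", y = "population fraction")
  }
}

#' Plot a BLI dose-response fit
#'
#' @param object A `dose_response_fit`.
#' @param ... Unused.
#' @return A ggplot of Req vs analyte with the fitted dose-response curve.
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  a_grid <- seq(0, max(object$req$analyte_uM), length.out = 200)
  curve <- tibble(analyte_uM = a_grid,
                  req = object$rmax * a_grid / (object$kd_uM + a_grid))
  ggplot2::ggplot(object$req, ggplot2::aes(.data$analyte_uM, .data$req)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(x = "[analyte] (uM)", y = "Req")
}
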