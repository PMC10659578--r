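#' Experiment conditions
#'
#' Concentrations and instrument settings shared by the synthetic-data
#' generators.
#'
#' @param enzyme_uM Enzyme (heme) concentration after mixing (\eqn{\mu}M).
#' @param substrate_uM Substrate concentration(s) (\eqn{\mu}M); scalar or
#'   series.
#' @param dead_time_s Instrument dead time (s): reaction time elapsed before
#'   the first observable point. Default 1.5 ms, typical of a stopped-flow
#'   mixer.
#' @param pathlength_cm Optical pathlength (cm).
#' @param mix_ratio Volume ratio of the two syringes (1 = equal volumes).
#' @return An `experiment_conditions` list.
#' @export
experiment_conditions <- function(enzyme_uM, substrate_uM = NULL,
                                  dead_time_s = 1.5e-3, pathlength_cm = 1,
                                  mix_ratio = 1) {
  check_number(enzyme_uM, "enzyme_uM", lower = 0, strict = TRUE)
  if (!is.null(substrate_uM) && any(substrate_uM < 0)) {
    stopf("`substrate_uM` must be >= 0.")
  }
  check_number(dead_time_s, "dead_time_s", lower = 0)
  check_number(pathlength_cm, "pathlength_cm", lower = 0, strict = TRUE)
  check_number(mix_ratio, "mix_ratio", lower = 0, strict = TRUE)
  structure(list(enzyme_uM = enzyme_uM, substrate_uM = substrate_uM,
                 dead_time_s = dead_time_s, pathlength_cm = pathlength_cm,
                 mix_ratio = mix_ratio),
            class = "experiment_conditions")
}

#' Photometric noise model
#'
#' Additive Gaussian noise on absorbance readings. The default sigma of
#' 0.002 AU is a realistic photodiode-array noise floor; the seed is recorded
#' in every generated dataset's provenance.
#'
#' @param sigma_AU Standard deviation (AU), >= 0.
#' @param seed Integer seed, or `NULL` for no reseeding.
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma_AU = 0.002, seed = NULL) {
  check_number(sigma_AU, "sigma_AU", lower = 0)
  structure(list(sigma_AU = sigma_AU, seed = seed), class = "noise_model")
}

#' Default log-spaced stopped-flow time grid
#'
#' 400 points log-spaced between `t_min` and `t_max`, resolving kinetic
#' phases separated by more than a thousand-fold in rate.
#'
#' @param t_max Last time point (s).
#' @param t_min First recorded time point (s).
#' @param n Number of points.
#' @return Numeric time grid (s).
#' @export
default_time_grid <- function(t_max, t_min = 1e-3, n = 400) {
  check_number(t_min, "t_min", lower = 0, strict = TRUE)
  check_number(t_max, "t_max", lower = t_min, strict = TRUE)
  logspace(t_min, t_max, n)
}

#' Generate a rapid-scan time-by-wavelength dataset
#'
#' Runs a sequential mechanism forward, composes the Beer--Lambert mixture
#' absorbance of the species spectra at every time point, and adds Gaussian
#' photometric noise. The recorded time axis starts after the instrument
#' dead time: a recorded time `t` corresponds to reaction time
#' `t + dead_time_s`, and `dead_time_s` is stored with the dataset so the
#' deconvolution can account for the unobserved early reaction.
#'
#' @param mechanism A [sequential_model()] whose species names all appear in
#'   `library`.
#' @param library A [species_library()].
#' @param conditions An [experiment_conditions()]; `enzyme_uM` sets the total
#'   concentration of the initial species.
#' @param noise A [noise_model()].
#' @param time_s Recorded time grid (s, strictly increasing, all >
#'   0). Default: 400 log-spaced points to `t_max`.
#' @param t_max Used only when `time_s` is `NULL`.
#' @return A `rapid_scan` object: list with `time_s`, `grid_nm`, `absorbance`
#'   (time x wavelength matrix, AU), `conditions`, and `provenance`
#'   (generator parameters incl. seed and the true rates).
#' @export
generate_rapid_scan <- function(mechanism, library, conditions,
                                noise = noise_model(), time_s = NULL,
                                t_max = 20) {
  if (!inherits(mechanism, "sequential_model")) {
    stopf("`mechanism` must be a sequential_model.")
  }
  missing_sp <- setdiff(mechanism$species_names, library_species(library))
  if (length(missing_sp) > 0) {
    stopf("mechanism species absent from library: %s",
          paste(missing_sp, collapse = ", "))
  }
  if (is.null(time_s)) time_s <- default_time_grid(t_max)
  check_increasing(time_s, "time_s")
  if (time_s[1] <= 0) stopf("recorded `time_s` must be > 0 (t = 0 is the end of the dead time).")
  traj <- simulate_sequential(mechanism, c0 = conditions$enzyme_uM,
                              time_s = time_s + conditions$dead_time_s)
  conc <- as.matrix(traj[, mechanism$species_names, drop = FALSE])
  eps <- as.matrix(library[, mechanism$species_names, drop = FALSE])
  a <- conc %*% t(eps) * (conditions$pathlength_cm / 1000)
  a <- with_seed(noise$seed, a + matrix(rnorm(length(a), sd = noise$sigma_AU),
                                        nrow = nrow(a)))
  structure(list(
    time_s = as.numeric(time_s),
    grid_nm = library$wavelength_nm,
    absorbance = a,
    conditions = conditions,
    provenance = list(generator = "rapid_scan",
                      species = mechanism$species_names,
                      rates_s1 = mechanism$rates,
                      enzyme_uM = conditions$enzyme_uM,
                      dead_time_s = conditions$dead_time_s,
                      sigma_AU = noise$sigma_AU,
                      seed = noise$seed)),
    class = "rapid_scan")
}

#' @export
print.rapid_scan <- function(x, ...) {
  cat("<rapid_scan> ", length(x$time_s), " times x ", length(x$grid_nm),
      " wavelengths, t = ", signif(min(x$time_s), 3), "-",
      signif(max(x$time_s), 3), " s\n", sep = "")
  invisible(x)
}

#' @method tidy rapid_scan
#' @export
tidy.rapid_scan <- function(x, ...) {
  tibble(
    time_s = rep(x$time_s, times = length(x$grid_nm)),
    wavelength_nm = rep(x$grid_nm, each = length(x$time_s)),
    absorbance = as.vector(x$absorbance)
  )
}

#' Extract a single-wavelength time course from a rapid-scan dataset
#'
#' @param dataset A `rapid_scan`.
#' @param wavelength_nm Wavelength to extract (nearest grid point is used).
#' @return A `heme_timecourse` tibble (`time_s`, `absorbance`).
#' @export
extract_timecourse <- function(dataset, wavelength_nm) {
  j <- which.min(abs(dataset$grid_nm - wavelength_nm))
  new_timecourse(dataset$time_s, dataset$absorbance[, j],
                 wavelength_nm = dataset$grid_nm[j],
                 conditions = dataset$conditions,
                 provenance = dataset$provenance)
}

new_timecourse <- function(time_s, absorbance, wavelength_nm = NA_real_,
                           conditions = NULL, provenance = NULL) {
  out <- tibble(time_s = as.numeric(time_s), absorbance = as.numeric(absorbance))
  attr(out, "wavelength_nm") <- wavelength_nm
  attr(out, "conditions") <- conditions
  attr(out, "provenance") <- provenance
  class(out) <- c("heme_timecourse", class(out))
  out
}

#' Generate a single-wavelength exponential time course
#'
#' The multi-exponential fit model run forward:
#' rising traces (heme reduction followed at the ferrous Soret band)
#' \eqn{A(t) = \mathrm{offset} + \sum_i a_i (1 - e^{-k_i t})}; decaying
#' traces (heme oxidation) \eqn{A(t) = \mathrm{offset} + \sum_i a_i
#' e^{-k_i t}}; plus Gaussian noise.
#'
#' @param phases Data frame with columns `k_obs` (s\eqn{^{-1}}, > 0) and
#'   `amplitude` (AU); at least one row.
#' @param offset Baseline absorbance (AU).
#' @param direction `"rise"` or `"decay"`.
#' @param noise A [noise_model()].
#' @param time_s Strictly increasing time grid (s).
#' @param wavelength_nm Monitored wavelength, recorded as metadata.
#' @return A `heme_timecourse` tibble with generator truth in its
#'   `provenance` attribute.
#' @export
generate_timecourse <- function(phases, offset = 0,
                                direction = c("rise", "decay"),
                                noise = noise_model(),
                                time_s = default_time_grid(20),
                                wavelength_nm = 427) {
  direction <- match.arg(direction)
  if (is.null(phases) || nrow(phases) == 0L) stopf("`phases` must have at least one row.")
  if (any(phases$k_obs <= 0)) stopf("all `k_obs` must be > 0.")
  check_increasing(time_s, "time_s")
  a <- rep(offset, length(time_s))
  for (i in seq_len(nrow(phases))) {
    e <- exp(-phases$k_obs[i] * time_s)
    a <- a + phases$amplitude[i] * (if (direction == "rise") 1 - e else e)
  }
  a <- with_seed(noise$seed, a + rnorm(length(a), sd = noise$sigma_AU))
  new_timecourse(time_s, a, wavelength_nm = wavelength_nm,
                 provenance = list(generator = "timecourse",
                                   k_obs = phases$k_obs,
                                   amplitude = phases$amplitude,
                                   offset = offset, direction = direction,
                                   sigma_AU = noise$sigma_AU,
                                   seed = noise$seed))
}

#' Generate a k_obs titration table
#'
#' Observed rates over a substrate series under a hyperbolic saturation law
#' \eqn{k_{obs} = V_{max} [S] / (K_M + [S])} or the linear binding law
#' \eqn{k_{obs} = k_{on} [S] + k_{off}}, with multiplicative noise
#' \eqn{k_{obs} (1 + \varepsilon)}, \eqn{\varepsilon \sim N(0,
#' \mathrm{noise\_frac}^2)}.
#'
#' @param law `"hyperbolic"` or `"linear"`.
#' @param params For hyperbolic: `list(vmax = , km = )` (s\eqn{^{-1}},
#'   \eqn{\mu}M). For linear: `list(k_on = , k_off = )` (M\eqn{^{-1}}
#'   s\eqn{^{-1}}, s\eqn{^{-1}}).
#' @param substrate_uM Substrate series (\eqn{\mu}M), >= 3 positive values
#'   for downstream fitting ( `[S] = 0` is allowed for the linear law).
#' @param noise_frac Relative noise per point, >= 0.
#' @param seed Integer seed or `NULL`.
#' @return Tibble (`substrate_uM`, `k_obs`) with the true parameters in the
#'   `provenance` attribute; class `titration`.
#' @export
generate_titration <- function(law = c("hyperbolic", "linear"), params,
                               substrate_uM, noise_frac = 0, seed = NULL) {
  law <- match.arg(law)
  if (noise_frac < 0) stopf("`noise_frac` must be >= 0.")
  if (length(substrate_uM) < 3L) stopf("need at least 3 substrate points.")
  if (any(substrate_uM < 0)) stopf("substrate concentrations must be >= 0.")
  k <- switch(law,
    hyperbolic = {
      check_number(params$vmax, "vmax", lower = 0, strict = TRUE)
      check_number(params$km, "km", lower = 0, strict = TRUE)
      params$vmax * substrate_uM / (params$km + substrate_uM)
    },
    linear = {
      check_number(params$k_on, "k_on", lower = 0, strict = TRUE)
      check_number(params$k_off, "k_off", lower = 0)
      params$k_on * substrate_uM * 1e-6 + params$k_off
    })
  k <- with_seed(seed, k * (1 + rnorm(length(k), sd = noise_frac)))
  out <- tibble(substrate_uM = as.numeric(substrate_uM), k_obs = k)
  attr(out, "provenance") <- c(list(generator = "titration", law = law,
                                    noise_frac = noise_frac, seed = seed), params)
  class(out) <- c("titration", class(out))
  out
}

#' Generate a synthetic BLI dose-response series
#'
#' Bio-layer interferometry association/dissociation traces over an analyte
#' series. Per concentration: equilibrium response \eqn{R_{eq} = R_{max}
#' \[A\]/(K_D + \[A\])}, perturbed by multiplicative noise; association
#' \eqn{R(t) = R_{eq}(1 - e^{-k_{obs} t})} with \eqn{k_{obs} = k_{off}
#' (\[A\]/K_D + 1)} (so that \eqn{k_{on} = k_{off}/K_D}); dissociation
#' \eqn{R(t) = R_0 e^{-k_{off} t}}. Additive Gaussian noise on every trace
#' point.
#'
#' @param kd_uM True dissociation constant (\eqn{\mu}M), > 0.
#' @param rmax Maximal response (response units), > 0.
#' @param analyte_uM Unique positive analyte concentrations (\eqn{\mu}M).
#' @param k_off Dissociation rate constant (s\eqn{^{-1}}), > 0.
#' @param t_assoc,t_dissoc Phase durations (s).
#' @param n_t Points per phase.
#' @param sigma Additive trace noise sd (response units).
#' @param req_noise_frac Multiplicative noise on the equilibrium response
#'   (default 0.02, i.e. 2 percent).
#' @param seed Integer seed or `NULL`.
#' @return A `bli_series`: list with `req` (tibble `analyte_uM`, `req_true`,
#'   `req`), `traces` (tibble `analyte_uM`, `phase`, `time_s`, `response`)
#'   and `provenance`.
#' @export
generate_bli <- function(kd_uM, rmax = 1, analyte_uM = c(20, 10, 5, 2.5, 1.3, 0.6),
                         k_off = 0.05, t_assoc = 300, t_dissoc = 300, n_t = 120,
                         sigma = 0.005, req_noise_frac = 0.02, seed = NULL) {
  check_number(kd_uM, "kd_uM", lower = 0, strict = TRUE)
  check_number(rmax, "rmax", lower = 0, strict = TRUE)
  check_number(k_off, "k_off", lower = 0, strict = TRUE)
  if (any(analyte_uM <= 0) || anyDuplicated(analyte_uM)) {
    stopf("analyte concentrations must be unique and positive.")
  }
  with_seed(seed, {
    t_grid <- seq(0, t_assoc, length.out = n_t)
    td_grid <- seq(0, t_dissoc, length.out = n_t)
    req_true <- rmax * analyte_uM / (kd_uM + analyte_uM)
    req_noisy <- req_true * (1 + rnorm(length(analyte_uM), sd = req_noise_frac))
    traces <- purrr::map(seq_along(analyte_uM), function(i) {
      k_obs <- k_off * (analyte_uM[i] / kd_uM + 1)
      assoc <- req_noisy[i] * (1 - exp(-k_obs * t_grid)) +
        rnorm(n_t, sd = sigma)
      r0 <- req_noisy[i] * (1 - exp(-k_obs * t_assoc))
      dissoc <- r0 * exp(-k_off * td_grid) + rnorm(n_t, sd = sigma)
      bind_rows(
        tibble(analyte_uM = analyte_uM[i], phase = "association",
               time_s = t_grid, response = assoc),
        tibble(analyte_uM = analyte_uM[i], phase = "dissociation",
               time_s = td_grid, response = dissoc))
    })
    structure(list(
      req = tibble(analyte_uM = analyte_uM, req_true = req_true, req = req_noisy),
      traces = bind_rows(traces),
      provenance = list(generator = "bli", kd_uM = kd_uM, rmax = rmax,
                        k_off = k_off, sigma = sigma,
                        req_noise_frac = req_noise_frac, seed = seed)),
      class = "bli_series")
  })
}

#' @export
print.bli_series <- function(x, ...) {
  cat("<bli_series> ", nrow(x$req), " analyte concentrations (",
      paste(signif(sort(x$req$analyte_uM, decreasing = TRUE), 3), collapse = ", "),
      " uM)\n", sep = "")
  invisible(x)
}
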