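# Single-trace and secondary fits: multi-exponential time courses,
# hyperbolic (saturation) and linear k_obs-vs-[S] analyses, K_D arithmetic,
# and BLI dose-response fits.
#
# Exponential fitting uses variable projection: for a candidate rate vector
# the offset and amplitudes are linear and solved exactly by least squares,
# so the nonlinear search runs over log-rates only. Combined with multistart
# initialisation this makes recovery robust to the usual local minima of
# sums of exponentials.

exp_design <- function(k, time_s, direction) {
  e <- vapply(k, function(ki) exp(-ki * time_s), numeric(length(time_s)))
  if (direction == "rise") e <- 1 - e
  cbind(offset = 1, e)
}

# SSE profiled over the linear parameters, and those parameters
varpro_solve <- function(log_k, time_s, y, direction) {
  k <- exp(log_k)
  X <- exp_design(k, time_s, direction)
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) {
    return(list(sse = Inf, coef = NULL))
  }
  list(sse = sum(fit$residuals^2), coef = unname(fit$coefficients))
}

#' Fit a multi-exponential time course
#'
#' Least-squares fit of
#' \eqn{A(t) = \mathrm{offset} + \sum_i a_i e^{-k_i t}} (decay) or
#' \eqn{A(t) = \mathrm{offset} + \sum_i a_i (1 - e^{-k_i t})} (rise), the
#' standard pre-steady-state analysis of stopped-flow absorbance traces.
#' Rates are searched by multistart variable projection (amplitudes and
#' offset solved linearly at each rate iterate), phases are returned ordered
#' fast to slow, and per-phase amplitude fractions
#' \eqn{100\,|a_i| / \sum_j |a_j|} are reported.
#'
#' @param data Data frame with columns `time_s` and `absorbance` (e.g. a
#'   `heme_timecourse`).
#' @param n_phases Number of exponential phases, 1--3.
#' @param window_s Optional length-2 fitting window (s); data outside are
#'   ignored. Default: all data.
#' @param direction `"rise"` or `"decay"`.
#' @param n_starts Number of multistart optimisations kept from the coarse
#'   rate-grid scan.
#' @return A `multiexp_fit` object; see [tidy.multiexp_fit()] and
#'   [glance.multiexp_fit()].
#' @examples
#' tc <- hemekin_fixture("fig2A_fadh_steap1", seed = 1)
#' fit <- fit_multiexponential(tc, n_phases = 2, direction = "rise")
#' tidy(fit)
#' @export
fit_multiexponential <- function(data, n_phases = 1, window_s = NULL,
                                 direction = c("rise", "decay"),
                                 n_starts = 5) {
  direction <- match.arg(direction)
  if (!n_phases %in% 1:3) stopf("`n_phases` must be 1, 2 or 3.")
  t <- data$time_s
  y <- data$absorbance
  if (is.null(window_s)) window_s <- range(t)
  if (length(window_s) != 2L || window_s[2] <= window_s[1]) {
    stopf("`window_s` must be an increasing length-2 interval.")
  }
  if (window_s[1] > max(t) || window_s[2] < min(t)) {
    stopf("`window_s` [%g, %g] does not overlap the data range [%g, %g].",
          window_s[1], window_s[2], min(t), max(t))
  }
  keep <- t >= window_s[1] & t <= window_s[2]
  t <- t[keep]; y <- y[keep]
  n <- length(t)
  if (n < 5 * (2 * n_phases + 1)) {
    stopf("need at least %d points in the window for %d phase(s); have %d.",
          5 * (2 * n_phases + 1), n_phases, n)
  }
  t_pos <- t[t > 0]
  k_lo <- 1 / (10 * max(t))
  k_hi <- 10 / min(t_pos)
  grid <- exp(seq(log(k_lo), log(k_hi), length.out = 12))
  combos <- utils::combn(log(grid), n_phases, simplify = FALSE)
  sse0 <- vapply(combos, function(lk) varpro_solve(lk, t, y, direction)$sse,
                 numeric(1))
  starts <- combos[order(sse0)][seq_len(min(n_starts, length(combos)))]
  best <- NULL
  for (st in starts) {
    res <- if (n_phases == 1L) {
      o <- optimize(function(lk) varpro_solve(lk, t, y, direction)$sse,
                    interval = log(c(k_lo / 10, k_hi * 10)), tol = 1e-12)
      list(par = o$minimum, value = o$objective, convergence = 0)
    } else {
      optim(st, function(lk) varpro_solve(lk, t, y, direction)$sse,
            method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-14))
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || !is.finite(best$value)) {
    stopf("multi-exponential fit failed to converge; best residual SSE = %g.",
          if (is.null(best)) NA_real_ else best$value)
  }
  k <- exp(best$par)
  sol <- varpro_solve(best$par, t, y, direction)
  offset <- sol$coef[1]
  amps <- sol$coef[-1]
  # fast-first ordering; ties broken by larger |amplitude|
  ord <- order(-k, -abs(amps))
  k <- k[ord]; amps <- amps[ord]
  if (n_phases > 1) {
    rel <- abs(diff(k)) / k[-length(k)]
    if (any(rel < 0.01)) {
      warnf("two fitted rates agree within 1%%; the trace may support only %d phase(s).",
            n_phases - 1L)
    }
  }
  se <- multiexp_se(t, y, direction, offset, amps, k)
  frac <- if (sum(abs(amps)) > 0) 100 * abs(amps) / sum(abs(amps)) else
    rep(100 / n_phases, n_phases)
  structure(list(
    phases = tibble(phase = seq_len(n_phases), k_obs = k, amplitude = amps,
                    fraction_pct = frac,
                    k_obs_se = se$k_se, amplitude_se = se$a_se),
    offset = offset, offset_se = se$offset_se,
    direction = direction, window_s = window_s, n_points = n,
    residual_sse = sol$sse, sigma = sqrt(sol$sse / max(n - (2 * n_phases + 1), 1)),
    aic = n * log(sol$sse / n) + 2 * (2 * n_phases + 1),
    convergence = best$convergence %||% 0,
    data = tibble(time_s = t, absorbance = y)),
    class = "multiexp_fit")
}

# standard errors from the numerical Jacobian of the full residual vector
multiexp_se <- function(t, y, direction, offset, amps, k) {
  theta <- c(offset, amps, log(k))
  p <- length(theta); n <- length(t)
  model <- function(th) {
    X <- exp_design(exp(th[(2 + length(amps)):p]), t, direction)
    X %*% c(th[1], th[2:(1 + length(amps))])
  }
  J <- matrix(0, n, p)
  h <- pmax(abs(theta), 1e-4) * 1e-6
  f0 <- model(theta)
  for (j in seq_len(p)) {
    thj <- theta; thj[j] <- thj[j] + h[j]
    J[, j] <- (model(thj) - f0) / h[j]
  }
  sse <- sum((y - f0)^2)
  s2 <- sse / max(n - p, 1)
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov)) {
    return(list(offset_se = NA_real_, a_se = rep(NA_real_, length(amps)),
                k_se = rep(NA_real_, length(k))))
  }
  se <- sqrt(pmax(diag(cov), 0))
  idx_k <- (2 + length(amps)):p
  list(offset_se = se[1], a_se = se[2:(1 + length(amps))],
       k_se = se[idx_k] * k)  # delta method: d k / d log k = k
}

#' Choose the number of exponential phases by AIC
#'
#' Fits 1..`max_phases` exponentials and returns the smallest phase count
#' whose AIC lies within 2 units of the minimum (parsimony margin).
#'
#' @inheritParams fit_multiexponential
#' @param max_phases Maximum phases to try (<= 3).
#' @return Integer, the recommended phase count; the per-model AICs are in
#'   the `aic` attribute.
#' @export
select_phase_count <- function(data, max_phases = 3, window_s = NULL,
                               direction = c("rise", "decay")) {
  direction <- match.arg(direction)
  if (max_phases > 3) stopf("`max_phases` must be <= 3.")
  aics <- rep(NA_real_, max_phases)
  for (m in seq_len(max_phases)) {
    fit <- tryCatch(
      suppressWarnings(fit_multiexponential(data, n_phases = m,
                                            window_s = window_s,
                                            direction = direction)),
      error = function(e) NULL)
    if (!is.null(fit)) aics[m] <- fit$aic
  }
  if (all(is.na(aics))) stopf("no phase count could be fitted.")
  n_rec <- which(aics <= min(aics, na.rm = TRUE) + 2)[1]
  structure(as.integer(n_rec), aic = aics)
}

#' Fit a hyperbolic (saturation) dependence of k_obs on substrate
#'
#' Least-squares fit of \eqn{k_{obs} = V_{max} [S] / (K_M + [S])}, the
#' Michaelis--Menten-type law describing saturation of the observed heme
#' reduction rate with the flavin donor concentration.
#'
#' @param data Data frame with columns `substrate_uM` and `k_obs`
#'   (a `titration` table).
#' @return A `hyperbolic_fit` with fields `vmax` (s\eqn{^{-1}}), `km`
#'   (\eqn{\mu}M), standard errors and `residual_sse`.
#' @examples
#' tt <- generate_titration("hyperbolic", list(vmax = 12, km = 4.7),
#'                          c(1, 2, 5, 10, 20))
#' fit_hyperbolic(tt)
#' @export
fit_hyperbolic <- function(data) {
  s <- data$substrate_uM; k <- data$k_obs
  if (length(s) < 3 || anyDuplicated(s[s > 0]) && length(unique(s)) < 3) {
    stopf("need >= 3 distinct substrate points.")
  }
  vmax0 <- 1.2 * max(k)
  half <- vmax0 / 2
  km0 <- tryCatch(approx(k, s, xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(s)
  fit <- minpack.lm::nlsLM(
    k_obs ~ vmax * substrate_uM / (km + substrate_uM),
    data = data.frame(substrate_uM = s, k_obs = k),
    start = list(vmax = vmax0, km = km0),
    lower = c(1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  if (cf[["km"]] > 5 * max(s) || (is.finite(se[["km"]]) && se[["km"]] > cf[["km"]])) {
    warnf("little curvature in the titration: KM (%.3g uM) is poorly constrained.",
          cf[["km"]])
  }
  structure(list(vmax = cf[["vmax"]], km = cf[["km"]],
                 vmax_se = se[["vmax"]], km_se = se[["km"]],
                 residual_sse = sum(stats::resid(fit)^2), n = length(s),
                 data = tibble(substrate_uM = s, k_obs = k)),
            class = "hyperbolic_fit")
}

#' Linear fit of k_obs versus substrate: k_on, k_off and K_D
#'
#' Ordinary least squares of \eqn{k_{obs} = k_{on} [S] + k_{off}}: the slope
#' (converted to M\eqn{^{-1}} s\eqn{^{-1}}) is the association rate constant,
#' the ordinate intercept the dissociation rate constant, and
#' \eqn{K_D = k_{off} / k_{on}} is reported in \eqn{\mu}M.
#'
#' @param data Data frame with columns `substrate_uM` and `k_obs`.
#' @return A `linear_kobs_fit` with `k_on`, `k_off`, `kd_uM`, standard
#'   errors (K_D by the delta method) and `residual_sse`.
#' @examples
#' tt <- generate_titration("linear", list(k_on = 1.5e5, k_off = 7.5),
#'                          c(25, 75, 125, 175))
#' fit_linear_kobs(tt)$kd_uM  # 50
#' @export
fit_linear_kobs <- function(data) {
  s <- data$substrate_uM; k <- data$k_obs
  if (length(s) < 2) stopf("need at least 2 points.")
  if (length(s) == 2) warnf("only 2 points: the line has zero residual and no error estimate.")
  fit <- lm(k ~ s)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (slope <= 0) {
    stopf("fitted slope is not positive (%.3g); k_obs does not increase with [S], the binding model is invalid.",
          slope)
  }
  sm <- suppressWarnings(summary(fit))$coefficients  # noiseless fits trip lm's perfect-fit warning
  slope_se <- if (nrow(sm) == 2 && length(s) > 2) sm[2, 2] else NA_real_
  int_se <- if (length(s) > 2) sm[1, 2] else NA_real_
  kd <- intercept / slope  # uM directly, since slope is per uM
  kd_se <- if (is.finite(slope_se) && is.finite(int_se)) {
    abs(kd) * sqrt((int_se / intercept)^2 + (slope_se / slope)^2)
  } else NA_real_
  structure(list(k_on = slope * 1e6, k_off = intercept, kd_uM = kd,
                 k_on_se = slope_se * 1e6, k_off_se = int_se, kd_uM_se = kd_se,
                 residual_sse = sum(stats::resid(fit)^2), n = length(s),
                 data = tibble(substrate_uM = s, k_obs = k)),
            class = "linear_kobs_fit")
}

#' Dissociation constant from rate constants
#'
#' \eqn{K_D = k_{off} / k_{on}}, reported in \eqn{\mu}M. Vectorized.
#'
#' @param k_on Association rate constant(s) (M\eqn{^{-1}} s\eqn{^{-1}}), > 0.
#' @param k_off Dissociation rate constant(s) (s\eqn{^{-1}}), >= 0.
#' @return K_D in \eqn{\mu}M.
#' @examples
#' compute_kd(1.5e5, 7.5)  # 50 uM
#' @export
compute_kd <- function(k_on, k_off) {
  if (any(k_on <= 0)) stopf("`k_on` must be > 0.")
  if (any(k_off < 0)) stopf("`k_off` must be >= 0.")
  (k_off / k_on) * 1e6
}

# monophasic association fit with zero baseline: R(t) = Req (1 - e^{-kt});
# Req is linear given k, so profile it out
fit_association <- function(time_s, response) {
  sse_k <- function(log_k) {
    x <- 1 - exp(-exp(log_k) * time_s)
    req <- sum(x * response) / sum(x * x)
    sum((response - req * x)^2)
  }
  t_pos <- time_s[time_s > 0]
  o <- optimize(sse_k, interval = log(c(0.01 / max(time_s), 100 / min(t_pos))),
                tol = 1e-12)
  k <- exp(o$minimum)
  x <- 1 - exp(-k * time_s)
  req <- sum(x * response) / sum(x * x)
  list(k_obs = k, req = req, sse = o$objective)
}

#' Fit a BLI dose-response series
#'
#' Each association trace is fitted with a monophasic exponential to obtain
#' the equilibrium response \eqn{R_{eq}}; the \eqn{R_{eq}} values are then
#' fitted against analyte concentration with the dose-response law
#' \eqn{R_{eq} = R_{max} [A] / (K_D + [A])}.
#'
#' @param series A `bli_series` from [generate_bli()], or a data frame of
#'   association traces with columns `analyte_uM`, `time_s`, `response`
#'   (and optionally `phase`, in which case only `"association"` rows are
#'   used).
#' @return A `dose_response_fit` with `kd_uM`, `rmax`, standard errors, the
#'   per-concentration `req` table, and `residual_sse` of the dose-response
#'   stage. A warning is issued if \eqn{R_{eq}} is non-monotone in analyte
#'   concentration beyond the noise level, a signature of non-specific
#'   binding.
#' @export
fit_bli <- function(series) {
  traces <- if (inherits(series, "bli_series")) series$traces else as_tibble(series)
  if ("phase" %in% names(traces)) traces <- traces[traces$phase == "association", ]
  conc <- sort(unique(traces$analyte_uM))
  if (length(conc) < 4) stopf("need >= 4 analyte concentrations; have %d.", length(conc))
  req <- purrr::map_dfr(conc, function(a) {
    tr <- traces[traces$analyte_uM == a, ]
    f <- fit_association(tr$time_s, tr$response)
    tibble(analyte_uM = a, req = f$req, k_obs = f$k_obs, trace_sse = f$sse)
  })
  d <- diff(req$req)
  noise_scale <- stats::sd(purrr::map_dbl(conc, function(a) {
    tr <- traces[traces$analyte_uM == a, ]
    stats::sd(diff(tr$response)) / sqrt(2)
  }))
  if (any(d < -max(3 * noise_scale, 1e-12))) {
    warnf("equilibrium responses are non-monotone in analyte concentration; possible non-specific binding.")
  }
  rmax0 <- 1.2 * max(req$req)
  kd0 <- conc[which.min(abs(req$req - rmax0 / 2))]
  fit <- minpack.lm::nlsLM(
    req ~ rmax * analyte_uM / (kd + analyte_uM), data = req,
    start = list(rmax = rmax0, kd = max(kd0, 1e-6)),
    lower = c(1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(rmax = NA_real_, kd = NA_real_))
  structure(list(kd_uM = cf[["kd"]], rmax = cf[["rmax"]],
                 kd_uM_se = se[["kd"]], rmax_se = se[["rmax"]],
                 req = req, residual_sse = sum(stats::resid(fit)^2)),
            class = "dose_response_fit")
}

#' Fit the oxidation time-course series of a Fe3+-NTA titration
#'
#' Convenience pipeline for the substrate-dependence analysis: fits each
#' A427 decay trace with a biphasic exponential inside the analysis window,
#' collects fast- and slow-phase `k_obs` per substrate concentration, and
#' runs [fit_linear_kobs()] on each phase.
#'
#' @param series An `oxidation_series` fixture (see [hemekin_fixture()]), or
#'   a list with elements `timecourses`, `substrate_uM`, `window_s`.
#' @return List with `k_obs` (tibble: substrate_uM, phase, k_obs),
#'   `fast` and `slow` (`linear_kobs_fit` objects).
#' @export
fit_oxidation_series <- function(series) {
  win <- series$window_s
  rows <- purrr::map_dfr(seq_along(series$substrate_uM), function(i) {
    fit <- fit_multiexponential(series$timecourses[[i]], n_phases = 2,
                                window_s = win, direction = "decay")
    tibble(substrate_uM = series$substrate_uM[i],
           phase = c("fast", "slow"), k_obs = fit$phases$k_obs)
  })
  fast <- fit_linear_kobs(rows[rows$phase == "fast", ])
  slow <- fit_linear_kobs(rows[rows$phase == "slow", ])
  list(k_obs = rows, fast = fast, slow = slow)
}
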