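#' Sequential first-order kinetic chain
#'
#' An irreversible chain \eqn{A \to B \to \dots} with one rate constant per
#' step. The first species is the initial state; the last is terminal.
#'
#' @param species_names Ordered character vector of species names.
#' @param rates Step rate constants \eqn{k_1 \dots k_{n-1}} (s\eqn{^{-1}}),
#'   all > 0; `length(species_names) == length(rates) + 1`.
#' @return A `sequential_model` object.
#' @examples
#' m <- sequential_model(c("A", "B", "C"), rates = c(177.9, 0.13))
#' simulate_sequential(m, c0 = 1.5, time_s = c(0, 0.01, 1, 20))
#' @export
sequential_model <- function(species_names, rates) {
  if (!is.character(species_names) || anyDuplicated(species_names)) {
    stopf("`species_names` must be unique character names.")
  }
  if (length(species_names) != length(rates) + 1L) {
    stopf("need exactly one rate per step: %d species require %d rates.",
          length(species_names), length(species_names) - 1L)
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) stopf("all rates must be > 0.")
  structure(list(species_names = species_names, rates = as.numeric(rates)),
            class = "sequential_model")
}

#' @export
print.sequential_model <- function(x, ...) {
  cat("<sequential_model> ", paste(x$species_names, collapse = " -> "), "\n",
      "  rates (s^-1): ", paste(signif(x$rates, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Bateman closed form for an irreversible chain with decay constants
# lambda_1..lambda_m and a terminal species (lambda = 0). Returns the
# fraction matrix (length(t) x n). Assumes all lambdas pairwise distinct.
bateman_fractions <- function(rates, time_s) {
  n <- length(rates) + 1L
  lam <- c(rates, 0)
  out <- matrix(0, nrow = length(time_s), ncol = n)
  for (j in seq_len(n)) {
    pref <- prod(rates[seq_len(j - 1L)])
    acc <- 0
    for (i in seq_len(j)) {
      denom <- prod(lam[setdiff(seq_len(j), i)] - lam[i])
      acc <- acc + exp(-lam[i] * time_s) / denom
    }
    out[, j] <- pref * acc
  }
  out
}

rates_near_degenerate <- function(rates, rel_tol = 1e-6) {
  lam <- c(rates, 0)
  for (i in seq_along(lam)) {
    for (j in seq_along(lam)) {
      if (i < j) {
        scale <- max(abs(lam[i]), abs(lam[j]))
        if (scale > 0 && abs(lam[i] - lam[j]) / scale < rel_tol) return(TRUE)
      }
    }
  }
  FALSE
}

ode_sequential_fractions <- function(rates, time_s, rtol = 1e-8, atol = 1e-12) {
  n <- length(rates) + 1L
  y0 <- c(1, rep(0, n - 1L))
  deriv <- function(t, y, p) {
    flux <- p * y[seq_along(p)]
    dy <- c(-flux, 0) + c(0, flux)
    list(dy)
  }
  tt <- time_s
  prepend <- tt[1] > 0
  if (prepend) tt <- c(0, tt)
  sol <- deSolve::lsoda(y0, tt, deriv, rates, rtol = rtol, atol = atol)
  m <- unname(sol[, -1, drop = FALSE])
  if (prepend) m <- m[-1, , drop = FALSE]
  m
}

#' Simulate a sequential first-order chain
#'
#' Integrates \eqn{dA/dt = -k_1 A}, \eqn{dB/dt = k_1 A - k_2 B}, ...
#' The closed-form Bateman solution is used whenever all decay constants are
#' pairwise distinct (relative difference > 1e-6); near-degenerate rate sets
#' fall back to stiff numerical integration (lsoda) to avoid catastrophic
#' cancellation. Total concentration is conserved exactly in the closed form
#' and to integrator tolerance otherwise.
#'
#' @param model A [sequential_model()].
#' @param c0 Initial concentration of the first species (\eqn{\mu}M), > 0.
#' @param time_s Strictly increasing time grid starting at >= 0 (s).
#' @param method `"auto"` (default), `"bateman"` or `"ode"`.
#' @param rtol,atol Integrator tolerances for the ODE path.
#' @return A `concentration_trajectory`: tibble with `time_s` first and one
#'   concentration column (\eqn{\mu}M) per species.
#' @export
simulate_sequential <- function(model, c0, time_s,
                                method = c("auto", "bateman", "ode"),
                                rtol = 1e-8, atol = 1e-12) {
  method <- match.arg(method)
  if (!inherits(model, "sequential_model")) stopf("`model` must be a sequential_model.")
  check_number(c0, "c0", lower = 0, strict = TRUE)
  if (length(time_s) < 1L || time_s[1] < 0) stopf("`time_s` must start at >= 0 s.")
  check_increasing(time_s, "time_s")
  if (method == "auto") {
    method <- if (rates_near_degenerate(model$rates)) "ode" else "bateman"
  }
  frac <- switch(method,
    bateman = bateman_fractions(model$rates, time_s),
    ode = ode_sequential_fractions(model$rates, time_s, rtol, atol))
  out <- tibble(time_s = as.numeric(time_s))
  for (j in seq_along(model$species_names)) {
    out[[model$species_names[j]]] <- c0 * frac[, j]
  }
  class(out) <- c("concentration_trajectory", class(out))
  out
}

#' Two-population pseudo-first-order heme oxidation model
#'
#' Ferrous heme oxidation by a ferric chelate substrate in excess, with two
#' enzyme populations (e.g. two conformations of the substrate site) that
#' each follow \eqn{k_{obs} = k_{on}[S] + k_{off}}. This is the model whose
#' slope/intercept analysis yields the published \eqn{k_{on}}, \eqn{k_{off}}
#' and \eqn{K_D = k_{off}/k_{on}} for Fe\eqn{^{3+}}-NTA reduction.
#'
#' @param fractions Length-2 numeric, population fractions in \[0,1\] summing
#'   to 1 (within 1e-9).
#' @param k_on Length-2, association rate constants (M\eqn{^{-1}}
#'   s\eqn{^{-1}}), > 0.
#' @param k_off Length-2, dissociation rate constants (s\eqn{^{-1}}), >= 0.
#' @return A `two_population_model` object.
#' @export
two_population_model <- function(fractions, k_on, k_off) {
  if (length(fractions) != 2L || length(k_on) != 2L || length(k_off) != 2L) {
    stopf("`fractions`, `k_on`, `k_off` must each have length 2.")
  }
  if (any(fractions < 0) || any(fractions > 1) || abs(sum(fractions) - 1) > 1e-9) {
    stopf("fractions must lie in [0,1] and sum to 1.")
  }
  if (any(k_on <= 0)) stopf("k_on must be > 0.")
  if (any(k_off < 0)) stopf("k_off must be >= 0.")
  structure(list(fractions = as.numeric(fractions), k_on = as.numeric(k_on),
                 k_off = as.numeric(k_off)),
            class = "two_population_model")
}

#' Simulate two-population heme oxidation under pseudo-first-order conditions
#'
#' \eqn{[\mathrm{Fe^{2+}heme}](t) = e_0 \sum_i f_i \exp[-(k_{on,i} [S]
#' \cdot 10^{-6} + k_{off,i}) t]}. A warning is issued when the substrate is
#' not in at least 10-fold excess over the enzyme, where the
#' pseudo-first-order approximation degrades.
#'
#' @param model A [two_population_model()].
#' @param substrate_uM Substrate concentration (\eqn{\mu}M), >= 0.
#' @param e0 Initial ferrous-heme concentration (\eqn{\mu}M), > 0.
#' @param time_s Increasing time grid (s).
#' @return Tibble with `time_s` and `ferrous_uM`; the per-population observed
#'   rates are kept in the `k_obs` attribute.
#' @export
simulate_two_population_oxidation <- function(model, substrate_uM, e0, time_s) {
  if (!inherits(model, "two_population_model")) {
    stopf("`model` must be a two_population_model.")
  }
  check_number(substrate_uM, "substrate_uM", lower = 0)
  check_number(e0, "e0", lower = 0, strict = TRUE)
  check_increasing(time_s, "time_s", strict = TRUE)
  if (substrate_uM < 10 * e0) {
    warnf("substrate (%g uM) is below 10x enzyme (%g uM); pseudo-first-order k_obs = k_on[S] + k_off may be inaccurate.",
          substrate_uM, e0)
  }
  k_obs <- model$k_on * substrate_uM * 1e-6 + model$k_off
  ferrous <- e0 * (model$fractions[1] * exp(-k_obs[1] * time_s) +
                   model$fractions[2] * exp(-k_obs[2] * time_s))
  out <- tibble(time_s = as.numeric(time_s), ferrous_uM = ferrous)
  attr(out, "k_obs") <- k_obs
  out
}

#' Diffusible-FAD electron shuttle chain model
#'
#' Mass-action mechanism for cross-membrane electron transfer in which FAD is
#' reduced by NADPH at the oxidoreductase site of STEAP2, and the reduced
#' flavin (FADH\eqn{^-}) then becomes diffusible: it can bind the
#' transmembrane heme site of STEAP2 or of STEAP1, deliver its two electrons
#' to heme in two sequential one-electron steps, and the ferrous heme in turn
#' reduces a ferric substrate pool. Hydride transfer is rate-limiting under
#' the conditions emulated here, so the overall heme-reduction progress curve
#' tracks NADPH consumption.
#'
#' @param k_hyd Effective NADPH-to-FAD hydride transfer rate (s\eqn{^{-1}}
#'   with respect to oxidized FAD at the initial NADPH level; NADPH depletion
#'   slows it proportionally).
#' @param k_release FADH\eqn{^-} release from a heme site (s\eqn{^{-1}}).
#' @param k_bind_steap1,k_bind_steap2 FADH\eqn{^-} binding to the STEAP1 /
#'   STEAP2 heme site (s\eqn{^{-1}} in free FADH\eqn{^-}; 0 disables a
#'   branch).
#' @param k_et Rate of each one-electron FADH\eqn{^-}-to-heme transfer step
#'   (s\eqn{^{-1}}).
#' @param k_sub Effective heme-to-substrate (Fe\eqn{^{3+}}) electron transfer
#'   rate (s\eqn{^{-1}} at the initial substrate level).
#' @param pools Named numeric vector of initial pools (\eqn{\mu}M):
#'   `NADPH`, `FAD`, `STEAP1_heme`, `STEAP2_heme`, `Fe3` (missing entries
#'   default to 0).
#' @return A `shuttle_chain_model` object.
#' @export
shuttle_chain_model <- function(k_hyd, k_release = 1, k_bind_steap1 = 1,
                                k_bind_steap2 = 1, k_et = 10, k_sub = 0,
                                pools = c(NADPH = 60, FAD = 2.2,
                                          STEAP1_heme = 0.9, STEAP2_heme = 1.1,
                                          Fe3 = 0)) {
  rates <- c(k_hyd = k_hyd, k_release = k_release, k_bind_steap1 = k_bind_steap1,
             k_bind_steap2 = k_bind_steap2, k_et = k_et, k_sub = k_sub)
  if (any(!is.finite(rates)) || any(rates < 0)) stopf("all rates must be >= 0.")
  if (all(rates == 0)) stopf("degenerate model: all rates are zero.")
  full <- c(NADPH = 0, FAD = 0, STEAP1_heme = 0, STEAP2_heme = 0, Fe3 = 0)
  unknown <- setdiff(names(pools), names(full))
  if (length(unknown) > 0) stopf("unknown pool(s): %s", paste(unknown, collapse = ", "))
  full[names(pools)] <- pools
  if (any(full < 0)) stopf("pools must be >= 0.")
  if (full[["STEAP1_heme"]] + full[["STEAP2_heme"]] <= 0) {
    stopf("at least one heme pool must be > 0.")
  }
  structure(list(rates = rates, pools = full), class = "shuttle_chain_model")
}

#' Simulate the diffusible-FAD shuttle chain
#'
#' Integrates the mass-action ODE system of [shuttle_chain_model()] with a
#' stiff-capable integrator. State variables (\eqn{\mu}M): `NADPH`,
#' `FAD_ox`, `FADH_free`, `FADH_STEAP1`, `FADH_STEAP2`, `FADsq_STEAP1`,
#' `FADsq_STEAP2` (bound semiquinone after the first electron has moved),
#' `heme1_ferric`, `heme1_ferrous`, `heme2_ferric`, `heme2_ferrous`, `Fe3`,
#' `Fe2`, and the bookkeeping variable `NADPH_consumed`. At every stored time
#' point the electrons held by the system (2 per FADH\eqn{^-}, 1 per
#' semiquinone, 1 per ferrous heme, 1 per Fe\eqn{^{2+}}) never exceed twice
#' the NADPH consumed.
#'
#' @param model A [shuttle_chain_model()].
#' @param time_s Increasing time grid starting at 0 (s).
#' @param rtol,atol Integrator tolerances.
#' @return A `concentration_trajectory` tibble (`time_s` + one column per
#'   state variable).
#' @export
simulate_shuttle_chain <- function(model, time_s, rtol = 1e-8, atol = 1e-12) {
  if (!inherits(model, "shuttle_chain_model")) {
    stopf("`model` must be a shuttle_chain_model.")
  }
  check_increasing(time_s, "time_s")
  if (time_s[1] != 0) stopf("`time_s` must start at 0.")
  p <- model$rates
  pools <- model$pools
  nadph0 <- pools[["NADPH"]]
  fe0 <- pools[["Fe3"]]
  heme1 <- pools[["STEAP1_heme"]]
  heme2 <- pools[["STEAP2_heme"]]
  y0 <- c(NADPH = nadph0, FAD_ox = pools[["FAD"]], FADH_free = 0,
          FADH_STEAP1 = 0, FADH_STEAP2 = 0, FADsq_STEAP1 = 0, FADsq_STEAP2 = 0,
          heme1_ferric = heme1, heme1_ferrous = 0,
          heme2_ferric = heme2, heme2_ferrous = 0,
          Fe3 = fe0, Fe2 = 0, NADPH_consumed = 0)
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    # hydride transfer, scaled by remaining NADPH fraction
    v_hyd <- if (nadph0 > 0) p[["k_hyd"]] * y[["FAD_ox"]] * y[["NADPH"]] / nadph0 else 0
    v_b1 <- if (heme1 > 0) p[["k_bind_steap1"]] * y[["FADH_free"]] else 0
    v_b2 <- if (heme2 > 0) p[["k_bind_steap2"]] * y[["FADH_free"]] else 0
    v_r1 <- p[["k_release"]] * y[["FADH_STEAP1"]]
    v_r2 <- p[["k_release"]] * y[["FADH_STEAP2"]]
    # two sequential one-electron transfers, gated on ferric heme availability
    g1 <- if (heme1 > 0) y[["heme1_ferric"]] / heme1 else 0
    g2 <- if (heme2 > 0) y[["heme2_ferric"]] / heme2 else 0
    v_e1a <- p[["k_et"]] * y[["FADH_STEAP1"]] * g1
    v_e1b <- p[["k_et"]] * y[["FADsq_STEAP1"]] * g1
    v_e2a <- p[["k_et"]] * y[["FADH_STEAP2"]] * g2
    v_e2b <- p[["k_et"]] * y[["FADsq_STEAP2"]] * g2
    # substrate reduction, scaled by remaining ferric substrate
    gs <- if (fe0 > 0) y[["Fe3"]] / fe0 else 0
    v_s1 <- p[["k_sub"]] * y[["heme1_ferrous"]] * gs
    v_s2 <- p[["k_sub"]] * y[["heme2_ferrous"]] * gs
    list(c(
      NADPH = -v_hyd,
      FAD_ox = -v_hyd + v_e1b + v_e2b,
      FADH_free = v_hyd - v_b1 - v_b2 + v_r1 + v_r2,
      FADH_STEAP1 = v_b1 - v_r1 - v_e1a,
      FADH_STEAP2 = v_b2 - v_r2 - v_e2a,
      FADsq_STEAP1 = v_e1a - v_e1b,
      FADsq_STEAP2 = v_e2a - v_e2b,
      heme1_ferric = -(v_e1a + v_e1b) + v_s1,
      heme1_ferrous = (v_e1a + v_e1b) - v_s1,
      heme2_ferric = -(v_e2a + v_e2b) + v_s2,
      heme2_ferrous = (v_e2a + v_e2b) - v_s2,
      Fe3 = -(v_s1 + v_s2),
      Fe2 = v_s1 + v_s2,
      NADPH_consumed = v_hyd
    ))
  }
  sol <- deSolve::lsoda(y0, time_s, deriv, NULL, rtol = rtol, atol = atol)
  out <- as_tibble(as.data.frame(sol))
  names(out)[1] <- "time_s"
  class(out) <- c("concentration_trajectory", class(out))
  out
}

#' Electron bookkeeping for a shuttle-chain trajectory
#'
#' @param traj Output of [simulate_shuttle_chain()].
#' @return Tibble with `time_s`, `electrons_held`, `electrons_supplied`
#'   (both \eqn{\mu}M electron equivalents).
#' @export
electron_balance <- function(traj) {
  tibble(
    time_s = traj$time_s,
    electrons_held = 2 * (traj$FADH_free + traj$FADH_STEAP1 + traj$FADH_STEAP2) +
      traj$FADsq_STEAP1 + traj$FADsq_STEAP2 +
      traj$heme1_ferrous + traj$heme2_ferrous + traj$Fe2,
    electrons_supplied = 2 * traj$NADPH_consumed
  )
}
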