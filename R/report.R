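#' Published reference values for the STEAP kinetics experiments
#'
#' The rate constants, saturation parameters and dissociation constants that
#' the fixtures encode, collected in one table for use as ground truth in
#' the reproduction report.
#'
#' @return Tibble with `quantity`, `value`, `units`, `fixture`.
#' @export
reference_kinetics <- function() {
  tibble::tribble(
    ~quantity,                         ~value,  ~units,        ~fixture,
    "steap1_fadh_fast_kobs",           7.7,     "s^-1",        "fig2A_fadh_steap1",
    "steap1_fadh_fast_fraction",       60,      "%",           "fig2A_fadh_steap1",
    "steap1_fadh_slow_kobs",           0.67,    "s^-1",        "fig2A_fadh_steap1",
    "steap1_fadh_fast_vmax",           12,      "s^-1",        "fig2B_inset_titration",
    "steap1_fadh_fast_km",             4.7,     "uM",          "fig2B_inset_titration",
    "l230g_fadh_fast_vmax",            2,       "s^-1",        "fig2s1_L230G",
    "l230g_fadh_fast_km",              3.6,     "uM",          "fig2s1_L230G",
    "b5r_steap1_a_to_b_rate",          177.9,   "s^-1",        "fig3A_b5r",
    "b5r_steap1_b_to_c_rate",          0.13,    "s^-1",        "fig3A_b5r",
    "steap2_nadph_rate",               1.2e-3,  "s^-1",        "fig4s1_steap2_nadph",
    "steap_mixture_rate",              5.5e-4,  "s^-1",        "fig2C_mixture",
    "steap1_nta_fast_kd",              50,      "uM",          "fig5_steap1_nta",
    "steap1_nta_slow_kd",              26.3,    "uM",          "fig5_steap1_nta",
    "steap2_nta_fast_kd",              200,     "uM",          "fig5_steap2_nta",
    "steap2_nta_slow_kd",              85.7,    "uM",          "fig5_steap2_nta",
    "b5r_steap1_bli_kd",               5.9,     "uM",          "bli_b5r"
  )
}

report_row <- function(quantity, reference, computed, tolerance_rel, fixture, seeds) {
  rel <- abs(computed - reference) / abs(reference)
  tibble(quantity = quantity, reference = reference, computed = computed,
         rel_dev = rel, tolerance_rel = tolerance_rel,
         pass = rel <= tolerance_rel, fixture = fixture,
         seeds = paste(seeds, collapse = ","))
}

#' End-to-end reproduction report
#'
#' Regenerates each fixture experiment from scratch at the given seed(s),
#' runs the corresponding analysis (multi-exponential fit, hyperbolic fit,
#' linear k_obs fit, global deconvolution, BLI fit), and compares the
#' recovered quantities with the published reference values in
#' [reference_kinetics()]. Stochastic rows average over `n_seeds` seeds
#' derived from `seed`.
#'
#' @param seed Base integer seed.
#' @param n_seeds Seeds per stochastic row (default 20; the deconvolution
#'   rows use half that to bound runtime).
#' @return Tibble with one row per checked quantity: reference and computed
#'   values, relative deviation, tolerance, pass/fail, fixture and seeds.
#' @export
reproduction_report <- function(seed = 1, n_seeds = 20) {
  seeds <- seed + seq_len(n_seeds) - 1L
  dec_seeds <- seeds[seq_len(max(1L, n_seeds %/% 2L))]
  rows <- list()

  # K_D arithmetic from the published k_on/k_off pairs
  kd <- compute_kd(c(1.5e5, 7.6e3, 1.1e4, 3.5e3), c(7.5, 0.2, 2.2, 0.3))
  ref_kd <- c("steap1_nta_fast_kd", "steap1_nta_slow_kd",
              "steap2_nta_fast_kd", "steap2_nta_slow_kd")
  ref_tab <- reference_kinetics()
  for (i in seq_along(kd)) {
    r <- ref_tab[ref_tab$quantity == ref_kd[i], ]
    rows[[length(rows) + 1]] <- report_row(ref_kd[i], r$value, signif(kd[i], 3),
                                           5e-3, r$fixture, integer(0))
  }

  # biphasic recovery, seed-averaged
  fits <- purrr::map(seeds, function(s) {
    f <- fit_multiexponential(hemekin_fixture("fig2A_fadh_steap1", seed = s),
                              n_phases = 2, direction = "rise")
    c(f$phases$k_obs[1], f$phases$fraction_pct[1])
  })
  mk <- mean(purrr::map_dbl(fits, 1)); mf <- mean(purrr::map_dbl(fits, 2))
  rows[[length(rows) + 1]] <- report_row("steap1_fadh_fast_kobs", 7.7, mk, 0.05,
                                         "fig2A_fadh_steap1", seeds)
  rows[[length(rows) + 1]] <- tibble(
    quantity = "steap1_fadh_fast_fraction", reference = 60, computed = mf,
    rel_dev = abs(mf - 60) / 60, tolerance_rel = NA_real_,
    pass = abs(mf - 60) <= 5, fixture = "fig2A_fadh_steap1",
    seeds = paste(seeds, collapse = ","))

  # hyperbolic self-consistency (noiseless) and the WT / L230G Vmax ratio
  wt <- fit_hyperbolic(hemekin_fixture("fig2B_inset_titration", sigma_AU = 0))
  mut <- fit_hyperbolic(hemekin_fixture("fig2s1_L230G", sigma_AU = 0))
  rows[[length(rows) + 1]] <- report_row("steap1_fadh_fast_vmax", 12, wt$vmax,
                                         1e-6, "fig2B_inset_titration", integer(0))
  rows[[length(rows) + 1]] <- tibble(
    quantity = "wt_over_l230g_vmax_ratio", reference = 5,
    computed = wt$vmax / mut$vmax, rel_dev = NA_real_, tolerance_rel = NA_real_,
    pass = wt$vmax / mut$vmax >= 5, fixture = "fig2s1_L230G",
    seeds = "")

  # global deconvolution recovery
  slow3 <- mean(purrr::map_dbl(dec_seeds, function(s) {
    d <- deconvolve_sequential(hemekin_fixture("fig3A_b5r", seed = s), 3)
    min(d$rates)
  }))
  rows[[length(rows) + 1]] <- report_row("b5r_steap1_b_to_c_rate", 0.13, slow3,
                                         0.10, "fig3A_b5r", dec_seeds)
  two <- mean(purrr::map_dbl(dec_seeds, function(s) {
    deconvolve_sequential(hemekin_fixture("fig4s1_steap2_nadph", seed = s), 2)$rates
  }))
  rows[[length(rows) + 1]] <- report_row("steap2_nadph_rate", 1.2e-3, two,
                                         0.10, "fig4s1_steap2_nadph", dec_seeds)

  # BLI recovery, seed-averaged
  kd_bli <- mean(purrr::map_dbl(seeds, function(s) {
    fit_bli(hemekin_fixture("bli_b5r", seed = s))$kd_uM
  }))
  rows[[length(rows) + 1]] <- report_row("b5r_steap1_bli_kd", 5.9, kd_bli, 0.10,
                                         "bli_b5r", seeds)

  bind_rows(rows)
}
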