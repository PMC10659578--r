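make_scan <- function(absorbance, time_s, grid_nm, dead_time_s = 0) {
  structure(list(time_s = time_s, grid_nm = grid_nm, absorbance = absorbance,
                 conditions = experiment_conditions(1, dead_time_s = dead_time_s),
                 provenance = list(generator = "test")),
            class = "rapid_scan")
}

test_that("rank estimation separates structured components from noise", {
  # static single species: every row identical
  lib <- canonical_spectra()
  row <- compose_absorbance(lib, c(heme_ferric = 1.5))$absorbance
  a_static <- matrix(rep(row, each = 10), nrow = 10)
  expect_warning(r <- estimate_rank(make_scan(a_static, 1:10, lib$wavelength_nm)),
                 "static")
  expect_equal(r$estimated_rank, 1L)

  # noiseless three-species fixture
  ds <- hemekin_fixture("fig3A_b5r", sigma_AU = 0)
  expect_equal(estimate_rank(ds)$estimated_rank, 3L)
  # and with realistic noise
  expect_equal(estimate_rank(hemekin_fixture("fig3A_b5r", seed = 1))$estimated_rank,
               3L)

  # pure noise: 0 or 1 with a warning when nothing is structured
  set.seed(2)
  a_noise <- matrix(rnorm(40 * 60, sd = 0.002), 40, 60)
  r2 <- tryCatch(estimate_rank(make_scan(a_noise, 1:40, seq_len(60))),
                 warning = function(w) {
                   expect_match(conditionMessage(w), "noise")
                   suppressWarnings(estimate_rank(make_scan(a_noise, 1:40,
                                                            seq_len(60))))
                 })
  expect_lte(r2$estimated_rank, 1L)

  expect_error(estimate_rank(make_scan(matrix(1, 2, 5), 1:2, 1:5)), "at least 3")
})

test_that("noiseless deconvolutions recover generator rates and spectra", {
  # two-species slow reduction
  ds2 <- hemekin_fixture("fig4s1_steap2_nadph", sigma_AU = 0)
  d2 <- deconvolve_sequential(ds2, 2)
  expect_equal(d2$rates, 1.2e-3, tolerance = 1e-4)

  # three-species chain: slow rate to 1e-3 relative, tiny residual
  ds3 <- hemekin_fixture("fig3A_b5r", sigma_AU = 0)
  d3 <- deconvolve_sequential(ds3, 3)
  expect_equal(min(d3$rates), 0.13, tolerance = 1e-3)
  expect_equal(max(d3$rates), 177.9, tolerance = 1e-3)
  rec <- reconstruct(ds3, d3)
  expect_lt(max(abs(rec$residual)), 1e-8)

  # concentration fractions sum to 1 at every time point
  frac_sum <- rowSums(as.matrix(d3$concentration_profiles[, -1]))
  expect_lt(max(abs(frac_sum - 1)), 1e-6)
  # species ordered by time of maximal population
  expect_true(all(diff(d3$species_t_max) >= 0))
})

test_that("deconvolution is deterministic across initialisations", {
  ds <- hemekin_fixture("fig4s1_steap2_nadph", sigma_AU = 0)
  da <- deconvolve_sequential(ds, 2, init_rates = 1e-2)
  db <- deconvolve_sequential(ds, 2, init_rates = 1e-4)
  expect_equal(da$rates, db$rates, tolerance = 1e-6)
  expect_equal(as.matrix(da$species_spectra[, -1]),
               as.matrix(db$species_spectra[, -1]), tolerance = 1e-6)
})

test_that("static data forced into two species raises an ill-conditioning warning", {
  lib <- canonical_spectra()
  row <- compose_absorbance(lib, c(heme_ferric = 1.5))$absorbance
  a_static <- matrix(rep(row, each = 30), nrow = 30) +
    matrix(rnorm(30 * length(row), sd = 1e-9), nrow = 30)
  ds <- make_scan(a_static, exp(seq(log(0.01), log(10), length.out = 30)),
                  lib$wavelength_nm)
  expect_warning(d <- deconvolve_sequential(ds, 2), "identical|fewer")
  s <- as.matrix(d$species_spectra[, -1])
  expect_gt(stats::cor(s[, 1], s[, 2]), 0.999)
})

test_that("reconstruction reproduces the stored residual and the noise floor", {
  ds <- hemekin_fixture("fig4s1_steap2_nadph", seed = 7)  # sigma 0.002
  d <- deconvolve_sequential(ds, 2)
  rec <- reconstruct(ds, d)
  expect_equal(rec$residual_norm, d$residual_norm, tolerance = 1e-12)
  expect_lt(abs(stats::sd(rec$residual) - 0.002) / 0.002, 0.20)

  # zero spectra: reconstruction is 0 and the residual is the data itself
  d0 <- d
  d0$species_spectra[, -1] <- 0
  rec0 <- reconstruct(ds, d0)
  expect_true(all(rec0$fitted == 0))
  expect_equal(rec0$residual, ds$absorbance)

  ds_small <- make_scan(ds$absorbance[1:10, ], ds$time_s[1:10], ds$grid_nm)
  expect_error(reconstruct(ds_small, d), "dimensions")
})

test_that("the fitted two-species rate matches a monoexponential fit of the leading SVD time profile", {
  ds <- hemekin_fixture("fig4s1_steap2_nadph", sigma_AU = 0)
  d <- deconvolve_sequential(ds, 2)
  sv <- svd(ds$absorbance)
  profile <- sv$u[, 1] * sv$d[1]
  f <- fit_multiexponential(tibble::tibble(time_s = ds$time_s,
                                           absorbance = profile),
                            n_phases = 1, direction = "decay")
  expect_lt(abs(f$phases$k_obs - d$rates) / d$rates, 0.01)
})
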