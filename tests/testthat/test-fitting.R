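test_that("noiseless biphasic traces are recovered to generator truth", {
  tc <- hemekin_fixture("fig2A_fadh_steap1", sigma_AU = 0)
  fit <- fit_multiexponential(tc, n_phases = 2, direction = "rise")
  truth <- attr(tc, "provenance")
  expect_equal(fit$phases$k_obs, truth$k_obs, tolerance = 1e-6)
  expect_equal(fit$phases$fraction_pct, c(60, 40), tolerance = 1e-6)
  expect_equal(fit$offset, truth$offset, tolerance = 1e-6)
  expect_equal(sum(fit$phases$fraction_pct), 100, tolerance = 1e-9)
})

test_that("a constant trace fits as zero amplitude with the mean as offset", {
  tt <- seq(0.01, 10, length.out = 60)
  tc <- tibble::tibble(time_s = tt, absorbance = rep(0.42, 60))
  fit <- fit_multiexponential(tc, n_phases = 1, direction = "decay")
  expect_lt(abs(fit$phases$amplitude), 1e-8)
  expect_equal(fit$offset, 0.42, tolerance = 1e-6)
})

test_that("exponential fitting is invariant to phase order and time rescaling", {
  tt <- exp(seq(log(1e-3), log(20), length.out = 300))
  ph_fast_first <- tibble::tibble(k_obs = c(8, 0.5), amplitude = c(0.05, 0.03))
  ph_slow_first <- ph_fast_first[2:1, ]
  tc1 <- generate_timecourse(ph_fast_first, 0.05, "rise", noise_model(0), tt)
  tc2 <- generate_timecourse(ph_slow_first, 0.05, "rise", noise_model(0), tt)
  f1 <- fit_multiexponential(tc1, 2, direction = "rise")
  f2 <- fit_multiexponential(tc2, 2, direction = "rise")
  expect_equal(f1$phases$k_obs, f2$phases$k_obs, tolerance = 1e-8)

  # time in ms: rates scale by 1/1000, fractions unchanged
  tc_ms <- tibble::tibble(time_s = tt * 1000, absorbance = tc1$absorbance)
  f_ms <- fit_multiexponential(tc_ms, 2, direction = "rise")
  expect_equal(f_ms$phases$k_obs * 1000, f1$phases$k_obs, tolerance = 1e-5)
  expect_equal(f_ms$phases$fraction_pct, f1$phases$fraction_pct,
               tolerance = 1e-5)
})

test_that("AIC phase selection finds the generating phase count", {
  tt <- exp(seq(log(1e-2), log(20), length.out = 200))
  mono <- generate_timecourse(tibble::tibble(k_obs = 1, amplitude = 0.08),
                              0.1, "rise", noise_model(0), tt)
  expect_equal(as.integer(select_phase_count(mono, 3, direction = "rise")), 1L)

  bi <- hemekin_fixture("fig2A_fadh_steap1", seed = 3)
  expect_equal(as.integer(select_phase_count(bi, 3, direction = "rise")), 2L)

  flat <- generate_timecourse(tibble::tibble(k_obs = 1, amplitude = 0),
                              0.3, "rise", noise_model(0.002, seed = 42), tt)
  n_flat <- select_phase_count(flat, 2, direction = "rise")
  expect_equal(as.integer(n_flat), 1L)
})

test_that("hyperbolic fits are exact on noiseless data and match a grid-search oracle when noisy", {
  tt <- generate_titration("hyperbolic", list(vmax = 12, km = 4.7),
                           c(1, 2, 5, 10, 20))
  fit <- fit_hyperbolic(tt)
  expect_equal(fit$vmax, 12, tolerance = 1e-8)
  expect_equal(fit$km, 4.7, tolerance = 1e-8)
  # defining property: k_obs at [S] = KM is Vmax / 2
  expect_equal(fit$vmax * fit$km / (fit$km + fit$km), fit$vmax / 2)

  noisy <- generate_titration("hyperbolic", list(vmax = 12, km = 4.7),
                              c(1, 2, 5, 10, 20), noise_frac = 0.05, seed = 8)
  nf <- fit_hyperbolic(noisy)
  grid_v <- seq(8, 16, by = 0.02)
  grid_k <- seq(2, 8, by = 0.02)
  sse <- outer(grid_v, grid_k, Vectorize(function(v, km) {
    sum((noisy$k_obs - v * noisy$substrate_uM / (km + noisy$substrate_uM))^2)
  }))
  best <- which(sse == min(sse), arr.ind = TRUE)
  expect_lt(abs(nf$vmax - grid_v[best[1]]), 0.03)
  expect_lt(abs(nf$km - grid_k[best[2]]), 0.03)
  expect_lte(nf$residual_sse, min(sse) + 1e-10)
})

test_that("linear k_obs fits reproduce the published K_D values and the OLS closed form", {
  t1 <- generate_titration("linear", list(k_on = 1.5e5, k_off = 7.5),
                           c(25, 75, 125, 175))
  f1 <- fit_linear_kobs(t1)
  expect_equal(f1$k_on, 1.5e5, tolerance = 1e-9)
  expect_equal(f1$k_off, 7.5, tolerance = 1e-9)
  expect_equal(f1$kd_uM, 50, tolerance = 1e-9)

  t2 <- generate_titration("linear", list(k_on = 3.5e3, k_off = 0.3),
                           c(75, 125, 175))
  expect_equal(signif(fit_linear_kobs(t2)$kd_uM, 3), 85.7)

  # closed-form OLS via the normal equations
  noisy <- generate_titration("linear", list(k_on = 1.1e4, k_off = 2.2),
                              c(75, 125, 175), noise_frac = 0.05, seed = 4)
  f <- fit_linear_kobs(noisy)
  X <- cbind(1, noisy$substrate_uM)
  beta <- solve(t(X) %*% X, t(X) %*% noisy$k_obs)
  expect_equal(f$k_off, beta[1], tolerance = 1e-12)
  expect_equal(f$k_on, beta[2] * 1e6, tolerance = 1e-12)
  # K_D = k_off / k_on (unit-consistent within 1e-9 relative)
  expect_equal(f$kd_uM, f$k_off / f$k_on * 1e6, tolerance = 1e-9)

  # two exact points: perfect line, warning about zero residual
  two <- tibble::tibble(substrate_uM = c(50, 150), k_obs = c(1, 2))
  expect_warning(f2 <- fit_linear_kobs(two), "2 points")
  expect_lt(f2$residual_sse, 1e-20)

  down <- tibble::tibble(substrate_uM = c(10, 50, 100), k_obs = c(3, 2, 1))
  expect_error(fit_linear_kobs(down), "slope")
})

test_that("K_D arithmetic matches the published table values", {
  expect_equal(signif(compute_kd(1.5e5, 7.5), 3), 50)
  expect_equal(signif(compute_kd(7.6e3, 0.2), 3), 26.3)
  expect_equal(signif(compute_kd(1.1e4, 2.2), 3), 200)
  expect_equal(signif(compute_kd(3.5e3, 0.3), 3), 85.7)
  expect_equal(compute_kd(1e5, 0), 0)
  expect_error(compute_kd(0, 1), "k_on")
})

test_that("BLI fits round-trip noiseless series and flag non-monotone Req", {
  b <- generate_bli(5, rmax = 1.4, analyte_uM = c(20, 10, 5, 2.5, 1.3, 0.6),
                    sigma = 0, req_noise_frac = 0)
  fit <- fit_bli(b)
  expect_equal(fit$kd_uM, 5, tolerance = 1e-6)
  expect_equal(fit$rmax, 1.4, tolerance = 1e-6)
  # Req at [A] = K_D equals Rmax / 2
  expect_equal(fit$rmax * fit$kd_uM / (fit$kd_uM + fit$kd_uM), fit$rmax / 2)

  # non-monotone Req beyond noise: association plateaus that dip at high [A]
  tt <- seq(0, 100, length.out = 50)
  bad <- purrr::map_dfr(c(1, 3, 10, 30), function(a) {
    req <- if (a == 30) 0.4 else a / (5 + a)
    tibble::tibble(analyte_uM = a, time_s = tt,
                   response = req * (1 - exp(-0.3 * tt)))
  })
  expect_warning(fit_bli(bad), "non-monotone")
  expect_error(fit_bli(bad[bad$analyte_uM < 30, ]), "4 analyte")
})

test_that("the oxidation-series pipeline recovers k_on, k_off and K_D", {
  ser <- hemekin_fixture("fig5_steap1_nta", sigma_AU = 0)
  res <- fit_oxidation_series(ser)
  expect_equal(res$fast$k_on, 1.5e5, tolerance = 1e-4)
  expect_equal(res$fast$k_off, 7.5, tolerance = 1e-4)
  expect_equal(res$fast$kd_uM, 50, tolerance = 1e-4)
  expect_equal(res$slow$kd_uM, 26.3, tolerance = 1e-2)
})
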