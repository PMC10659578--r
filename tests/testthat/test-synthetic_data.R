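test_that("noiseless rapid scans equal the Beer-Lambert composition exactly", {
  ds <- hemekin_fixture("fig4s1_steap2_nadph", sigma_AU = 0)
  lib <- canonical_spectra()
  spA <- lib$heme_ferric + lib$flavin_ox
  spB <- lib$heme_ferrous + lib$flavin_red
  m <- sequential_model(c("A", "B"), 1.2e-3)
  traj <- simulate_sequential(m, 2.3, ds$time_s + ds$conditions$dead_time_s)
  manual <- (cbind(traj$A, traj$B) %*% rbind(spA, spB)) / 1000
  expect_equal(unname(ds$absorbance), unname(manual), tolerance = 1e-12)
})

test_that("the noiseless three-species dataset has numerical rank 3", {
  ds <- hemekin_fixture("fig3A_b5r", sigma_AU = 0)
  sv <- svd(ds$absorbance)$d
  expect_equal(sum(sv > 1e-10 * sv[1]), 3)
})

test_that("generators are pure functions of parameters and seed", {
  d1 <- hemekin_fixture("fig3A_b5r", seed = 5)
  d2 <- hemekin_fixture("fig3A_b5r", seed = 5)
  d3 <- hemekin_fixture("fig3A_b5r", seed = 6)
  expect_identical(d1$absorbance, d2$absorbance)
  expect_false(identical(d1$absorbance, d3$absorbance))
  expect_equal(d1$provenance$seed, 5)

  b1 <- generate_bli(5.9, seed = 9)
  b2 <- generate_bli(5.9, seed = 9)
  expect_identical(b1$traces$response, b2$traces$response)
})

test_that("time-course generator evaluates the exponential sum exactly", {
  tt <- seq(0.01, 20, length.out = 50)
  ph <- tibble::tibble(k_obs = c(7.7, 0.67), amplitude = c(0.06, 0.04))
  tc <- generate_timecourse(ph, offset = 0.1, direction = "rise",
                            noise = noise_model(0), time_s = tt)
  hand <- 0.1 + 0.06 * (1 - exp(-7.7 * tt)) + 0.04 * (1 - exp(-0.67 * tt))
  expect_equal(tc$absorbance, hand, tolerance = 1e-14)

  # plateau of a single rising phase is offset + amplitude
  tc1 <- generate_timecourse(tibble::tibble(k_obs = 2, amplitude = 0.5),
                             offset = 0.2, direction = "rise",
                             noise = noise_model(0),
                             time_s = c(1, 10, 1000))
  expect_equal(tc1$absorbance[3], 0.7, tolerance = 1e-9)

  # zero amplitudes give a constant trace at the offset
  tc0 <- generate_timecourse(tibble::tibble(k_obs = 2, amplitude = 0),
                             offset = 0.2, noise = noise_model(0),
                             time_s = tt)
  expect_true(all(tc0$absorbance == 0.2))

  expect_error(generate_timecourse(tibble::tibble(k_obs = numeric(),
                                                  amplitude = numeric())),
               "at least one")
})

test_that("titration generator reproduces the stated laws point-wise", {
  # hyperbolic at [S] = KM gives Vmax / 2
  th <- generate_titration("hyperbolic", list(vmax = 12, km = 4.7),
                           c(1, 4.7, 20))
  expect_equal(th$k_obs[2], 6)

  # linear at [S] = 0 gives k_off; STEAP2 fast-phase value at 125 uM
  tl <- generate_titration("linear", list(k_on = 1.1e4, k_off = 2.2),
                           c(0, 75, 125))
  expect_equal(tl$k_obs[1], 2.2)
  expect_equal(tl$k_obs[3], 3.575)

  expect_error(generate_titration("linear", list(k_on = 1, k_off = 0),
                                  c(1, 2, 3), noise_frac = -0.1), "noise_frac")
  pr <- attr(tl, "provenance")
  expect_equal(pr$k_on, 1.1e4)
})

test_that("BLI generator satisfies the dose-response limits and trace layout", {
  b <- generate_bli(5, rmax = 2, analyte_uM = c(40, 20, 10, 5, 2.5, 1.25),
                    sigma = 0, req_noise_frac = 0)
  # Req at [A] = K_D is Rmax / 2; saturation approaches Rmax
  expect_equal(b$req$req[b$req$analyte_uM == 5], 1)
  b_hi <- generate_bli(5, rmax = 2, analyte_uM = c(5000, 10, 5, 1),
                       sigma = 0, req_noise_frac = 0)
  expect_gt(b_hi$req$req[b_hi$req$analyte_uM == 5000], 2 * 0.999)

  # six standard analyte concentrations give six association + six dissociation traces
  b6 <- generate_bli(5.9, seed = 1)
  counts <- table(b6$traces$phase, b6$traces$analyte_uM)
  expect_equal(dim(counts), c(2L, 6L))
  expect_true(all(counts > 0))
  expect_error(generate_bli(-1), "kd_uM")
})

test_that("dead time shifts the recorded axis while provenance keeps the truth", {
  ds <- hemekin_fixture("fig3A_b5r", sigma_AU = 0)
  expect_gt(ds$time_s[1], 0)
  expect_equal(ds$conditions$dead_time_s, 1.5e-3)
  expect_equal(ds$provenance$rates_s1, c(177.9, 0.13))
  # at least 5 recorded points fall inside the first 30 ms
  expect_gte(sum(ds$time_s <= 0.03), 5)
})
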