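test_that("single-step chain obeys the half-life relation and conserves mass", {
  m <- sequential_model(c("A", "B"), 1)
  tr <- simulate_sequential(m, c0 = 1, time_s = c(0, log(2), 5))
  expect_equal(tr$A[2], 0.5, tolerance = 1e-12)
  expect_equal(tr$A + tr$B, rep(1, 3), tolerance = 1e-12)
})

test_that("Bateman closed form agrees with stiff numerical integration for the published rate pair", {
  m <- sequential_model(c("A", "B", "C"), c(177.9, 0.13))
  tt <- c(0.002, 0.01, 0.05, 0.3, 1, 5, 20)
  bt <- simulate_sequential(m, 1, tt, method = "bateman")
  od <- simulate_sequential(m, 1, tt, method = "ode", rtol = 1e-10, atol = 1e-14)
  for (sp in c("A", "B", "C")) {
    expect_lt(max(abs(bt[[sp]] - od[[sp]])), 1e-8)
  }
})

test_that("total concentration is conserved for random chains", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:4, 1)
    k <- exp(stats::runif(n - 1, log(1e-3), log(1e2)))
    m <- sequential_model(paste0("s", 1:n), k)
    tt <- exp(seq(log(1e-3), log(50), length.out = 40))
    tr <- simulate_sequential(m, c0 = 2.5, time_s = tt)
    tot <- rowSums(as.matrix(tr[, -1]))
    expect_lt(max(abs(tot - 2.5)) / 2.5, 1e-9)
    expect_true(all(as.matrix(tr[, -1]) > -1e-9))
  }
})

test_that("sequential simulation is invariant under time-grid refinement", {
  m <- sequential_model(c("A", "B", "C"), c(5, 0.2))
  coarse <- seq(0, 10, by = 0.5)
  fine <- seq(0, 10, by = 0.1)
  tr_c <- simulate_sequential(m, 1, coarse)
  tr_f <- simulate_sequential(m, 1, fine)
  shared <- match(coarse, fine)
  for (sp in c("A", "B", "C")) {
    expect_equal(tr_c[[sp]], tr_f[[sp]][shared], tolerance = 1e-9)
  }
})

test_that("near-degenerate rates take the ODE path and stay accurate", {
  k <- c(1, 1 + 1e-9)
  m <- sequential_model(c("A", "B", "C"), k)
  tr <- simulate_sequential(m, 1, seq(0, 5, 0.5))  # auto -> ode
  # against the exact equal-rates solution B(t) = k t e^{-kt}
  expect_equal(tr$B, 1 * seq(0, 5, 0.5) * exp(-seq(0, 5, 0.5)), tolerance = 1e-6)
  expect_error(simulate_sequential(m, 1, c(0, 1, 1)), "increasing")
})

test_that("two-population oxidation follows k_obs = k_on[S] + k_off", {
  m <- two_population_model(c(0.85, 0.15), c(1.5e5, 7.6e3), c(7.5, 0.2))
  tt <- seq(0, 1, length.out = 50)
  tr <- simulate_two_population_oxidation(m, substrate_uM = 175, e0 = 1.1, tt)
  # fast-population observed rate from the published parameters
  expect_equal(attr(tr, "k_obs")[1], 1.5e5 * 175e-6 + 7.5)  # 33.75
  expect_equal(attr(tr, "k_obs")[1], 33.75)
  expect_true(all(diff(tr$ferrous_uM) < 0))

  # [S] = 0: each population decays at its k_off only
  expect_warning(tr0 <- simulate_two_population_oxidation(m, 0, 1.1, tt),
                 "pseudo-first-order")
  expect_equal(tr0$ferrous_uM,
               1.1 * (0.85 * exp(-7.5 * tt) + 0.15 * exp(-0.2 * tt)),
               tolerance = 1e-12)
})

test_that("a vanishing second population reduces to a single exponential", {
  m <- two_population_model(c(1, 0), c(1e5, 1e4), c(5, 1))
  tt <- seq(0, 2, length.out = 30)
  tr <- simulate_two_population_oxidation(m, 200, 1, tt)
  k <- 1e5 * 200e-6 + 5
  expect_equal(tr$ferrous_uM, exp(-k * tt), tolerance = 1e-12)
})

test_that("shuttle chain is inert without NADPH and rejects degenerate models", {
  m <- shuttle_chain_model(k_hyd = 1, pools = c(NADPH = 0, FAD = 2.2,
                                                STEAP1_heme = 0.9,
                                                STEAP2_heme = 1.1))
  tr <- simulate_shuttle_chain(m, seq(0, 100, length.out = 20))
  expect_lt(max(abs(tr$heme1_ferrous)), 1e-10)
  expect_lt(max(abs(tr$NADPH_consumed)), 1e-10)

  expect_error(shuttle_chain_model(k_hyd = 0, k_release = 0, k_bind_steap1 = 0,
                                   k_bind_steap2 = 0, k_et = 0, k_sub = 0),
               "degenerate")
  expect_error(shuttle_chain_model(k_hyd = 1,
                                   pools = c(STEAP1_heme = 0, STEAP2_heme = 0)),
               "heme pool")
})

test_that("electron bookkeeping holds at every stored time point", {
  m <- shuttle_chain_model(k_hyd = 0.05, k_release = 0.5, k_bind_steap1 = 2,
                           k_bind_steap2 = 1, k_et = 5, k_sub = 0.5,
                           pools = c(NADPH = 60, FAD = 2.2, STEAP1_heme = 0.9,
                                     STEAP2_heme = 1.1, Fe3 = 50))
  tr <- simulate_shuttle_chain(m, seq(0, 200, length.out = 100))
  eb <- electron_balance(tr)
  expect_true(all(eb$electrons_held <= eb$electrons_supplied + 1e-6))
  expect_true(all(as.matrix(tr[, -1]) > -1e-8))
})

test_that("with rate-limiting hydride transfer the heme rise tracks NADPH consumption", {
  # k_hyd far below every downstream rate; hemes can absorb all electrons,
  # so ferrous heme accumulates as 2 x (NADPH consumed)
  m <- shuttle_chain_model(k_hyd = 1e-3, k_release = 1, k_bind_steap1 = 1,
                           k_bind_steap2 = 1, k_et = 10, k_sub = 0,
                           pools = c(NADPH = 1, FAD = 2.2, STEAP1_heme = 0.9,
                                     STEAP2_heme = 1.1))
  tt <- seq(0, 3000, length.out = 200)
  tr <- simulate_shuttle_chain(m, tt)
  ferrous <- tr$heme1_ferrous + tr$heme2_ferrous

  fit_f <- fit_multiexponential(tibble::tibble(time_s = tt, absorbance = ferrous),
                                n_phases = 1, direction = "rise")
  fit_n <- fit_multiexponential(tibble::tibble(time_s = tt, absorbance = tr$NADPH),
                                n_phases = 1, direction = "decay")
  expect_lt(abs(fit_f$phases$k_obs - fit_n$phases$k_obs) / fit_n$phases$k_obs,
            0.10)
})
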