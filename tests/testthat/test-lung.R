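test_that("flow waveform follows the half-sine arc and guards its domain", {
  expect_equal(flow_waveform(0, 0.5), 0)
  expect_equal(flow_waveform(0.5, 0.5), 0.5)
  expect_equal(flow_waveform(0.25, 1), sin(pi / 4), tolerance = 1e-12)
  expect_equal(flow_waveform(0.25, 1), 0.70711, tolerance = 1e-5)
  th <- seq(0, 1, length.out = 101)
  expect_true(all(flow_waveform(th, 0.8) >= 0 & flow_waveform(th, 0.8) <= 0.8))
  expect_error(flow_waveform(1.2, 0.5), "theta")
  expect_error(flow_waveform(-0.1, 0.5), "theta")
  expect_error(flow_waveform(0.5, 0), "Q0")
})

test_that("normalised volume is the phase integral of flow, odd about mid-expiration", {
  expect_equal(normalized_volume(0.5, 1), 0)
  expect_equal(normalized_volume(0, 1), -1 / pi, tolerance = 1e-12)
  expect_equal(normalized_volume(0, 1), -0.31831, tolerance = 1e-5)
  expect_equal(normalized_volume(1, 1), 1 / pi, tolerance = 1e-12)
  th <- seq(0, 0.5, length.out = 20)
  expect_equal(normalized_volume(0.5 - th, 2), -normalized_volume(0.5 + th, 2))
})

test_that("pressure components split into resistive and elastic parts", {
  l <- lung_params(2.7, 4.8)
  pc <- pressure_components(0.5, 1, l)
  expect_equal(pc$P_R, 2.7)
  expect_equal(pc$P_E, 0)
  pc0 <- pressure_components(0, 1, l)
  expect_equal(pc0$P_R, 0)
  expect_equal(pc0$P_E, -4.8 / pi, tolerance = 1e-12)
  expect_equal(pc0$P_E, -1.5279, tolerance = 1e-4)
})

test_that("muscle-pressure amplitude/phase match the resistive+elastic sum", {
  l <- lung_params(2.7, 4.8)
  p <- muscle_pressure_profile(1, l)
  expect_equal(p$A_mus, sqrt(2.7^2 + (4.8 / pi)^2), tolerance = 1e-12)
  expect_equal(p$A_mus, 3.1023, tolerance = 1e-4)
  expect_equal(p$phi, atan(-4.8 / (pi * 2.7)), tolerance = 1e-12)
  expect_equal(p$phi, -0.51496, tolerance = 1e-4)
  # pure resistance limit
  pr <- muscle_pressure_profile(1, list(R = 1, E = 0))
  expect_equal(pr$A_mus, 1)
  expect_equal(pr$phi, 0)
  # linearity in Q0
  p2 <- muscle_pressure_profile(2, l)
  expect_equal(p2$A_mus, 2 * p$A_mus)
  expect_equal(p2$phi, p$phi)
  expect_error(muscle_pressure_profile(1, list(R = 0, E = 4)), "R must be")
  expect_equal(muscle_pressure_profile(1, list(R = 0, E = 4),
                                       allow_zero_resistance = TRUE)$phi,
               -pi / 2)
})

test_that("sinusoid identity holds across the admissible parameter box", {
  set.seed(42)
  th <- seq(0, 1, length.out = 200)
  for (k in 1:25) {
    l <- lung_params(runif(1, 1.5, 5), runif(1, 2, 10))
    Q0 <- runif(1, 0.1, 2)
    p <- muscle_pressure_profile(Q0, l)
    pc <- pressure_components(th, Q0, l)
    expect_lt(max(abs(muscle_pressure(p, th) - (pc$P_R + pc$P_E))),
              1e-9 * p$A_mus)
  }
})

test_that("plant integration matches the first-order closed form", {
  l <- lung_params(2.7, 4.8)
  dt <- 1e-3
  n <- 5000
  out <- simulate_plant(l, rep(4.8, n), rep(0, n), dt)
  t <- (seq_len(n) - 1) * dt
  vref <- (4.8 / 4.8) * (1 - exp(-4.8 * t / 2.7))
  expect_lt(max(abs(out$volume[-1] - vref[-1]) / vref[-1]), 1e-3)
  # steady state -> P0 / E = 1 L
  expect_equal(out$volume[n], 1, tolerance = 1e-3)
  # value at one time constant
  i_tau <- round((2.7 / 4.8) / dt) + 1
  expect_equal(out$volume[i_tau], 1 - exp(-1), tolerance = 1e-3)
})

test_that("plant is linear and quiescent without forcing", {
  l <- lung_params(3, 5)
  n <- 2000; dt <- 5e-3
  t <- (seq_len(n) - 1) * dt
  pm <- 2 * sin(2 * pi * t / 3)
  px <- pmax(0, sin(2 * pi * t / 3 - 0.4))
  a <- simulate_plant(l, pm, px, dt)
  b <- simulate_plant(l, 2 * pm, 2 * px, dt)
  expect_equal(b$volume, 2 * a$volume, tolerance = 1e-12)
  z <- simulate_plant(l, rep(0, 100), rep(0, 100), 1e-3)
  expect_true(all(z$volume == 0) && all(z$flow == 0))
})

test_that("plant guards sampling assumptions", {
  l <- lung_params(2.7, 4.8)  # tau = 0.5625 s
  expect_warning(simulate_plant(l, rep(1, 10), rep(0, 10), dt = 0.1),
                 "time constant")
  expect_error(simulate_plant(l, rep(1, 10), rep(0, 5), dt = 1e-3),
               "equal length")
  expect_error(simulate_plant(l, rep(1, 5), rep(0, 5), dt = 1e-3,
                              t = c(0, 0.001, 0.002, 0.004, 0.005)),
               "non-uniform")
})

test_that("lung and breath constructors enforce their invariants", {
  expect_error(lung_params(-1, 4), "R")
  expect_error(lung_params(2, 0), "E")
  expect_error(lung_params(2, 4, Vlung0 = 1, PPEEP = 2), "reduced tidal")
  expect_silent(lung_params(2, 4, Vlung0 = 0.5, PPEEP = -2))
  expect_error(breath_pattern(Q0 = -1), "Q0")
  expect_error(breath_pattern(rate = 100), "rate")
  expect_error(breath_pattern(insp_fraction = 1), "insp_fraction")
})
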