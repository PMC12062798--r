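test_that("controller configuration enforces the published gain ranges", {
  expect_silent(controller_config(assist_gain = 0, kP = 2.6, kD = 0.5))
  expect_error(controller_config(assist_gain = 1.5), "assist_gain")
  expect_error(controller_config(B = 0.05), "'B'")
  expect_error(controller_config(K = 6), "'K'")
  expect_error(controller_config(kP = 1), "kP")     # boundary excluded
  expect_error(controller_config(kD = 0), "kD")
  expect_error(controller_config(Fmax = 500), "Fmax")
  expect_error(controller_config(Psup_max = 25), "Psup_max")
})

test_that("phase estimator tracks expired-volume fraction with warm-up and clamp", {
  st <- phase_state()
  expect_identical(st$phase_label, "inspiration")
  # expiration onset
  st <- estimate_phase(0.3, st, dt = 0.01, hysteresis = 0.01)
  expect_identical(st$phase_label, "expiration")
  expect_equal(st$theta, 0)
  expect_true(st$warmup)
  # during warm-up theta stays pinned at 0
  st <- estimate_phase(0.4, st, dt = 0.01, hysteresis = 0.01)
  expect_equal(st$theta, 0)
  # completing the first expiration sets the prediction
  st <- estimate_phase(-0.3, st, dt = 0.01, hysteresis = 0.01)
  expect_false(st$warmup)
  expect_equal(st$breaths, 1L)
  vex1 <- st$vex_pred
  expect_gt(vex1, 0)
  # second breath: theta = vex_cum / vex_pred
  st$phase_label <- "expiration"; st$vex_cum <- 0.4; st$vex_pred <- 0.8
  st2 <- estimate_phase(0, st, dt = 0.01, hysteresis = 0.01)
  expect_equal(st2$theta, 0.5)
  # clamp at 1
  st$vex_cum <- 1.0
  st3 <- estimate_phase(0, st, dt = 0.01, hysteresis = 0.01)
  expect_equal(st3$theta, 1)
})

test_that("micro-expirations do not corrupt the expired-volume prediction", {
  st <- phase_state()
  st$phase_label <- "expiration"; st$warmup <- FALSE
  st$vex_pred <- 0.8; st$vex_cum <- 0.01   # boundary flutter, 1.25% of pred
  st <- estimate_phase(-0.5, st, dt = 0.01, hysteresis = 0.01)
  expect_equal(st$vex_pred, 0.8)           # unchanged
  st$phase_label <- "expiration"; st$vex_cum <- 0.75
  st <- estimate_phase(-0.5, st, dt = 0.01, hysteresis = 0.01)
  expect_equal(st$vex_pred, 0.75)          # genuine breath updates it
})

test_that("reference pressure profile scales, floors and respects the airway cap", {
  l <- lung_params(2.7, 4.8)
  prof <- muscle_pressure_profile(1, l)
  cfg0 <- controller_config(assist_gain = 0)
  expect_equal(desired_pressure_profile(c(0, 0.3, 0.7, 1), prof, cfg0),
               rep(0, 4))
  cfg <- controller_config(assist_gain = 0.5)
  expect_equal(desired_pressure_profile(0.5, prof, cfg),
               0.5 * prof$A_mus * sin(pi / 2 + prof$phi), tolerance = 1e-12)
  expect_equal(desired_pressure_profile(0.5, prof, cfg), 1.3500,
               tolerance = 1e-3)
  # no suction: early phase where the sinusoid is negative
  expect_equal(desired_pressure_profile(0, prof, cfg), 0)
  # airway cap: an amplitude whose assisted sum would pass 30
  big <- muscle_pressure_profile(9, l)    # A ~ 27.9 cmH2O
  cfg1 <- controller_config(assist_gain = 1)
  th <- seq(0, 1, length.out = 201)
  pm <- muscle_pressure(big, th)
  pref <- desired_pressure_profile(th, big, cfg1)
  expect_lte(max(pm + pref), 30 + 1e-12)
  expect_gt(max(pm + pref), 29.9)         # the clip binds, it is not vacuous
})

test_that("force planning and mapping follow the planning law with clamps", {
  cfg <- controller_config(B = 1, K = 0.5)
  tm <- transmission_model(8.09, 67.41, 0.25)
  expect_equal(desired_force(10, tm, cfg), 40)
  expect_equal(desired_force(0, tm, cfg), 0)
  expect_equal(desired_force(200, tm, cfg), 400)   # clamped at Fmax
  expect_equal(plan_force(100, 0, 0, cfg), 100)    # passthrough
  expect_equal(plan_force(100, 40, 10, cfg), 100 - 1 * 10 - 0.5 * 40)
  expect_equal(plan_force(10, 100, 50, cfg), 0)    # lower clamp
  # monotone non-increasing in both feedback arguments
  f1 <- vapply(seq(0, 200, by = 20), function(fi) plan_force(150, fi, 5, cfg),
               numeric(1))
  f2 <- vapply(seq(-50, 50, by = 10), function(d) plan_force(150, 20, d, cfg),
               numeric(1))
  expect_true(all(diff(f1) <= 0))
  expect_true(all(diff(f2) <= 0))
})

test_that("supply-pressure reference offers literal and exact inverses", {
  cfg <- controller_config()
  tm <- transmission_model(8.1, 67.41, 0.01)
  expect_equal(supply_pressure_ref(81, tm, cfg), 10)
  tm2 <- transmission_model(8.09, 67.41, 0.01)
  expect_equal(supply_pressure_ref(400, tm2, cfg), 20)  # clamped from 49.4
  expect_equal(supply_pressure_ref(67.41, tm2, cfg, exact_inverse = TRUE), 0)
  expect_equal(supply_pressure_ref(8.09 + 67.41, tm2, cfg,
                                   exact_inverse = TRUE), 1)
})

test_that("valve current law applies the square-root feedforward with saturation", {
  cfg <- controller_config(kP = 2.6, kD = 0.5)
  out <- control_current(5, 5, 0, 0, cfg, k1 = 1, Cv = 1, Pin = 16)
  expect_equal(out$I, 4)
  expect_false(out$saturated)
  expect_equal(control_current(5, 5, 0, 0, cfg, 1, 1, Pin = 0)$I, 0)
  # radicand 16 - 2.6 * 10 < 0 -> floored with a flag, not an error
  sat <- control_current(15, 5, 0, 0, cfg, 1, 1, Pin = 16)
  expect_equal(sat$I, 0)
  expect_true(sat$saturated)
})

test_that("stability check encodes kP > 1, kD > 0 and verifies it numerically", {
  ok <- check_stability(list(kP = 2.6, kD = 0.5))
  expect_true(ok$stable)
  expect_equal(ok$margin, 0.5)
  expect_true(ok$lyapunov_nonincreasing)
  expect_false(check_stability(list(kP = 1.0, kD = 0.5))$stable)
  expect_false(check_stability(list(kP = 5, kD = 0))$stable)
  # an unstable proportional gain shows up in the simulated trajectory too
  expect_false(check_stability(list(kP = 0.5, kD = 0.5),
                               x0 = c(1, 0))$lyapunov_nonincreasing)
})

test_that("Lyapunov function is non-increasing for 50 random admissible gain pairs", {
  set.seed(99)
  for (k in 1:50) {
    cfg <- list(kP = runif(1, 1 + 1e-6, 10), kD = runif(1, 1e-6, 1))
    res <- check_stability(cfg, x0 = rnorm(2, 0, 5))
    expect_true(res$stable)
    expect_true(res$lyapunov_nonincreasing)
  }
})
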