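test_that("force-pressure law evaluates and guards the rated range", {
  tm <- transmission_model(8.09, 67.41, 0.01)
  expect_equal(force_from_pressure(tm, 0), 67.41)
  expect_equal(force_from_pressure(tm, 20), 8.09 * 20 + 67.41)
  expect_equal(force_from_pressure(tm, 20), 229.21, tolerance = 1e-10)
  expect_equal(force_from_pressure(transmission_model(1, 0, 0.01), 7), 7)
  expect_error(force_from_pressure(tm, 21), "rated range")
  expect_error(force_from_pressure(tm, -1), "rated range")
  # strictly increasing in Psup
  ps <- seq(0, 20, length.out = 50)
  expect_true(all(diff(force_from_pressure(tm, ps)) > 0))
})

test_that("lumped delta equals the stage-wise cascade", {
  expect_equal(compose_delta(cascade_constants(1, 1, 1, 1, 1)), 1)
  expect_equal(compose_delta(cascade_constants(A_contact = 2, Cab = 0.5,
                                               kth = 2, V0 = 1, eta = 0.8)),
               0.4, tolerance = 1e-15)
  # brute-force chain through the intermediate abdominal/thoracic stages
  chain <- function(cc, Fa) {
    Pab <- Fa / cc$A_contact          # force to abdominal pressure
    dVab <- cc$Cab * Pab              # abdominal volume change
    dPth <- cc$kth * dVab / cc$V0     # thoracic pressure (magnitude)
    dPth * cc$eta                     # transmitted to the lung
  }
  set.seed(11)
  for (k in 1:100) {
    cc <- cascade_constants(runif(1, 0.1, 2), runif(1, 0.01, 1),
                            runif(1, 0.5, 5), runif(1, 1, 6),
                            runif(1, 0.2, 1))
    expect_equal(chain(cc, 10), compose_delta(cc) * 10,
                 tolerance = 1e-12)
  }
})

test_that("force-to-lung-pressure map scales and guards sign", {
  tm <- transmission_model(8, 80, 0.25)
  expect_equal(pexo_from_force(tm, 200), 50)
  expect_equal(pexo_from_force(tm, 0), 0)
  expect_equal(pexo_from_force(transmission_model(8, 80, 0.1), 400), 40)
  expect_error(pexo_from_force(tm, -5), "non-negative")
})

test_that("calibration recovers generating coefficients and reports fit quality", {
  psup <- seq(0, 20, length.out = 21)
  cal <- calibrate_transmission(cbind(psup, 8.09 * psup + 67.41))
  expect_equal(unname(coef(cal)["alpha_t"]), 8.09, tolerance = 1e-12)
  expect_equal(unname(coef(cal)["mu"]), 67.41, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(cal$pearson_r, 1, tolerance = 1e-12)
  # round trip: refitted line reproduces the forces
  expect_lt(max(abs((coef(cal)["alpha_t"] * psup + coef(cal)["mu"]) -
                      (8.09 * psup + 67.41))), 1e-9)
  # independent route: closed-form OLS slope/intercept
  fa <- 8.09 * psup + 67.41
  expect_equal(unname(coef(cal)["alpha_t"]),
               cov(psup, fa) / var(psup), tolerance = 1e-12)
  expect_equal(unname(coef(cal)["mu"]),
               mean(fa) - cov(psup, fa) / var(psup) * mean(psup),
               tolerance = 1e-12)
})

test_that("degenerate and singular calibrations are flagged, not silently fit", {
  psup <- seq(0, 20, length.out = 11)
  flat <- calibrate_transmission(cbind(psup, rep(50, 11)))
  expect_true(flat$degenerate)
  expect_equal(flat$model$alpha_t, 0)
  expect_equal(flat$model$mu, 50)
  expect_true(is.na(flat$pearson_r))
  expect_error(calibrate_transmission(cbind(rep(5, 10), 1:10)), "singular")
  expect_error(calibrate_transmission(cbind(1:2, 1:2)), "at least 3")
})

test_that("noisy calibration lands within standard-error bounds", {
  set.seed(303)
  psup <- seq(0, 20, length.out = 121)
  sigma <- 8
  fa <- 8.09 * psup + 67.41 + rnorm(121, 0, sigma)
  cal <- calibrate_transmission(cbind(psup, fa))
  se <- summary(cal$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(cal$model$alpha_t - 8.09), 4 * se["psup"])
  expect_lt(abs(cal$model$mu - 67.41), 4 * se["(Intercept)"])
})
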