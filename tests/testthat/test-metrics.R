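test_that("breath segmentation counts cycles and rejects degenerate input", {
  tr <- sine_trace(Q0 = 0.5, rate = 12, duration = 60)
  br <- segment_breaths(tr)
  expect_true(nrow(br) %in% c(11, 12))
  flat <- data.frame(t = seq(0, 10, by = 0.005), Q = 0)
  expect_equal(nrow(segment_breaths(flat)), 0)
  half <- sine_trace(Q0 = 0.5, rate = 12, duration = 2.4)  # single half-cycle
  expect_equal(nrow(segment_breaths(half)), 0)
})

test_that("boundary flutter is rejected by the minimum-volume criterion", {
  tr <- sine_trace(Q0 = 0.5, rate = 12, duration = 60)
  # inject a tiny positive blip inside each inspiration
  blip <- tr$Q
  period <- 5; fs <- 200
  for (k in 0:10) {
    i <- round((k * period + 3.1) * fs)
    blip[i:(i + 8)] <- 0.03
  }
  tr2 <- tr; tr2$Q <- blip
  tr2$V <- cumsum(c(0, diff(tr2$t) * (blip[-length(blip)] + blip[-1]) / 2))
  expect_equal(nrow(segment_breaths(tr2)), nrow(segment_breaths(tr)))
})

test_that("sine fixture reproduces the closed-form metrics", {
  Q0 <- 0.5; rate <- 12
  m <- compute_metrics(sine_trace(Q0 = Q0, rate = rate, duration = 60))
  Tb <- 60 / rate
  expect_equal(m$pef, Q0, tolerance = 0.005)
  expect_equal(m$mtv, Q0 * Tb / pi, tolerance = 0.005)     # 0.7958 L
  expect_equal(m$mv, rate * Q0 * Tb / pi, tolerance = 0.005)  # 9.549 L/min
  expect_equal(m$rate_observed, rate, tolerance = 0.01)
  # internal consistency: MV agrees with MTV x observed rate within 2%
  expect_lt(abs(m$mv - m$mtv * m$rate_observed) / m$mv, 0.02)
  # phase split balances for periodic zero-mean flow
  expect_equal(m$mv_insp, m$mv_exp, tolerance = 0.01)
})

test_that("metrics error without a complete breath and scale with flow", {
  flat <- data.frame(t = seq(0, 10, by = 0.005), Q = 0, V = 0)
  expect_error(compute_metrics(flat), "breath")
  tr <- sine_trace(Q0 = 0.4, rate = 20, duration = 30)
  m1 <- compute_metrics(tr)
  tr3 <- tr; tr3$Q <- 3 * tr$Q; tr3$V <- 3 * tr$V
  m3 <- compute_metrics(tr3)
  expect_equal(m3$pef, 3 * m1$pef, tolerance = 1e-12)
  expect_equal(m3$mtv, 3 * m1$mtv, tolerance = 1e-12)
  expect_equal(m3$mv, 3 * m1$mv, tolerance = 1e-12)
})

test_that("improvement rates are plain percent changes", {
  base <- structure(list(pef = 0.5, mtv = 1, mv = 9, mv_exp = 9,
                         mv_insp = 9), class = "metrics_report")
  up <- structure(list(pef = 0.6, mtv = 1.1, mv = 9.9, mv_exp = 9.9,
                       mv_insp = 9.9), class = "metrics_report")
  imp <- improvement_rates(base, up)
  expect_equal(imp$pct_change[imp$metric == "pef"], 20)
  expect_equal(improvement_rates(base, base)$pct_change, rep(0, 5))
  expect_equal(mean(c(10, 20, 30)), 20)   # cohort aggregation is the mean
  bad <- base; bad$pef <- 0
  expect_error(improvement_rates(bad, up), "positive")
})

test_that("paired significance handles identical, degenerate and shifted cohorts", {
  x <- matrix(rnorm(24), 8, 3, dimnames = list(NULL, c("pef", "mtv", "mv")))
  same <- paired_significance(x, x)
  expect_equal(same$p_value, rep(1, 3))
  expect_equal(same$stars, rep("", 3))
  shifted <- paired_significance(x, x + 1)   # zero-variance differences
  expect_true(all(shifted$degenerate))
  expect_error(paired_significance(x[1:2, ], x[1:2, ]), "at least 3")
  set.seed(8)
  y <- x + 1 + matrix(rnorm(24, 0, 0.3), 8, 3)
  res <- paired_significance(x, y)
  expect_true(all(res$p_value < 0.001))
  expect_true(all(res$stars == "***"))
  resw <- paired_significance(x, y, test = "wilcoxon")
  expect_true(all(resw$p_value < 0.05))
})

test_that("empirical power of the paired test matches the analytic power", {
  set.seed(31)
  n <- 8; reps <- 1000
  hits <- replicate(reps, {
    base <- rnorm(n)
    t.test(base + 1 + rnorm(n) * 0, base + rnorm(n),
           paired = TRUE)$p.value < 0.05
  })
  target <- power.t.test(n = n, delta = 1, sd = 1, sig.level = 0.05,
                         type = "paired")$power
  expect_lt(abs(mean(hits) - target), 0.05)
})
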