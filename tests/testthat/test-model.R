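test_that("model evaluation matches the closed form on both branches", {
  g <- biphasic_model("gaussian", b = 1, c = 0, d = 10, e = 5, f = 1)
  expect_equal(predict(g, 5), 10)                       # peak is d
  expect_equal(predict(g, 4), 10 * exp(-0.5), tolerance = 1e-6)
  g2 <- biphasic_model("gaussian", b = 1, c = 0, d = 10, e = 5, f = 2)
  expect_equal(predict(g2, 7), 10 * exp(-0.5), tolerance = 1e-6)
  lg <- biphasic_model("loggaussian", b = 0.5, c = 3, d = 20, e = 2, f = 1.5)
  expect_equal(predict(lg, 0), 3)                       # left-tail limit
  expect_equal(predict(lg, 2), 20)
  # right branch uses width b*f on the log-dose scale
  expect_equal(predict(lg, 2 * exp(0.75)),
               3 + 17 * exp(-0.5), tolerance = 1e-12)
})

test_that("evaluation rejects invalid doses and parameters", {
  g <- biphasic_model("gaussian", b = 1, c = 0, d = 10, e = 5)
  expect_error(predict(g, NaN), "finite")
  expect_error(predict(g, Inf), "finite")
  expect_error(predict(g, -1), "non-negative")
  expect_error(biphasic_model("gaussian", b = -1, c = 0, d = 1, e = 1),
               "'b'")
  expect_error(biphasic_model("gaussian", b = 1, c = 2, d = 1, e = 1),
               "exceed")
  expect_error(biphasic_model("loggaussian", b = 1, c = 0, d = 1, e = -2),
               "'e'")
})

test_that("tails approach the baseline on both sides", {
  set.seed(401)
  for (i in 1:20) {
    m <- random_model()
    far <- if (m$kind == "gaussian") m$e + 50 * m$b * max(m$f, 1)
           else m$e * exp(50 * m$b * max(m$f, 1))
    expect_equal(predict(m, far), m$c, tolerance = 1e-8)
    if (m$kind == "loggaussian") expect_equal(predict(m, 0), m$c)
  }
})

test_that("effect_at_p interpolates baseline to peak and is even in p", {
  m <- biphasic_model("gaussian", b = 1, c = 0, d = 10, e = 5)
  expect_equal(effect_at_p(m, -50), 5)
  expect_equal(effect_at_p(m, 0), 10)
  zn <- biphasic_model("loggaussian", b = 0.41, c = 2.27, d = 79.31,
                       e = 2.43, f = 0.66)
  expect_equal(effect_at_p(zn, -50), 40.79)
  expect_equal(effect_at_p(zn, 50), effect_at_p(zn, -50))
  expect_error(effect_at_p(m, 101), "\\[-100, 100\\]")
})

test_that("dose_at_p inverts the curve branch by branch", {
  g <- biphasic_model("gaussian", b = 1, c = 0, d = 10, e = 5)
  expect_equal(dose_at_p(g, 0), 5)
  expect_equal(dose_at_p(g, -50), 5 - sqrt(2 * log(2)), tolerance = 1e-6)
  lg <- biphasic_model("loggaussian", b = 0.4103, c = 2, d = 70, e = 2.43,
                       f = 0.7)
  expect_equal(dose_at_p(lg, -50), 2.43 * exp(-0.4103 * sqrt(2 * log(2))),
               tolerance = 1e-12)
  expect_error(dose_at_p(g, 100), "strictly within")
  # ascending-branch inversion below dose 0 is clipped with a classed warning
  wide <- biphasic_model("gaussian", b = 4, c = 0, d = 10, e = 5)
  expect_warning(dd <- dose_at_p(wide, -99), class = "biphasicCI_dose_clipped")
  expect_identical(dd, 0)
})

test_that("round-trip evaluate(dose_at_p(p)) == effect_at_p(p)", {
  set.seed(402)
  ps <- c(seq(-99, -9, by = 10), seq(9, 99, by = 10), 0)
  for (i in 1:100) {
    m <- random_model()
    rel <- abs(predict(m, dose_at_p(m, ps)) - effect_at_p(m, ps)) /
      effect_at_p(m, ps)
    expect_lt(max(rel), 1e-10)
  }
})

test_that("dose_at_p is strictly increasing in p; branches are monotone", {
  set.seed(403)
  ps <- seq(-99, 99, by = 3)
  for (i in 1:20) {
    m <- random_model()
    expect_true(all(diff(dose_at_p(m, ps)) > 0))
    left <- seq(max(m$e * 0.01, dose_at_p(m, -99)), m$e, length.out = 50)
    right <- seq(m$e, dose_at_p(m, 99), length.out = 50)
    expect_true(all(diff(predict(m, left)) > 0))
    expect_true(all(diff(predict(m, right)) < 0))
  }
})

test_that("edp bundles (p, dose, effect) with the peak at p = 0", {
  zn <- biphasic_model("loggaussian", b = 0.410, c = 2.27, d = 79.31,
                       e = 2.43, f = 0.66)
  v <- edp(zn, c(-50, 0, 50))
  expect_equal(v$dose[v$p == 0], 2.43)
  expect_equal(v$effect[v$p == 0], 79.31)
  expect_equal(v$effect[v$p == -50], v$effect[v$p == 50])
})
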