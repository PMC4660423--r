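test_that("noise-free data reproduces the generating parameters", {
  for (kind in c("gaussian", "loggaussian")) {
    m <- biphasic_model(kind, b = 1.2, c = 1, d = 50, e = 4, f = 0.8)
    dat <- simulate_single(m, design_doses(m, 9, 2), cv = 0, n_rep = 1)
    fit <- fit_biphasic(response ~ dose, dat, kind = kind)
    expect_true(fit$converged)
    expect_lt(max(abs(coef(fit) - coef(m)) / coef(m)), 1e-6)
    expect_lt(fit$rss, 1e-12)
  }
})

test_that("fit accessors and methods are coherent", {
  m <- biphasic_model("loggaussian", b = 0.8, c = 1, d = 60, e = 3, f = 0.9)
  dat <- simulate_single(m, design_doses(m, 8, 2), cv = 0.05, n_rep = 3,
                         seed = 7)
  fit <- fit_biphasic(response ~ dose, dat)
  expect_s3_class(fit, "biphasic_fit")
  expect_equal(fit$n_obs, nrow(dat))
  expect_equal(fitted(fit) + residuals(fit), dat$response)
  expect_equal(sum(residuals(fit)^2), fit$rss)
  expect_equal(predict(fit, dose = 3), predict(fit$model, 3))
  expect_output(print(fit), "Biphasic dose-response fit")
  expect_output(print(summary(fit)), "Effective-dose vectors")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_named(sims[[1]], c("series_id", "dose", "response", "replicate"))
})

test_that("Box-Cox lambda = 1 reproduces the untransformed fit", {
  m <- biphasic_model("loggaussian", b = 0.8, c = 2, d = 60, e = 3, f = 1.1)
  dat <- simulate_single(m, design_doses(m, 8, 2), cv = 0.1, n_rep = 3,
                         seed = 21)
  plain <- fit_biphasic(response ~ dose, dat, kind = "loggaussian")
  tbs <- fit_biphasic(response ~ dose, dat, kind = "loggaussian",
                      boxcox = TRUE, lambda_grid = 1)
  expect_equal(tbs$boxcox_lambda, 1)
  expect_equal(coef(tbs), coef(plain), tolerance = 1e-5)
})

test_that("Box-Cox profile likelihood picks a stabilising lambda", {
  m <- biphasic_model("loggaussian", b = 0.8, c = 2, d = 60, e = 3, f = 1.1)
  dat <- simulate_single(m, design_doses(m, 8, 2), cv = 0.3, n_rep = 4,
                         seed = 22)
  tbs <- fit_biphasic(response ~ dose, dat, kind = "loggaussian",
                      boxcox = TRUE)
  # strongly multiplicative noise should pull lambda well below 1
  expect_lt(tbs$boxcox_lambda, 1)
  expect_true(tbs$converged)
})

test_that("degenerate and invalid inputs are flagged, never silent", {
  flat <- data.frame(dose = rep(2^(0:5), 2), response = 5)
  expect_warning(
    expect_warning(fit <- fit_biphasic(response ~ dose, flat),
                   "degenerate|constant"),
    "peak")
  expect_false(fit$converged)
  expect_true(is.na(fit$rss))
  few <- data.frame(dose = c(1, 2, 4, 8), response = c(1, 5, 4, 2))
  expect_error(fit_biphasic(response ~ dose, few), "5 distinct")
  oneside <- data.frame(dose = rep(2^(0:5), 2),
                        response = predict(
                          biphasic_model("loggaussian", b = 1, c = 0,
                                         d = 10, e = 100),
                          rep(2^(0:5), 2)))
  expect_warning(fit_biphasic(response ~ dose, oneside), "peak")
})

test_that("select_model picks the generating kind by minimum RSS", {
  lg <- biphasic_model("loggaussian", b = 0.6, c = 1, d = 60, e = 3, f = 0.8)
  dat <- simulate_single(lg, design_doses(lg, 9, 2), cv = 0.08, n_rep = 3,
                         seed = 31)
  sel <- select_model(response ~ dose, dat)
  expect_equal(sel$kind, "loggaussian")
  expect_equal(nrow(sel$selection), 2)

  # linear dose spacing: geometric designs starve a dose-scale gaussian
  g <- biphasic_model("gaussian", b = 2, c = 1, d = 60, e = 10, f = 0.8)
  dat0 <- simulate_single(g, seq(2, 16, length.out = 9), cv = 0, n_rep = 1)
  sel0 <- select_model(response ~ dose, dat0)
  expect_equal(sel0$kind, "gaussian")
  expect_lt(sel0$rss, 1e-10)
})

test_that("parameter bias vanishes as the noise level shrinks", {
  m <- biphasic_model("loggaussian", b = 0.8, c = 1, d = 80, e = 2.5,
                      f = 0.8)
  doses <- design_doses(m, 8, 2)
  err <- vapply(c(0, 0.02, 0.1), function(cv) {
    set.seed(51)
    med <- replicate(25, {
      dat <- simulate_single(m, doses, cv = cv, n_rep = 3)
      fit <- suppressWarnings(fit_biphasic(response ~ dose, dat))
      if (fit$converged) max(abs(coef(fit) - coef(m)) / coef(m)) else NA
    })
    median(med, na.rm = TRUE)
  }, 0)
  expect_lt(err[1], 1e-6)
  expect_true(all(diff(err) > 0))   # error grows with cv
  expect_lt(err[2], 0.1)
})
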