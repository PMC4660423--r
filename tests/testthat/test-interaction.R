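test_that("the weighted index is the exact product of the two dimensions", {
  expect_identical(ci_weighted(0.5, 0.5), 0.25)
  expect_identical(ci_weighted(1, 1), 1)
  expect_identical(ci_weighted(0.5, 2), 1)
  expect_error(ci_weighted(-1, 1), "positive")
})

test_that("management thresholds classify 0.5 and 2 inclusively", {
  expect_equal(as.character(classify_management(c(0.25, 1, 2.5))),
               c("synergism", "additive", "antagonism"))
  expect_equal(as.character(classify_management(c(0.5, 2))),
               c("additive", "additive"))
  expect_error(classify_management(0), "positive")
})

test_that("a sham mixture scores CI = 1 in both dimensions at every p", {
  m <- biphasic_model("loggaussian", b = 0.7, c = 2, d = 60, e = 3, f = 0.8)
  s <- mixture_spec(c("x", "y"), c(0.4, 0.6))
  prof <- ci_profile(m, list(m, m), s, seq(-95, 95, by = 5))
  expect_equal(prof$ci_d, rep(1, nrow(prof)))
  expect_equal(prof$ci_e, rep(1, nrow(prof)))
  expect_equal(prof$ci_w, prof$ci_d * prof$ci_e)
  expect_true(all(prof$category == "additive"))
})

test_that("CI ratios and orientation follow their definitions", {
  cp <- component_pair()
  p <- c(-50, 0, 50)
  # a mixture curve with twice the additive peak effect and half the dose
  cur <- predict_with_interaction(cp$fits, cp$spec, seq(-99, 99, 0.5),
                                  ci_d = 0.5, ci_e = 0.5)
  ci <- ci_at_p(cur, cp$fits, cp$spec, p)
  expect_equal(ci$ci_d, rep(0.5, 3), tolerance = 1e-6)
  expect_equal(ci$ci_e, rep(0.5, 3), tolerance = 1e-6)
  expect_equal(ci$ci_w, ci$ci_d * ci$ci_e)
  lit <- ci_at_p(cur, cp$fits, cp$spec, p, ci_e_orientation = "literal")
  expect_equal(lit$ci_e, 1 / ci$ci_e, tolerance = 1e-9)
})

test_that("profiles generated with constant CI are recovered flat", {
  cp <- component_pair()
  for (ci_true in list(c(0.5, 1), c(1, 2), c(2, 0.7))) {
    cur <- predict_with_interaction(cp$fits, cp$spec, seq(-99, 99, 0.5),
                                    ci_d = ci_true[1], ci_e = ci_true[2])
    prof <- ci_profile(cur, cp$fits, cp$spec, seq(-90, 90, 10))
    expect_lt(max(abs(prof$ci_d - ci_true[1])), 1e-6)
    expect_lt(max(abs(prof$ci_e - ci_true[2])), 1e-6)
  }
})

test_that("ci_e falls as the mixture peak rises; ci_d falls as its MPC drops", {
  cp <- component_pair()
  p <- c(-60, -20, 0, 20, 60)
  mk <- function(d = 60, e = 4) biphasic_model("loggaussian", b = 0.8,
                                               c = 1.2, d = d, e = e,
                                               f = 0.85)
  ci_e_by_d <- vapply(c(40, 60, 90), function(d)
    ci_at_p(mk(d = d), cp$fits, cp$spec, p)$ci_e, numeric(length(p)))
  expect_true(all(apply(ci_e_by_d, 1, diff) < 0))
  ci_d_by_e <- vapply(c(5, 4, 3), function(e)
    ci_at_p(mk(e = e), cp$fits, cp$spec, p)$ci_d, numeric(length(p)))
  expect_true(all(apply(ci_d_by_e, 1, diff) < 0))
})

test_that("the departure t-test works on the log scale", {
  r <- test_departure(c(0.5, 0.55, 0.45, 0.5))
  expect_equal(r$t, -16.97, tolerance = 1e-3)
  expect_lt(r$p_value, 0.001)
  expect_equal(r$df, 3)
  # degenerate conventions
  expect_equal(test_departure(c(1, 1, 1))$p_value, 1)
  z <- test_departure(c(2, 2, 2))
  expect_equal(z$p_value, 0)
  expect_true(z$degenerate)
  # log-scale shift equivariance: doubling maps H0:1 onto H0:2
  x <- c(0.8, 1.1, 0.95, 1.2)
  expect_equal(test_departure(2 * x, null_value = 2)$t,
               test_departure(x)$t)
  expect_error(test_departure(1.2), "at least 2")
  expect_error(test_departure(c(1, -1)), "positive")
})

test_that("polygonogram summary tabulates pairs by p level", {
  m <- biphasic_model("loggaussian", b = 0.7, c = 2, d = 60, e = 3)
  s <- mixture_spec(c("Zn", "Cu"), c(0.5, 0.5))
  sham <- ci_at_p(m, list(m, m), s, c(-50, 0, 50))
  syn <- sham; syn$ci_w <- rep(0.3, 3)
  syn$category <- classify_management(syn$ci_w)
  tab <- polygonogram_summary(list("Zn:Cu" = sham, "Zn:Co" = syn))
  expect_equal(nrow(tab), 2 * 3)
  expect_true(all(tab$category[tab$component_b == "Cu"] == "additive"))
  expect_true(all(tab$category[tab$component_b == "Co"] == "synergism"))
  expect_warning(polygonogram_summary(list("Zn:Cu" = sham),
                                      p_levels = c(-50, 25)),
                 "absent")
})

test_that("replicate-level CI estimation recovers an imposed departure", {
  cp <- component_pair()
  cur <- predict_with_interaction(cp$fits, cp$spec, seq(-99, 99, 0.5),
                                  ci_d = 0.5, ci_e = 1)
  doses <- design_doses(cur, 8, 2)
  set.seed(77)
  dat <- simulate_mixture(cp$fits, cp$spec, 0.5, 1, doses, cv = 0.08,
                          n_rep = 4)
  rep_ci <- suppressWarnings(
    ci_replicates(dat, cp$fits, cp$spec, p = 0, kind = "loggaussian"))
  expect_gte(nrow(rep_ci), 2)
  td <- test_departure(rep_ci$ci_d)
  expect_lt(td$estimate, 0.7)   # clearly synergistic in D
  expect_lt(td$p_value, 0.05)
  te <- test_departure(rep_ci$ci_e)
  expect_gt(te$p_value, 0.05)   # no departure imposed in E
})
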