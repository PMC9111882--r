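test_that("identical estimates pool to their common value with tau2 = 0", {
  ef <- data.frame(d = rep(0.1, 5), se = rep(0.05, 5))
  fit <- meta_change(d ~ 1, data = ef)
  expect_equal(unname(fit$beta), 0.1)
  expect_equal(fit$tau2, 0)
  expect_equal(unname(fit$se_beta), 0.05 / sqrt(5))
  expect_equal(unname(fit$ci.lb), 0.1 - 1.959964 * 0.05 / sqrt(5),
               tolerance = 1e-6)
  expect_equal(unname(fit$ci.ub), 0.1 + 1.959964 * 0.05 / sqrt(5),
               tolerance = 1e-6)
  expect_equal(fit$QE, 0)
  expect_equal(fit$I2, 0)
})

test_that("two opposite equal-precision estimates pool to zero", {
  ef <- data.frame(d = c(-0.1, 0.1), se = c(0.04, 0.04))
  fit <- meta_change(d ~ 1, data = ef)
  expect_equal(unname(fit$beta), 0, tolerance = 1e-12)
})

test_that("REML agrees with the brute-force restricted-likelihood grid", {
  ef <- toy_effects()
  fit <- meta_change(d ~ 1, data = ef)
  oracle <- reml_grid_oracle(ef$d, ef$se^2)
  expect_lt(abs(unname(fit$beta) - oracle$pooled), 1e-5)
  expect_lt(abs(fit$tau2 - oracle$tau2), 1e-5)
  expect_lt(abs(unname(fit$se_beta) - oracle$se_pooled), 1e-5)
})

test_that("REML matches an independent reference implementation", {
  skip_if_not_installed("metafor")
  ef <- toy_effects()
  fit <- meta_change(d ~ 1, data = ef)
  ref <- metafor::rma(yi = ef$d, sei = ef$se, method = "REML",
                      control = list(threshold = 1e-10))
  expect_equal(unname(fit$beta), unname(c(ref$beta)), tolerance = 1e-7)
  expect_equal(fit$tau2, ref$tau2, tolerance = 1e-7)
  expect_equal(fit$QE, ref$QE, tolerance = 1e-8)
  expect_equal(fit$I2, ref$I2, tolerance = 1e-4)

  dl <- meta_change(d ~ 1, data = ef, method = "DL")
  refdl <- metafor::rma(yi = ef$d, sei = ef$se, method = "DL")
  expect_equal(dl$tau2, refdl$tau2, tolerance = 1e-10)
})

test_that("Cochran's Q follows its fixed-effect hand computation", {
  # three estimates d = 0, 0.1, 0.2 with common se 0.05: FE mean 0.1,
  # Q = (0.01 + 0 + 0.01)/0.0025 = 8
  ef <- data.frame(d = c(0, 0.1, 0.2), se = rep(0.05, 3))
  fit <- meta_change(d ~ 1, data = ef)
  expect_equal(fit$QE, 8)
  expect_equal(fit$QE_df, 2)
  expect_equal(fit$QE_p, pchisq(8, 2, lower.tail = FALSE))
})

test_that("mean Q is close to k - 1 under homogeneity", {
  set.seed(31)
  k <- 10
  Qs <- replicate(400, {
    se <- runif(k, 0.02, 0.08)
    ef <- data.frame(d = rnorm(k, 0, se), se = se)
    meta_change(d ~ 1, data = ef, method = "DL")$QE
  })
  expect_equal(mean(Qs), k - 1, tolerance = 0.08)
})

test_that("pooling is invariant to estimate order", {
  ef <- toy_effects()
  fit <- meta_change(d ~ 1, data = ef)
  perm <- ef[sample(nrow(ef)), ]
  fitp <- meta_change(d ~ 1, data = perm)
  expect_equal(fit$beta, fitp$beta, tolerance = 1e-9)
  expect_equal(fit$tau2, fitp$tau2, tolerance = 1e-9)
  expect_equal(fit$QE, fitp$QE, tolerance = 1e-9)
})

test_that("rescaling d and se rescales the pooled estimate only", {
  ef <- toy_effects()
  f1 <- meta_change(d ~ 1, data = ef)
  ef2 <- transform(ef, d = 3 * d, se = 3 * se)
  f2 <- meta_change(d ~ 1, data = ef2)
  expect_equal(unname(f2$beta), 3 * unname(f1$beta), tolerance = 1e-6)
  expect_equal(unname(f2$se_beta), 3 * unname(f1$se_beta), tolerance = 1e-6)
  expect_equal(f2$zval, f1$zval, tolerance = 1e-5)
  expect_equal(f2$I2, f1$I2, tolerance = 1e-3)
  expect_equal(f2$QE_p, f1$QE_p, tolerance = 1e-9)
})

test_that("DL and REML agree at the tau2 = 0 boundary for equal-precision estimates", {
  # with a common se, both estimators hit the boundary exactly when
  # Q <= k - 1, and the fit reduces to the fixed-effect mean
  set.seed(7)
  found <- 0
  for (i in 1:50) {
    ef <- data.frame(d = rnorm(6, 0, 0.02), se = 0.05)
    dl <- meta_change(d ~ 1, data = ef, method = "DL")
    if (dl$QE <= dl$QE_df) {
      found <- found + 1
      re <- meta_change(d ~ 1, data = ef, method = "REML")
      expect_identical(dl$tau2, 0)
      expect_identical(re$tau2, 0)
      expect_equal(re$beta, dl$beta, tolerance = 1e-10)
      expect_equal(unname(re$beta), mean(ef$d), tolerance = 1e-10)
    }
  }
  expect_gt(found, 5)  # the condition actually occurred
})

test_that("degenerate inputs are rejected", {
  expect_error(meta_change(d ~ 1, data = data.frame(d = 0.1, se = 0.05)),
               "at least two")
  expect_error(meta_change(d ~ 1, data = data.frame(d = c(0.1, 0.2),
                                                    se = c(0, 0.05))),
               "se = 0")
  expect_warning(
    fit <- pool_changes(data.frame(d = c(0.1, 0.2, 0), se = c(0.05, 0.04, 0))),
    "degenerate")
  expect_equal(fit$k, 2)
})

test_that("leave-one-out refits k models and flags gross outliers", {
  ef <- data.frame(estimate_id = paste0("e", 1:5),
                   d = rep(0.1, 5), se = rep(0.05, 5))
  loo <- leave_one_out(pool_changes(ef))
  expect_equal(nrow(loo), 5)
  expect_true(all(abs(loo$pooled - 0.1) < 1e-12))
  expect_false(any(loo$outside_ci | loo$sig_flip))

  # four tight negative estimates plus one gross positive outlier: the
  # full model is non-significant, omitting the outlier makes it
  # strongly significant, so that omission is flagged
  out <- data.frame(estimate_id = paste0("e", 1:5),
                    d = c(-0.12, -0.11, -0.13, -0.10, 0.90),
                    se = c(0.01, 0.01, 0.01, 0.01, 0.005))
  loo2 <- leave_one_out(pool_changes(out))
  expect_equal(nrow(loo2), 5)
  expect_true(loo2$outside_ci[loo2$omitted == "e5"] |
                loo2$sig_flip[loo2$omitted == "e5"])
  expect_false(any(loo2$sig_flip[loo2$omitted != "e5"]))

  expect_error(leave_one_out(data.frame(d = c(0.1, 0.2), se = c(0.05, 0.05))),
               "at least 3")
})

test_that("accessor methods are mutually consistent", {
  ef <- toy_effects()
  fit <- meta_change(d ~ 1, data = ef)
  expect_equal(unname(coef(fit)), unname(fit$beta))
  expect_equal(drop(vcov(fit)), unname(fit$se_beta)^2, tolerance = 1e-12)
  expect_equal(unname(fitted(fit)), rep(unname(fit$beta), 7))
  expect_equal(unname(residuals(fit)), ef$d - unname(fit$beta))
  expect_equal(sum(weights(fit)), 100)
  ci <- confint(fit)
  expect_equal(unname(ci[1, 1]), unname(fit$ci.lb))
  pr <- predict(fit, newdata = data.frame(row = 1))
  expect_equal(pr$fit, unname(fit$beta))
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(7, 3))
})
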