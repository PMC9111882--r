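test_that("Bonferroni threshold divides alpha by the model count", {
  expect_identical(bonferroni_alpha(0.05, 4), 0.0125)
  expect_identical(bonferroni_alpha(0.05, 1), 0.05)
  expect_identical(bonferroni_alpha(0.01, 5), 0.002)
  expect_error(bonferroni_alpha(0.05, 0), "positive")
  expect_error(bonferroni_alpha(1.2, 4), "alpha")
})

test_that("an intercept-only design reproduces the plain random-effects fit", {
  ef <- toy_effects()
  plain <- pool_changes(ef)
  viaformula <- meta_change(d ~ 1, data = ef)
  expect_equal(viaformula$beta, plain$beta)
  expect_equal(viaformula$tau2, plain$tau2)
  expect_equal(viaformula$se_beta, plain$se_beta)
  expect_equal(viaformula$QE, plain$QE)
})

test_that("meta-regression uses the stated reference levels and dummy coding", {
  ef <- toy_effects()
  ef$period <- c("P2", "P1", "P3", "P1", "P2", "P1", "P3")
  mr <- fit_meta_regression(ef, "period")
  expect_equal(mr$reference_level, "P1")
  expect_equal(mr$QM_df, 2)          # levels - 1 coefficients
  expect_equal(nrow(mr$level_means), 3)
  expect_equal(mr$alpha_corrected, 0.0125)
  # intercept is the P1 level mean
  expect_equal(unname(mr$beta[1]),
               mr$level_means$fit[mr$level_means$level == "P1"])
})

test_that("level means are invariant to the reference level", {
  ef <- toy_effects()
  ef$g <- c("A", "B", "C", "A", "B", "C", "A")
  lvord <- list(c("A", "B", "C"), c("C", "A", "B"), c("B", "C", "A"))
  means <- lapply(lvord, function(lv) {
    ef$g <- factor(ef$g, levels = lv)
    fit <- meta_change(d ~ g, data = ef)
    pr <- predict(fit, newdata = data.frame(g = factor(c("A", "B", "C"),
                                                       levels = lv)))
    pr$fit
  })
  expect_equal(means[[1]], means[[2]], tolerance = 1e-8)
  expect_equal(means[[1]], means[[3]], tolerance = 1e-8)
})

test_that("two-level fits equal subgroup pooling under the shared tau2", {
  set.seed(13)
  ef <- data.frame(d = rnorm(12, -0.05, 0.05), se = runif(12, 0.02, 0.08),
                   weighted = rep(c(FALSE, TRUE), each = 6))
  mr <- fit_meta_regression(ef, "weighted")
  # subgroup oracle: inverse-variance means within each level using the
  # meta-regression's residual tau2
  for (lv in c(FALSE, TRUE)) {
    sub <- ef[ef$weighted == lv, ]
    w <- 1 / (sub$se^2 + mr$tau2)
    expect_equal(mr$level_means$fit[mr$level_means$level == as.character(lv)],
                 sum(w * sub$d) / sum(w), tolerance = 1e-6)
    expect_equal(mr$level_means$se[mr$level_means$level == as.character(lv)],
                 1 / sqrt(sum(w)), tolerance = 1e-6)
  }
})

test_that("meta-regression matches the reference implementation", {
  skip_if_not_installed("metafor")
  ef <- toy_effects()
  ef$period <- c("P2", "P1", "P3", "P1", "P2", "P1", "P3")
  mr <- fit_meta_regression(ef, "period")
  ref <- metafor::rma(yi = ef$d, sei = ef$se,
                      mods = ~ factor(period, levels = c("P1", "P2", "P3")),
                      data = ef, method = "REML",
                      control = list(threshold = 1e-10))
  expect_equal(unname(mr$beta), unname(c(ref$beta)), tolerance = 1e-6)
  expect_equal(mr$tau2, ref$tau2, tolerance = 1e-6)
  expect_equal(mr$QM, ref$QM, tolerance = 1e-5)
})

test_that("degenerate moderator designs are rejected or repaired", {
  ef <- toy_effects()
  ef$period <- "P1"
  expect_error(fit_meta_regression(ef, "period"), "single observed level")

  ef$period <- factor(c("P2", "P1", "P3", "P1", "P2", "P1", "P1"),
                      levels = c("P1", "P2", "P3", "unused"))
  expect_warning(fit_meta_regression(ef, "period"), "empty level")
})

test_that("a true period effect is recovered by the P3 - P1 contrast", {
  set.seed(17)
  cfg <- synthetic_config(
    k = 60, mu = -0.02, tau = 0.03, churn = 0.5, n_range = c(1000, 1000),
    moderator_effects = list(period = c(P1 = 0, P2 = 0, P3 = -0.14)),
    moderator_prevalence = list(
      period = c(P1 = 0.5, P2 = 0.2, P3 = 0.3),
      age_profile = c(general = 1), weighted = c(`FALSE` = 1),
      sub_region = c(Western = 1)))
  contrasts <- replicate(200, {
    rec <- generate_studies(cfg, seed = sample.int(1e6, 1))
    ef <- compute_effects(rec)
    mr <- fit_meta_regression(ef, "period")
    unname(mr$beta[which(colnames(mr$X) == "periodP3")])
  })
  expect_equal(mean(contrasts), -0.14, tolerance = 0.02 / 0.14)
})
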