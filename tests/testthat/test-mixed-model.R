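lmer_oracle <- function(y, d, reml = TRUE) {
  df <- data.frame(
    y = y,
    age = factor(d$gestational_age, c("90", "110")),
    geno = factor(d$fetal_genotype, c("LW", "MSLW", "LWMS", "MS")),
    sow = d$sow_id)
  suppressMessages(lme4::lmer(y ~ age * geno + (1 | sow), df, REML = reml,
                              control = lme4::lmerControl(calc.derivs = FALSE)))
}

test_that("mixed-model estimates agree with lme4 on simulated probes", {
  skip_if_not_installed("lme4")
  d <- generateDesign(4, 4, seed = 1)
  sim <- simulateExpression(d, 6, c(0.2, 0.2, 0.2, 0.2, 0.2),
                            sow_sd = 0.3, resid_sd = 0.25, seed = 11)
  E <- exprMatrix(sim)
  for (j in seq_len(nrow(E))) {
    fit <- fitProbeMixedModel(E[j, ], d)
    lf <- lmer_oracle(E[j, ], d, reml = TRUE)
    expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-6)
    vc <- as.data.frame(lme4::VarCorr(lf))
    expect_equal(fit$sigma2_sow, vc$vcov[1], tolerance = 1e-5)
    expect_equal(fit$sigma2_resid, vc$vcov[2], tolerance = 1e-5)
    expect_equal(fit$loglik_reml, as.numeric(stats::logLik(lf)),
                 tolerance = 1e-6)
    fit_ml <- fitProbeMixedModel(E[j, ], d, criterion = "ML")
    lf_ml <- lmer_oracle(E[j, ], d, reml = FALSE)
    expect_equal(fit_ml$loglik_ml, as.numeric(stats::logLik(lf_ml)),
                 tolerance = 1e-6)
  }
})

test_that("constant response collapses to the intercept with zero variances", {
  d <- generateDesign(3, 3, seed = 2)
  y <- rep(7.5, nrow(d))
  fit <- fitProbeMixedModel(y, d)
  expect_equal(unname(fit$beta["(Intercept)"]), 7.5, tolerance = 1e-8)
  expect_equal(unname(fit$beta[-1]), rep(0, fit$p - 1), tolerance = 1e-8)
  expect_lt(fit$sigma2_sow, 1e-10)
  expect_lt(fit$sigma2_resid, 1e-10)
})

test_that("with no sow variance the fixed effects equal OLS", {
  # one fetus per sow: the sow effect coincides with the residual
  d1 <- generateDesign(8, 1, seed = 3)
  sim <- simulateExpression(d1, 3, c(1, 0, 0, 0, 0), sow_sd = 0,
                            resid_sd = 0.4, seed = 4)
  # balanced litters: GLS coincides with OLS for any sow-variance estimate
  d2 <- generateDesign(6, 4, seed = 5, balanced_litters = TRUE)
  sim2 <- simulateExpression(d2, 3, c(0, 1, 0, 0, 0), sow_sd = 0,
                             resid_sd = 0.3, seed = 6)
  for (cs in list(list(sim, d1), list(sim2, d2))) {
    E <- exprMatrix(cs[[1]]); d <- cs[[2]]
    df <- data.frame(
      age = factor(d$gestational_age, c("90", "110")),
      geno = factor(d$fetal_genotype, c("LW", "MSLW", "LWMS", "MS")))
    for (j in seq_len(nrow(E))) {
      fit <- fitProbeMixedModel(E[j, ], d)
      ols <- stats::lm(E[j, ] ~ age * geno, df)
      expect_equal(unname(fit$beta), unname(stats::coef(ols)),
                   tolerance = 1e-6)
    }
  }
})

test_that("REML recovers the sow variance in repeated simulation", {
  d <- generateDesign(6, 4, seed = 7)
  n_rep <- 200
  sim <- simulateExpression(d, n_rep, c(1, 0, 0, 0, 0), sow_sd = 0.5,
                            resid_sd = 0.2, seed = 8)
  E <- exprMatrix(sim)
  s2 <- vapply(seq_len(n_rep), function(j)
    fitProbeMixedModel(E[j, ], d)$sigma2_sow, numeric(1))
  expect_equal(mean(s2), 0.25, tolerance = 0.15)
})

test_that("ML log-likelihood of the full model dominates nested models", {
  d <- generateDesign(4, 4, seed = 9)
  sim <- simulateExpression(d, 8, c(0.25, 0.25, 0.25, 0.25, 0),
                            seed = 10)
  E <- exprMatrix(sim)
  for (j in seq_len(nrow(E))) {
    full <- fitProbeMixedModel(E[j, ], d, criterion = "ML")
    for (f in list(~ gestational_age + fetal_genotype, ~ gestational_age,
                   ~ fetal_genotype, ~ 1)) {
      red <- fitProbeMixedModel(E[j, ], d, fixed = f, criterion = "ML")
      expect_gte(full$loglik_ml, red$loglik_ml - 1e-7)
    }
  }
})

test_that("F-type test behaves at its boundaries and detects planted signal", {
  d <- generateDesign(8, 4, seed = 1)
  sim <- simulateExpression(d, 1, c(0, 0, 0, 1, 0), effect_size = 2,
                            sow_sd = 0.1, resid_sd = 0.1, seed = 12)
  y <- exprMatrix(sim)[1, ]
  full <- fitProbeMixedModel(y, d)
  red <- fitProbeMixedModel(y, d, fixed = ~ 1)
  # identical models: F = 0, p = 1
  same <- ftypeTest(full, full)
  expect_equal(same$F_stat, 0)
  expect_equal(same$p_value, 1)
  # strong planted age effect: overwhelming evidence
  ft <- ftypeTest(full, red)
  expect_lt(ft$p_value, 1e-6)
  expect_equal(ft$df_num, 7)
  # non-nested models are refused
  f_age <- fitProbeMixedModel(y, d, fixed = ~ gestational_age)
  f_gen <- fitProbeMixedModel(y, d, fixed = ~ fetal_genotype)
  expect_error(ftypeTest(f_age, f_gen), "not nested")
  # likelihood-ratio alternative gives a consistent chi-square p
  lrt <- ftypeTest(fitProbeMixedModel(y, d, criterion = "ML"),
                   fitProbeMixedModel(y, d, fixed = ~ 1, criterion = "ML"),
                   type = "lrt")
  expect_equal(lrt$p_value,
               stats::pchisq(lrt$chisq, lrt$df, lower.tail = FALSE))
  expect_lt(lrt$p_value, 1e-6)
})

test_that("Satterthwaite F matches lmerTest's joint contest", {
  skip_if_not_installed("lmerTest")
  d <- generateDesign(8, 4, seed = 1)
  sim <- simulateExpression(d, 5, c(1, 0, 0, 0, 0), sow_sd = 0.15,
                            resid_sd = 0.3, seed = 13)
  E <- exprMatrix(sim)
  df <- data.frame(
    age = factor(d$gestational_age, c("90", "110")),
    geno = factor(d$fetal_genotype, c("LW", "MSLW", "LWMS", "MS")),
    sow = d$sow_id)
  for (j in seq_len(nrow(E))) {
    full <- fitProbeMixedModel(E[j, ], d)
    red <- fitProbeMixedModel(E[j, ], d, fixed = ~ 1)
    ours <- ftypeTest(full, red)
    df$y <- E[j, ]
    m <- suppressMessages(lmerTest::lmer(y ~ age * geno + (1 | sow), df))
    ct <- lmerTest::contest(m, diag(8)[-1, ], joint = TRUE)
    expect_equal(ours$F_stat, ct[["F value"]], tolerance = 1e-5)
    expect_equal(ours$df_den, ct[["DenDF"]], tolerance = 1e-4)
    expect_equal(ours$p_value, ct[["Pr(>F)"]], tolerance = 1e-5)
  }
})

test_that("rank-deficient designs fail naming the empty cell", {
  d <- generateDesign(4, 4, seed = 14)
  keep <- !(d$gestational_age == "110" & d$fetal_genotype == "MS")
  sub <- d[keep, ]
  expect_error(fitProbeMixedModel(rnorm(nrow(sub)), sub), "110:MS")
})

test_that("BH adjustment is order-preserving and matches the step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.1, 1.2)), "in \\[0, 1\\]")
  expect_error(bhAdjust(c(0.1, NA)), "finite")
  for (s in 1:20) {
    set.seed(s)
    p <- stats::runif(sample(2:50, 1))
    expect_equal(bhAdjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})
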