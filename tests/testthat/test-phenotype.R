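test_that("assumption checks flag variance and normality violations", {
  set.seed(1)
  g <- rep(c("a", "b"), each = 20)
  # one group with 10x the variance trips Bartlett
  y <- c(rnorm(20, sd = 1), rnorm(20, sd = sqrt(10)))
  chk <- checkAssumptions(y, g)
  expect_lt(chk$bartlett_p, 0.01)
  # heavy right skew trips Shapiro
  ys <- exp(rnorm(50, sd = 1.2))
  chk2 <- checkAssumptions(ys, rep("a", 25) |> c(rep("b", 25)))
  expect_lt(chk2$shapiro_p, 0.05)
  # well-behaved data passes both at typical levels
  yn <- rnorm(40)
  chk3 <- checkAssumptions(yn, g)
  expect_gt(chk3$bartlett_p, 0.001)
  expect_error(checkAssumptions(c(1, 2), c("a", "b")), "at least 3")
  expect_error(checkAssumptions(c(1, 2, 3), c("a", "a", "b")),
               ">= 2 observations")
})

test_that("Box-Cox profile likelihood recovers known exponents", {
  lam0 <- vapply(1:5, function(s) {
    set.seed(s)
    boxcoxLambda(exp(rnorm(200)))$lambda
  }, numeric(1))
  expect_true(all(abs(lam0) < 0.15))
  # lambda is weakly identified when the data sit far from zero, so the
  # identity transform is recovered on average over replicates
  lam1 <- vapply(1:10, function(s) {
    set.seed(500 + s)
    boxcoxLambda(rnorm(500, mean = 10, sd = 1))$lambda
  }, numeric(1))
  expect_lt(abs(mean(lam1) - 1), 0.3)
})

test_that("Box-Cox agrees with the MASS profile and is continuous at 0", {
  skip_if_not_installed("MASS")
  set.seed(7)
  y <- exp(rnorm(150, sd = 0.8)) + 2
  ours <- boxcoxLambda(y, shift = FALSE)
  bc <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_equal(ours$lambda, bc$x[which.max(bc$y)], tolerance = 0.02)
  # the log branch is the continuous limit of the power branch
  z_log <- boxcoxTransform(y, list(lambda = 0, shift = 0))
  z_eps <- boxcoxTransform(y, list(lambda = 1e-4, shift = 0))
  expect_equal(z_log, z_eps, tolerance = 1e-3)
  expect_lt(max(abs(z_log - z_eps)), 1e-2 * max(abs(z_log)))
  expect_error(boxcoxLambda(c(-1, 1, 2, 3, 4), shift = FALSE),
               "non-positive")
})

test_that("two-way ANOVA handles degenerate and balanced cases", {
  d <- generateDesign(6, 4, seed = 1)
  age <- d$gestational_age
  geno <- d$fetal_genotype
  # constant response: all F = 0, p = 1
  z <- twowayAnova(rep(3, nrow(d)), age, geno)
  expect_equal(unname(z$F), c(0, 0, 0))
  expect_equal(unname(z$p), c(1, 1, 1))
  # balanced 2x2: Type II equals the classical sequential decomposition
  set.seed(2)
  n <- 10
  bage <- rep(c("90", "110"), each = 2 * n)
  bgen <- rep(rep(c("LW", "MS"), each = n), 2)
  y <- rnorm(4 * n) + (bage == "110") * 0.8
  ours <- twowayAnova(y, bage, bgen)
  cls <- stats::anova(stats::lm(y ~ factor(bage) * factor(bgen)))
  expect_equal(unname(ours$F["age"]), cls$`F value`[1], tolerance = 1e-10)
  expect_equal(unname(ours$F["genotype"]), cls$`F value`[2],
               tolerance = 1e-10)
  # a missing age x genotype combination is refused
  keep <- !(bage == "110" & bgen == "MS")
  expect_error(twowayAnova(y[keep], bage[keep], bgen[keep]), "empty")
  expect_error(twowayAnova(y[1:5], bage[1:5], bgen[1:5]), "2 observed levels")
})

test_that("age F equals the squared age-contrast t on a balanced design", {
  set.seed(3)
  n <- 10
  age <- rep(c("90", "110"), each = 2 * n)
  geno <- rep(rep(c("LW", "MS"), each = n), 2)
  y <- rnorm(4 * n) + (age == "110") * 0.6
  ours <- twowayAnova(y, age, geno)
  # with effects coding on a balanced layout the 1-df main effect satisfies
  # F = t^2 for the corresponding coefficient
  af <- C(factor(age, c("90", "110")), contr.sum)
  gf <- C(factor(geno), contr.sum)
  fit <- stats::lm(y ~ af * gf)
  t_age <- stats::coef(summary(fit))["af1", "t value"]
  expect_equal(unname(ours$F["age"]), unname(t_age)^2, tolerance = 1e-8)
})

test_that("Tukey letters separate means and unite equal groups", {
  set.seed(4)
  d <- generateDesign(6, 4, seed = 5)
  base <- rnorm(nrow(d), sd = 0.2)
  y <- base + (d$gestational_age == "110") * 5
  lets <- tukeyLetters(y, d$gestational_age, d$fetal_genotype)
  l110 <- lets[grepl("^110:", names(lets))]
  l90 <- lets[grepl("^90:", names(lets))]
  expect_length(intersect(unique(unlist(strsplit(l110, ""))),
                          unique(unlist(strsplit(l90, "")))), 0)
  # indistinguishable cells share a letter
  lets0 <- tukeyLetters(base, d$gestational_age, d$fetal_genotype)
  common <- Reduce(intersect, strsplit(lets0, ""))
  expect_gt(length(common), 0)
})

test_that("the phenotype workflow records its transform decisions", {
  d <- generateDesign(6, 4, seed = 6)
  sim <- simulateExpression(d, 10, seed = 7)
  sim <- simulatePhenotypes(sim, n_phenotypes = 3, n_drivers = 2,
                            noise_sd = 0.5, seed = 8)
  # make one variable strongly skewed
  ph <- phenotypes(sim)
  cd <- SummarizedExperiment::colData(sim)
  set.seed(9)
  cd$pheno_03 <- exp(scale(ph[, 3])[, 1] * 1.5)
  SummarizedExperiment::colData(sim) <- cd
  res <- analyzePhenotypes(sim)
  expect_equal(nrow(res), 3)
  expect_identical(res$transformed, res$shapiro_p < 0.05)
  expect_true(all(is.na(res$lambda) == !res$transformed))
  expect_true(all(res$p_age >= 0 & res$p_age <= 1, na.rm = TRUE))
})
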