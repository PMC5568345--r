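test_that("generated designs satisfy the reciprocal-cross invariants", {
  cases <- list(c(9, 4), c(1, 1), c(3, 2), c(5, 3))
  for (cs in cases) {
    d <- generateDesign(cs[1], cs[2], seed = 11)
    expect_equal(nrow(d), 2 * cs[1] * cs[2])
    expect_equal(length(unique(d$sow_id)), 2 * cs[1])
    # fetal genotype is the deterministic cross function
    expect_identical(d$fetal_genotype,
                     crossGenotype(d$maternal_genotype, d$paternal_genotype))
    # one maternal genotype and one age per sow
    per_sow <- split(d, d$sow_id)
    for (s in per_sow) {
      expect_length(unique(s$maternal_genotype), 1)
      expect_length(unique(s$gestational_age), 1)
      if (cs[2] >= 2)  # both sire breeds present in every litter
        expect_setequal(unique(s$paternal_genotype), c("LW", "MS"))
    }
    # sows split across ages, extra sow at day 90
    for (br in c("LW", "MS")) {
      sows_br <- unique(d[d$maternal_genotype == br, c("sow_id", "gestational_age")])
      n90 <- sum(sows_br$gestational_age == "90")
      expect_equal(n90, ceiling(cs[1] / 2))
    }
  }
})

test_that("study-sized design has 18 sows, 72 samples, 8 full cells", {
  d <- generateDesign(9, 4, seed = 1)
  expect_equal(length(unique(d$sow_id)), 18)
  expect_equal(nrow(d), 72)
  tab <- table(d$gestational_age, d$fetal_genotype)
  expect_equal(sum(tab > 0), 8)
})

test_that("design generation is deterministic and validates parameters", {
  expect_identical(generateDesign(4, 3, seed = 7), generateDesign(4, 3, seed = 7))
  expect_error(generateDesign(0, 3), "must be >= 1")
  expect_error(generateDesign(3, 0), "must be >= 1")
  d <- generateDesign(1, 1, seed = 0)
  expect_equal(nrow(d), 2)
  expect_identical(d$fetal_genotype,
                   crossGenotype(d$maternal_genotype, d$paternal_genotype))
})

test_that("simulated expression realizes the planted fixed-effect structure", {
  d <- generateDesign(6, 4, seed = 2)
  # zero-noise null probe is constant at its baseline
  s0 <- simulateExpression(d, 3, c(1, 0, 0, 0, 0), sow_sd = 0, resid_sd = 0,
                           seed = 5)
  e0 <- exprMatrix(s0)
  tt <- truthTable(s0)
  for (j in 1:3)
    expect_equal(unname(e0[j, ]), rep(tt$mu[j], ncol(e0)), tolerance = 1e-12)

  # age-only probes: day110 - day90 difference = 1 within every genotype
  sa <- simulateExpression(d, 30, c(0, 0, 0, 1, 0), effect_size = 1,
                           sow_sd = 0, resid_sd = 0.2, seed = 6)
  ea <- exprMatrix(sa)
  dd <- designTable(sa)
  for (g in unique(dd$fetal_genotype)) {
    i110 <- dd$gestational_age == "110" & dd$fetal_genotype == g
    i90 <- dd$gestational_age == "90" & dd$fetal_genotype == g
    diffs <- rowMeans(ea[, i110, drop = FALSE]) -
      rowMeans(ea[, i90, drop = FALSE])
    tol <- 3 * 0.2 * sqrt(1 / sum(i110) + 1 / sum(i90))
    expect_true(all(abs(diffs - 1) < 3 * tol))
    expect_lt(abs(mean(diffs) - 1), tol)
  }

  # degenerate proportions put every probe in the null class
  sn <- simulateExpression(d, 100, c(1, 0, 0, 0, 0), seed = 7)
  expect_true(all(truthTable(sn)$true_class == "null"))
})

test_that("expression simulation is deterministic with stable probe streams", {
  d <- generateDesign(3, 3, seed = 1)
  a <- simulateExpression(d, 40, seed = 42)
  b <- simulateExpression(d, 40, seed = 42)
  expect_identical(exprMatrix(a), exprMatrix(b))
  expect_identical(truthTable(a), truthTable(b))
  # first probes unchanged when more probes are requested
  big <- simulateExpression(d, 80, seed = 42)
  expect_identical(exprMatrix(big)[1:40, ], exprMatrix(a))
})

test_that("expression simulation rejects invalid inputs", {
  d <- generateDesign(2, 2, seed = 1)
  expect_error(simulateExpression(d[1, , drop = FALSE], 5), "at least 2")
  expect_error(simulateExpression(d, 5, c(0.5, 0.1, 0.1, 0.1, 0.1)),
               "sum to 1")
  expect_error(simulateExpression(d, 5, sow_sd = -1), ">= 0")
})

test_that("between-sow variance of sow means approaches sow_sd^2", {
  d <- generateDesign(12, 12, seed = 3)
  s <- simulateExpression(d, 60, c(1, 0, 0, 0, 0), sow_sd = 0.5,
                          resid_sd = 0.1, seed = 8)
  e <- exprMatrix(s)
  dd <- designTable(s)
  v <- vapply(seq_len(nrow(e)), function(j) {
    sow_means <- tapply(e[j, ], dd$sow_id, mean)
    stats::var(sow_means - mean(sow_means))
  }, numeric(1))
  # expected var = sow_sd^2 + resid_sd^2/12
  expect_equal(mean(v), 0.25 + 0.01 / 12, tolerance = 0.15)
})

test_that("simulated phenotypes follow their driver probes", {
  d <- generateDesign(4, 4, seed = 1)
  s <- simulateExpression(d, 30, seed = 2)
  # zero noise, one driver, unit weight: phenotype equals the probe row
  p1 <- simulatePhenotypes(s, n_phenotypes = 2, n_drivers = 1,
                           driver_weight = 1, noise_sd = 0, seed = 3)
  drv <- S4Vectors::metadata(p1)$phenotype_drivers
  ph <- phenotypes(p1)
  for (k in 1:2) {
    probe <- drv[[k]]$probes
    expect_equal(unname(ph[, k]), unname(exprMatrix(p1)[probe, ]))
  }
  # zero driver weight: phenotype is pure noise, uncorrelated with probes
  p0 <- simulatePhenotypes(s, n_phenotypes = 1, n_drivers = 5,
                           driver_weight = 0, noise_sd = 1, seed = 4)
  r <- abs(stats::cor(phenotypes(p0)[, 1], t(exprMatrix(p0))))
  expect_lt(stats::median(r), 3 / sqrt(ncol(p0)))
  # determinism
  p2 <- simulatePhenotypes(s, n_phenotypes = 2, n_drivers = 1,
                           driver_weight = 1, noise_sd = 0, seed = 3)
  expect_identical(phenotypes(p1), phenotypes(p2))
  expect_error(simulatePhenotypes(s, n_phenotypes = 0), ">= 1")
  expect_error(simulatePhenotypes(s, n_drivers = 1000), "exceeds")
})

test_that("synthetic qPCR encodes expression in cycles and is deterministic", {
  d <- generateDesign(3, 3, seed = 1)
  s <- simulateExpression(d, 10, seed = 2)
  q1 <- simulateQPCR(s, n_references = 3, seed = 5)
  q2 <- simulateQPCR(s, n_references = 3, seed = 5)
  expect_identical(q1$cq, q2$cq)
  expect_true(all(q1$cq > 0))
  expect_true(all(q1$efficiency > 0.98 & q1$efficiency < 1.05))
  # noiseless, perfect-efficiency Cq maps back to expression exactly
  q0 <- simulateQPCR(s, efficiency_range = c(1, 1), cq_noise_sd = 0,
                     reference_sd = 0, seed = 6)
  g <- q0$target_genes[1]
  back <- max(exprMatrix(s)[g, ]) - (q0$cq[g, ] - min(q0$cq[g, ]))
  expect_equal(unname(back), unname(exprMatrix(s)[g, ]), tolerance = 1e-10)
})

test_that("MaturityExperiment enforces design consistency", {
  d <- generateDesign(2, 2, seed = 1)
  s <- simulateExpression(d, 5, seed = 1)
  expect_s4_class(s, "MaturityExperiment")
  expect_identical(designTable(s)$sample_id, colnames(exprMatrix(s)))
  bad <- d
  bad$fetal_genotype[1] <- "MS"  # contradicts the parental cross
  expect_error(MaturityExperiment(exprMatrix(s), bad), "inconsistent")
})
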