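sim_xy <- function(seed, n = 40, p = 30, q = 3, support = 5, noise = 0.3,
                   rank1 = FALSE, coef_range = c(1, 2)) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", seq_len(p))))
  B <- matrix(0, p, q)
  # comparable coefficient magnitudes so the support dominates the weights
  coefs <- sample(c(-1, 1), support * q, replace = TRUE) *
    runif(support * q, coef_range[1], coef_range[2])
  B[seq_len(support), ] <- coefs
  if (rank1) B[seq_len(support), ] <- outer(coefs[seq_len(support)],
                                            runif(q, 0.5, 1.5))
  Y <- X %*% B + matrix(rnorm(n * q, sd = noise), n, q)
  colnames(Y) <- paste0("ph", seq_len(q))
  list(X = X, Y = Y, support = paste0("g", seq_len(support)))
}

test_that("PCA summaries decompose variance correctly", {
  d <- generateDesign(4, 4, seed = 1)
  sim <- simulateExpression(d, 20, seed = 1)
  p <- pcaSummary(exprMatrix(sim))
  expect_equal(sum(p$var_fraction), 100, tolerance = 1e-9)
  expect_true(all(p$var_fraction >= 0))
  expect_equal(nrow(p$scores), ncol(sim))
  # two perfectly correlated probes: one component carries everything
  base <- rnorm(10)
  two <- rbind(a = base, b = 2 * base + 3)
  colnames(two) <- paste0("s", 1:10)
  expect_equal(unname(pcaSummary(two)$var_fraction[1]), 100,
               tolerance = 1e-9)
  expect_error(pcaSummary(matrix(1, 3, 4)), "constant")
})

test_that("sPLS selects exactly keepX probes and honors bounds", {
  s <- sim_xy(1)
  f1 <- splsFit(s$X, s$Y, 1, keepX = 1)
  expect_equal(sum(f1@weights[, 1] != 0), 1)
  expect_error(splsFit(s$X, s$Y, 1, keepX = 0), "keepX")
  expect_error(splsFit(s$X, s$Y, 1, keepX = ncol(s$X) + 1), "keepX")
  Ybad <- s$Y; Ybad[, 2] <- 7
  expect_error(splsFit(s$X, Ybad, 1), "ph2")
})

test_that("noiseless sparse signal is recovered exactly", {
  for (s in 1:3) {
    dat <- sim_xy(s, n = 200, q = 1, noise = 0, coef_range = c(2, 3))
    f <- splsFit(dat$X, dat$Y, 1, keepX = 5)
    expect_setequal(selectedProbes(f, 1), dat$support)
  }
})

test_that("single predictor/response degenerates to simple regression", {
  set.seed(3)
  x <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "g1"))
  y <- matrix(2 * x + rnorm(20, sd = 0.1), 20, 1,
              dimnames = list(NULL, "ph1"))
  f <- splsFit(x, y, 1, keepX = 1)
  expect_equal(abs(cor(f@variates[, 1], scale(x)[, 1])), 1, tolerance = 1e-10)
})

test_that("unconstrained first component matches the classical PLS oracle", {
  for (s in 1:3) {
    dat <- sim_xy(s + 10)
    f <- splsFit(dat$X, dat$Y, 1, keepX = ncol(dat$X))
    w_o <- pls1_oracle(dat$X, dat$Y)
    w <- f@weights[, 1]
    sgn <- sign(sum(w * w_o))
    expect_lt(max(abs(w - sgn * w_o)), 1e-8)
  }
})

test_that("successive variates are uncorrelated under regression deflation", {
  dat <- sim_xy(20, q = 4, support = 10)
  f <- splsFit(dat$X, dat$Y, 3, keepX = c(10, 10, 10))
  ct <- cor(f@variates)
  expect_lt(max(abs(ct[upper.tri(ct)])), 1e-8)
  expect_lt(max(abs(colMeans(f@variates))), 1e-10)
})

test_that("Q2 separates informative from uninformative responses", {
  dat <- sim_xy(30, n = 48, noise = 0.3)
  q2 <- q2CrossVal(dat$X, dat$Y, 2, keepX = 5, n_folds = 5, seed = 1)
  expect_gt(q2[1], 0.09)
  expect_true(all(q2 <= 1))
  set.seed(31)
  Ynoise <- matrix(rnorm(48 * 3), 48, 3, dimnames = list(NULL, paste0("n", 1:3)))
  q2n <- q2CrossVal(dat$X, Ynoise, 1, keepX = 5, n_folds = 5, seed = 1)
  expect_lte(q2n[1], 0.09)
  expect_error(q2CrossVal(dat$X, dat$Y, 1, 5, n_folds = 1), "n_folds")
})

test_that("MSEP and R2 reach their noiseless and pure-noise limits", {
  dat <- sim_xy(40, n = 150, noise = 1e-6, rank1 = TRUE,
                coef_range = c(2, 3))
  f <- splsFit(dat$X, dat$Y, 1, keepX = 5)
  mr <- msepR2(dat$X, dat$Y, f, n_folds = 4, seed = 2)
  # nearly noiseless rank-1 signal: one component predicts almost perfectly
  expect_true(all(mr$msep < 0.1))
  expect_true(all(mr$r2 > 0.9))
  set.seed(41)
  Yn <- matrix(rnorm(150), 150, 1, dimnames = list(NULL, "noise"))
  fn <- splsFit(dat$X, Yn, 1, keepX = 5)
  mrn <- msepR2(dat$X, Yn, fn, n_folds = 4, seed = 2)
  expect_equal(mrn$msep, 1, tolerance = 0.5)
  expect_lt(mrn$r2, 0.3)
})

test_that("MSEP ranking matches an independent mixOmics CV loop", {
  skip_if_not_installed("mixOmics")
  dat <- sim_xy(50, n = 40, p = 25, q = 4, support = 5, noise = 0.5)
  # degrade two responses with extra noise so the ranking is non-trivial
  set.seed(51)
  dat$Y[, 3] <- dat$Y[, 3] + rnorm(40, sd = 8)
  dat$Y[, 4] <- dat$Y[, 4] + rnorm(40, sd = 3)
  f <- splsFit(dat$X, dat$Y, 1, keepX = 5)
  mr <- msepR2(dat$X, dat$Y, f, n_folds = 4, seed = 3)
  Ys <- scale(dat$Y)
  fold <- maturix:::.makeFolds(40, 4, seed = 3)  # same partition as msepR2
  press <- matrix(0, 1, 4)
  for (fd in 1:4) {
    test <- fold == fd
    m <- mixOmics::spls(dat$X[!test, ], Ys[!test, ], ncomp = 1, keepX = 5,
                        mode = "regression", scale = TRUE)
    pr <- predict(m, dat$X[test, ])$predict[, , 1]
    press <- press + colSums((Ys[test, ] - pr)^2)
  }
  oracle_msep <- drop(press) / 40
  expect_equal(order(mr$msep), order(oracle_msep))
})

test_that("relevance network scores behave like signed correlations", {
  set.seed(60)
  n <- 40
  driver <- rnorm(n)
  X <- cbind(d1 = driver, indep = rnorm(n),
             matrix(rnorm(n * 10), n, 10,
                    dimnames = list(NULL, paste0("g", 1:10))))
  Y <- cbind(ph1 = driver)  # phenotype equals the driver probe exactly
  f <- splsFit(X, Y, 1, keepX = 1)
  edges <- relevanceNetwork(f, X, Y, components = 1, cutoff = 0.75)
  expect_equal(edges$probe_id, "d1")
  expect_gt(abs(edges$score), 0.95)
  expect_true(all(abs(edges$score) <= 1))
  # independent probes score near zero / extreme cutoff empties the set
  all_edges <- relevanceNetwork(f, X, Y, 1, cutoff = 0.75, probes = "all")
  expect_false("indep" %in% all_edges$probe_id)
  # with noise in the response, a near-1 cutoff empties the edge set
  Yn <- Y + rnorm(n, sd = 0.3)
  fn <- splsFit(X, Yn, 1, keepX = 1)
  none <- relevanceNetwork(fn, X, Yn, 1, cutoff = 0.999999, probes = "all")
  expect_equal(nrow(none), 0)
  expect_error(relevanceNetwork(f, X, Y, integer(0)), "non-empty")
  expect_error(relevanceNetwork(f, X, Y, 1, cutoff = 1.2), "cutoff")
})

test_that("network writers emit valid SIF and GraphML", {
  edges <- data.frame(probe_id = c("p1", "p2"), phenotype = c("ph1", "ph1"),
                      score = c(0.9, -0.8), component_of_origin = c(1L, 1L))
  tmp <- withr::local_tempdir()
  sif <- file.path(tmp, "n.sif")
  writeNetworkSIF(edges, sif)
  lines <- readLines(sif)
  expect_length(lines, 2)
  expect_match(lines[2], "^p2\tneg\tph1$")
  gml <- file.path(tmp, "n.graphml")
  writeNetworkGraphML(edges, gml, submodel = c(p1 = "complete"))
  doc <- xml2::read_xml(gml)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, "//d1:edge", ns), 2)
  expect_length(xml2::xml_find_all(doc, "//d1:node", ns), 3)
})
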