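## Per-probe linear mixed model with a single random litter (sow) intercept.
##
## Model: y = X beta + Z u + e, u ~ N(0, sigma2_sow I), e ~ N(0, sigma2_resid I).
## With ZZ' = Q D Q' (computed once per design), the rotated responses
## Q'y have diagonal covariance sigma2_resid (I + lambda D),
## lambda = sigma2_sow/sigma2_resid, so the profiled ML/REML criterion is a
## cheap 1-d function of lambda; optimization (golden section on log lambda
## with an explicit boundary check at lambda = 0) runs in compiled code.
## Fixed effects use treatment contrasts: age 90 reference, genotype level
## order LW < MSLW < LWMS < MS, interaction as the product basis.

.designFactors <- function(design) {
  design <- .checkDesign(design)
  data.frame(
    gestational_age = factor(design$gestational_age, AGE_LEVELS),
    fetal_genotype = factor(design$fetal_genotype, GENOTYPE_LEVELS),
    maternal_genotype = factor(design$maternal_genotype, BREED_LEVELS),
    paternal_genotype = factor(design$paternal_genotype, BREED_LEVELS),
    sow_id = design$sow_id,
    row.names = design$sample_id)
}

# precompute the rotated fixed-effect basis for one design + formula
.mmContext <- function(design, fixed = ~ gestational_age * fetal_genotype) {
  df <- .designFactors(design)
  X <- stats::model.matrix(fixed, df)
  n <- nrow(X); p <- ncol(X)
  if (length(unique(df$sow_id)) < 2)
    stop("design must contain at least 2 sows")
  if (n - p < 1) stop("no residual degrees of freedom for this formula")
  if (qr(X)$rank < p) {
    tab <- table(df$gestational_age, df$fetal_genotype)
    empty <- which(tab == 0, arr.ind = TRUE)
    cells <- if (nrow(empty)) paste(rownames(tab)[empty[, 1]],
                                    colnames(tab)[empty[, 2]],
                                    sep = ":", collapse = ", ") else "unknown"
    stop("rank-deficient fixed-effect design; empty cell(s): ", cells)
  }
  Z <- stats::model.matrix(~ 0 + factor(sow_id), df)
  eg <- eigen(tcrossprod(Z), symmetric = TRUE)
  Q <- eg$vectors
  d <- pmax(eg$values, 0)
  list(X = X, Q = Q, d = d, Xt = crossprod(Q, X), n = n, p = p,
       coef_names = colnames(X), factors = df, fixed = fixed)
}

.asProbeFit <- function(raw, ctx, yt, probe_id = NA_character_) {
  beta <- as.numeric(raw$beta)
  names(beta) <- ctx$coef_names
  structure(list(
    probe_id = probe_id, beta = beta,
    sigma2_sow = raw$sigma2_sow, sigma2_resid = raw$sigma2_resid,
    lambda = raw$lambda,
    loglik_ml = raw$loglik_ml, loglik_reml = raw$loglik_reml,
    n = ctx$n, p = ctx$p, cov_unscaled = raw$cov_unscaled,
    yt = yt, ctx = ctx), class = "probe_fit")
}

#' Fit the per-probe mixed model
#'
#' Estimates fixed effects and the two variance components (sow, residual)
#' for one probe by profiled ML or REML; the sow variance is constrained to
#' be nonnegative (a boundary estimate of 0 is allowed).  Both ML and REML
#' log-likelihoods are reported at the fitted variance ratio.
#'
#' @param y numeric expression values, one per design row.
#' @param design design data.frame (see \code{\link{generateDesign}}).
#' @param fixed fixed-effects formula in terms of \code{gestational_age},
#'   \code{fetal_genotype}, \code{maternal_genotype}, \code{paternal_genotype}.
#' @param criterion "REML" (default, for testing) or "ML" (for BIC).
#' @param tol convergence tolerance on the profiled criterion.
#' @return a \code{probe_fit} list: \code{beta} (named fixed effects),
#'   \code{sigma2_sow}, \code{sigma2_resid}, \code{loglik_ml},
#'   \code{loglik_reml}, \code{cov_unscaled} and the model context.
#' @examples
#' d <- generateDesign(4, 4, seed = 1)
#' sim <- simulateExpression(d, n_probes = 1, class_proportions = c(0,0,0,1,0),
#'                           seed = 1)
#' fit <- fitProbeMixedModel(exprMatrix(sim)[1, ], d)
#' fit$beta
#' @export
fitProbeMixedModel <- function(y, design,
                               fixed = ~ gestational_age * fetal_genotype,
                               criterion = c("REML", "ML"), tol = 1e-10) {
  criterion <- match.arg(criterion)
  ctx <- if (inherits(design, "mm_context")) design else .mmContext(design, fixed)
  if (length(y) != ctx$n) stop("length(y) does not match the design")
  yt <- drop(crossprod(ctx$Q, y))
  raw <- .fit_vc_cpp(ctx$Xt, yt, ctx$d, criterion == "REML", tol)
  .asProbeFit(raw, ctx, yt)
}

# --- Satterthwaite machinery -------------------------------------------------

# asymptotic covariance of (sigma2_resid, sigma2_sow) from a numeric Hessian
# of the -2 REML log-likelihood
.vcCov <- function(ctx, yt, s2e, s2u) {
  f <- function(a, b) .crit_theta_cpp(ctx$Xt, yt, ctx$d, a, b, TRUE)
  # small negative s2u excursions are fine as long as V stays positive
  h1 <- max(1e-8, 1e-4 * s2e)
  h2 <- max(1e-8, 1e-4 * max(s2u, s2e))
  f00 <- f(s2e, s2u)
  H <- matrix(0, 2, 2)
  H[1, 1] <- (f(s2e + h1, s2u) - 2 * f00 + f(s2e - h1, s2u)) / h1^2
  H[2, 2] <- (f(s2e, s2u + h2) - 2 * f00 + f(s2e, s2u - h2)) / h2^2
  H[1, 2] <- H[2, 1] <-
    (f(s2e + h1, s2u + h2) - f(s2e + h1, s2u - h2) -
       f(s2e - h1, s2u + h2) + f(s2e - h1, s2u - h2)) / (4 * h1 * h2)
  W <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(W) || any(!is.finite(W)) || any(diag(W) <= 0)) NULL else W
}

# joint Wald F of the contrasts in rows of L, denominator df by the
# eigen-contrast Satterthwaite pooling
.waldFTest <- function(fitfull, L) {
  ctx <- fitfull$ctx
  q <- nrow(L)
  n <- ctx$n; p <- ctx$p
  s2e <- fitfull$sigma2_resid
  s2u <- fitfull$sigma2_sow
  M <- .cvc_cpp(ctx$Xt, ctx$d, s2e, s2u, L)
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  U <- eg$vectors[, pos, drop = FALSE]
  lam <- eg$values[pos]
  qeff <- sum(pos)
  cb <- drop(L %*% fitfull$beta)
  tsq <- drop(crossprod(U, cb))^2 / lam
  Fstat <- sum(tsq) / qeff

  df_resid <- n - p
  nu <- rep(df_resid, qeff)
  if (fitfull$lambda > 1e-8 && !is.null(fitfull$yt)) {
    W <- .vcCov(ctx, fitfull$yt, s2e, s2u)
    if (!is.null(W)) {
      h1 <- max(1e-8, 1e-4 * s2e)
      h2 <- max(1e-8, 1e-4 * max(s2u, s2e))
      Mp1 <- .cvc_cpp(ctx$Xt, ctx$d, s2e + h1, s2u, L)
      Mm1 <- .cvc_cpp(ctx$Xt, ctx$d, s2e - h1, s2u, L)
      Mp2 <- .cvc_cpp(ctx$Xt, ctx$d, s2e, s2u + h2, L)
      Mm2 <- .cvc_cpp(ctx$Xt, ctx$d, s2e, s2u - h2, L)
      for (i in seq_len(qeff)) {
        u <- U[, i]
        g <- c(drop(crossprod(u, (Mp1 - Mm1) %*% u)) / (2 * h1),
               drop(crossprod(u, (Mp2 - Mm2) %*% u)) / (2 * h2))
        denom <- drop(crossprod(g, W %*% g))
        if (denom > 0) {
          v <- 2 * lam[i]^2 / denom
          if (is.finite(v) && v > 0) nu[i] <- v
        }
      }
    }
  }
  ok <- nu > 2
  if (!any(ok)) {
    df_den <- df_resid
  } else if (qeff == 1) {
    df_den <- nu[1]
  } else {
    E <- sum(nu[ok] / (nu[ok] - 2))
    df_den <- if (E > qeff) 2 * E / (E - qeff) else df_resid
  }
  p_value <- stats::pf(Fstat, qeff, df_den, lower.tail = FALSE)
  list(F_stat = Fstat, df_num = qeff, df_den = df_den, p_value = p_value)
}

#' F-type test of a full against a nested reduced mixed model
#'
#' Joint Wald-type F test of the fixed-effect contrasts present in the full
#' model but absent from the reduced one, at the full model's REML variance
#' estimates, with denominator degrees of freedom by the Satterthwaite
#' approximation (eigen-contrast pooling).  \code{type = "lrt"} substitutes a
#' ML likelihood-ratio chi-square for sensitivity checks.
#'
#' @param full,reduced \code{probe_fit} objects on the same design; the
#'   reduced model's coefficients must be a subset of the full model's.
#' @param type "wald" (default) or "lrt".
#' @return list with \code{F_stat}, \code{df_num}, \code{df_den},
#'   \code{p_value} (for "lrt": \code{chisq}, \code{df}, \code{p_value}).
#' @examples
#' d <- generateDesign(4, 4, seed = 1)
#' sim <- simulateExpression(d, 1, c(0, 0, 0, 1, 0), effect_size = 2, seed = 3)
#' y <- exprMatrix(sim)[1, ]
#' full <- fitProbeMixedModel(y, d)
#' red <- fitProbeMixedModel(y, d, fixed = ~ 1)
#' ftypeTest(full, red)$p_value
#' @export
ftypeTest <- function(full, reduced, type = c("wald", "lrt")) {
  type <- match.arg(type)
  stopifnot(inherits(full, "probe_fit"), inherits(reduced, "probe_fit"))
  if (full$n != reduced$n)
    stop("full and reduced fits use different designs")
  extra <- setdiff(names(full$beta), names(reduced$beta))
  if (!all(names(reduced$beta) %in% names(full$beta)))
    stop("models are not nested: reduced has coefficients absent from full")
  if (!length(extra))
    return(list(F_stat = 0, df_num = 0L, df_den = full$n - full$p,
                p_value = 1))
  if (type == "lrt") {
    stat <- max(0, 2 * (full$loglik_ml - reduced$loglik_ml))
    df <- length(extra)
    return(list(chisq = stat, df = df,
                p_value = stats::pchisq(stat, df, lower.tail = FALSE)))
  }
  L <- matrix(0, length(extra), full$p,
              dimnames = list(extra, names(full$beta)))
  L[cbind(seq_along(extra), match(extra, names(full$beta)))] <- 1
  .waldFTest(full, L)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values, order-preserving with the input.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
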