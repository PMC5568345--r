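## Sparse partial least squares in regression mode: probes predict phenotypic
## variables.  Per component the dominant singular pair of X'Y is computed by
## alternating iteration with the X-weight soft-thresholded so exactly keepX
## entries survive; scores t = X w; both X and Y are deflated on t
## (regression mode).  Q2 = 1 - PRESS/RSS with fold-held-out PRESS decides how
## many components carry predictive signal (retention rule Q2 > 0.09).

.standardize <- function(M, center = NULL, scale = NULL) {
  M <- as.matrix(M)
  if (is.null(center)) center <- colMeans(M, na.rm = TRUE)
  if (is.null(scale)) {
    scale <- apply(M, 2, stats::sd, na.rm = TRUE)
  }
  if (any(!is.finite(scale)) || any(scale < 1e-12)) {
    bad <- colnames(M)[!is.finite(scale) | scale < 1e-12]
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  S <- sweep(sweep(M, 2, center, "-"), 2, scale, "/")
  attr(S, "center") <- center
  attr(S, "scale") <- scale
  S
}

# keep exactly k largest |v| entries, soft-shrunk by the (k+1)-th magnitude
.softThreshold <- function(v, k) {
  if (k >= length(v)) return(v)
  av <- abs(v)
  thr <- sort(av, decreasing = TRUE)[k + 1]
  out <- sign(v) * pmax(av - thr, 0)
  # ties at the threshold could keep fewer than k; break by magnitude order
  if (sum(out != 0) < k) {
    idx <- order(av, decreasing = TRUE)[seq_len(k)]
    out <- numeric(length(v))
    out[idx] <- sign(v[idx]) * (av[idx] - thr)
    out[idx][out[idx] == 0] <- sign(v[idx][out[idx] == 0]) * 1e-12
  }
  out
}

#' Sparse PLS fit (SPLSFit objects)
#'
#' @slot weights p x H matrix of sparse X-weights (unit norm).
#' @slot xLoadings,yLoadings regression loadings used for deflation.
#' @slot yWeights q x H matrix of Y-weights (unit norm).
#' @slot variates n x H latent score matrix (zero-mean columns).
#' @slot keepX integer vector, probes retained per component.
#' @slot xCenter,xScale,yCenter,yScale standardization parameters.
#' @slot q2 per-component Q2 (filled by \code{\link{q2CrossVal}}; NA before).
#' @export
setClass("SPLSFit", slots = c(
  weights = "matrix", xLoadings = "matrix", yLoadings = "matrix",
  yWeights = "matrix", variates = "matrix", keepX = "integer",
  xCenter = "numeric", xScale = "numeric",
  yCenter = "numeric", yScale = "numeric", q2 = "numeric"))

setValidity("SPLSFit", function(object) {
  H <- ncol(object@weights)
  nz <- colSums(object@weights != 0)
  if (length(object@keepX) != H) return("keepX length != n_components")
  if (any(nz > object@keepX)) return("more nonzero weights than keepX")
  if (max(abs(colMeans(object@variates))) > 1e-8)
    return("variates are not zero-mean")
  TRUE
})

#' @describeIn SPLSFit show method
#' @param object an SPLSFit
#' @export
setMethod("show", "SPLSFit", function(object) {
  cat("SPLSFit:", ncol(object@weights), "component(s),",
      nrow(object@weights), "probes ->", nrow(object@yLoadings),
      "phenotypes\n")
  cat("  keepX:", paste(object@keepX, collapse = ", "), "\n")
  if (any(is.finite(object@q2)))
    cat("  Q2:", paste(round(object@q2, 3), collapse = ", "), "\n")
  invisible(NULL)
})

#' Fit a sparse PLS regression of phenotypes on probes
#'
#' X and Y are centered and unit-scaled internally.  Per component the
#' dominant singular pair of the deflated cross-covariance is computed by
#' alternating iteration; the X-weight is soft-thresholded so exactly
#' \code{keepX[h]} probes survive, then renormalized.  Scores are
#' \code{t = X w}; X and Y are both regressed out on t (regression-mode
#' deflation).  Missing Y entries are treated as zero after standardization
#' (mean imputation) for the fit; downstream diagnostics exclude them.
#'
#' @param X samples x probes matrix.
#' @param Y samples x phenotypes matrix (NA allowed).
#' @param n_components number of latent components.
#' @param keepX probes to retain per component (recycled to
#'   \code{n_components}).
#' @return an \linkS4class{SPLSFit}.
#' @examples
#' d <- generateDesign(4, 4, seed = 1)
#' sim <- simulateExpression(d, 50, seed = 1)
#' sim <- simulatePhenotypes(sim, 3, n_drivers = 5, noise_sd = 0.5, seed = 1)
#' f <- splsFit(t(exprMatrix(sim)), phenotypes(sim), 2, keepX = 10)
#' f
#' @export
splsFit <- function(X, Y, n_components = 1, keepX = ncol(X)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same samples")
  if (nrow(X) < 3) stop("need at least 3 samples")
  keepX <- as.integer(rep_len(keepX, n_components))
  if (any(keepX < 1 | keepX > ncol(X)))
    stop("keepX must lie in [1, ncol(X)]")
  Xs <- .standardize(X)
  Ys <- .standardize(Y)
  Yw <- Ys; Yw[is.na(Yw)] <- 0
  n <- nrow(Xs); p <- ncol(Xs); q <- ncol(Ys)
  W <- matrix(0, p, n_components,
              dimnames = list(colnames(X), NULL))
  V <- matrix(0, q, n_components, dimnames = list(colnames(Y), NULL))
  P <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  D <- matrix(0, q, n_components, dimnames = list(colnames(Y), NULL))
  Tm <- matrix(0, n, n_components, dimnames = list(rownames(X), NULL))
  Xh <- Xs; Yh <- Yw
  for (h in seq_len(n_components)) {
    M <- crossprod(Xh, Yh)
    sv <- svd(M, nu = 1, nv = 1)
    v <- drop(sv$v)
    u <- numeric(p)
    for (it in seq_len(200)) {
      u_new <- .softThreshold(drop(M %*% v), keepX[h])
      nu_ <- sqrt(sum(u_new^2))
      if (nu_ < 1e-300) break
      u_new <- u_new / nu_
      v_new <- drop(crossprod(M, u_new))
      v_new <- v_new / sqrt(sum(v_new^2))
      if (max(abs(u_new - u)) < 1e-12) { u <- u_new; v <- v_new; break }
      u <- u_new; v <- v_new
    }
    tt <- drop(Xh %*% u)
    t2 <- sum(tt^2)
    if (t2 < 1e-300) stop("degenerate component ", h, ": zero score variance")
    ph <- drop(crossprod(Xh, tt)) / t2
    dh <- drop(crossprod(Yh, tt)) / t2
    W[, h] <- u; V[, h] <- v; P[, h] <- ph; D[, h] <- dh; Tm[, h] <- tt
    Xh <- Xh - tcrossprod(tt, ph)
    Yh <- Yh - tcrossprod(tt, dh)
  }
  new("SPLSFit", weights = W, xLoadings = P, yLoadings = D, yWeights = V,
      variates = Tm, keepX = keepX,
      xCenter = attr(Xs, "center"), xScale = attr(Xs, "scale"),
      yCenter = attr(Ys, "center"), yScale = attr(Ys, "scale"),
      q2 = rep(NA_real_, n_components))
}

#' Probes selected on given components
#' @param fit an \linkS4class{SPLSFit}.
#' @param components component indices (default: all).
#' @return character vector of probe names with nonzero weight.
#' @export
selectedProbes <- function(fit, components = seq_len(ncol(fit@weights))) {
  rownames(fit@weights)[rowSums(fit@weights[, components, drop = FALSE] != 0) > 0]
}

# cumulative prediction of standardized Y from the first h components
.splsPredict <- function(fit, Xnew, h = ncol(fit@weights)) {
  Xs <- sweep(sweep(as.matrix(Xnew), 2, fit@xCenter, "-"), 2, fit@xScale, "/")
  W <- fit@weights[, seq_len(h), drop = FALSE]
  P <- fit@xLoadings[, seq_len(h), drop = FALSE]
  D <- fit@yLoadings[, seq_len(h), drop = FALSE]
  Wstar <- W %*% solve(crossprod(P, W))
  Xs %*% (Wstar %*% t(D))
}

.makeFolds <- function(n, n_folds, seed, strata = NULL) {
  if (n_folds < 2 || n_folds > n) stop("n_folds must lie in [2, n]")
  .withSeed(seed, {
    fold <- integer(n)
    if (is.null(strata)) strata <- rep(1L, n)
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    # balance: make sure every fold is non-empty
    if (length(unique(fold)) < n_folds) {
      fold <- rep_len(seq_len(n_folds), n)[sample.int(n)]
    }
    fold
  })
}

#' Cross-validated Q2 per sPLS component
#'
#' \code{Q2_h = 1 - PRESS_h / RSS_{h-1}}: PRESS pools, over folds and all
#' phenotype columns, the squared held-out prediction error of a model with
#' h components; RSS is the residual sum of squares of the full-data model
#' after h-1 components (RSS_0 = total sum of squares of standardized Y).
#' Components are conventionally retained while Q2 exceeds 0.09.
#'
#' @inheritParams splsFit
#' @param n_folds number of cross-validation folds.
#' @param seed fold-assignment seed.
#' @param strata optional factor for stratified folds (e.g. age x genotype).
#' @return numeric vector of Q2 values, one per component.
#' @export
q2CrossVal <- function(X, Y, n_components = 1, keepX = ncol(X),
                       n_folds = 5, seed = 1L, strata = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  fold <- .makeFolds(n, n_folds, seed, strata)
  full <- splsFit(X, Y, n_components, keepX)
  Ys <- .standardize(Y)
  obs_ok <- !is.na(Ys)
  press <- numeric(n_components)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    if (!any(test) || sum(!test) < 3) stop("fold with too few samples")
    ft <- splsFit(X[!test, , drop = FALSE], Y[!test, , drop = FALSE],
                  n_components, keepX)
    # predictions on the global standardized scale of Y
    for (h in seq_len(n_components)) {
      pred <- .splsPredict(ft, X[test, , drop = FALSE], h)
      pred <- sweep(sweep(pred, 2, ft@yScale, "*"), 2, ft@yCenter, "+")
      pred <- sweep(sweep(pred, 2, attr(Ys, "center"), "-"), 2,
                    attr(Ys, "scale"), "/")
      err <- (Ys[test, , drop = FALSE] - pred)^2
      press[h] <- press[h] + sum(err[obs_ok[test, , drop = FALSE]])
    }
  }
  rss_prev <- sum(Ys[obs_ok]^2)
  q2 <- numeric(n_components)
  for (h in seq_len(n_components)) {
    q2[h] <- 1 - press[h] / rss_prev
    resid_h <- Ys - .splsPredict(full, X, h)
    rss_prev <- sum(resid_h[obs_ok]^2)
  }
  q2
}

#' Cross-validated MSEP and R2 per phenotype
#'
#' Mean squared error of prediction on the standardized phenotype scale and
#' the squared Pearson correlation between held-out predictions and
#' observations, per phenotype column; the MSEP ranking identifies the best
#' predicted variables.
#'
#' @inheritParams q2CrossVal
#' @param fit an \linkS4class{SPLSFit} defining n_components and keepX.
#' @return data.frame(phenotype, msep, r2), ordered as in Y.
#' @export
msepR2 <- function(X, Y, fit, n_folds = 5, seed = 1L, strata = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  H <- ncol(fit@weights)
  n <- nrow(X)
  fold <- .makeFolds(n, n_folds, seed, strata)
  Ys <- .standardize(Y)
  pred <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Ys))
  for (f in sort(unique(fold))) {
    test <- fold == f
    ft <- splsFit(X[!test, , drop = FALSE], Y[!test, , drop = FALSE],
                  H, fit@keepX)
    pr <- .splsPredict(ft, X[test, , drop = FALSE], H)
    pr <- sweep(sweep(pr, 2, ft@yScale, "*"), 2, ft@yCenter, "+")
    pred[test, ] <- sweep(sweep(pr, 2, attr(Ys, "center"), "-"), 2,
                          attr(Ys, "scale"), "/")
  }
  msep <- colMeans((Ys - pred)^2, na.rm = TRUE)
  r2 <- vapply(seq_len(ncol(Y)), function(k) {
    ok <- !is.na(Ys[, k]) & !is.na(pred[, k])
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(Ys[ok, k], pred[ok, k])^2
  }, numeric(1))
  data.frame(phenotype = colnames(Y), msep = unname(msep), r2 = unname(r2),
             stringsAsFactors = FALSE)
}

#' Tune keepX over a ladder by Q2
#'
#' Evaluates \code{q2CrossVal} for each candidate keepX (applied to every
#' component) and returns the candidate maximizing the first-component Q2.
#'
#' @inheritParams q2CrossVal
#' @param keepX_grid candidate probe counts (default ladder 10, 25, 50, 100,
#'   250, clipped to ncol(X)).
#' @return list(keepX, q2_grid) where q2_grid has one row per candidate.
#' @export
tuneKeepX <- function(X, Y, n_components = 1,
                      keepX_grid = c(10, 25, 50, 100, 250),
                      n_folds = 5, seed = 1L, strata = NULL) {
  keepX_grid <- unique(pmin(keepX_grid, ncol(X)))
  rows <- lapply(keepX_grid, function(k)
    q2CrossVal(X, Y, n_components, k, n_folds, seed, strata))
  q2g <- do.call(rbind, rows)
  rownames(q2g) <- keepX_grid
  best <- keepX_grid[which.max(q2g[, 1])]
  list(keepX = best, q2_grid = q2g)
}
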