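## BIC assignment of each differential probe to one of four fixed-effect
## sub-models: complete (age + genotype + interaction), additive, age-only,
## genotype-only.  All candidates keep the random sow term and are fitted by
## ML, since REML likelihoods are not comparable across fixed-effect
## structures; k counts the fixed coefficients plus both variance components,
## so penalty differences reflect fixed effects only.

SUBMODEL_FORMULAS <- list(
  complete = ~ gestational_age * fetal_genotype,
  additive = ~ gestational_age + fetal_genotype,
  age      = ~ gestational_age,
  genotype = ~ fetal_genotype)

# tie-break preference: fewer fixed-effect parameters first
SUBMODEL_TIE_ORDER <- c("age", "genotype", "additive", "complete")

#' Bayesian Information Criterion of a mixed-model fit
#'
#' \code{BIC = -2 loglik_ML + k log(n_obs)} with \code{k} = number of fixed
#' effect coefficients + 2 variance components.
#'
#' @param fit a \code{probe_fit} carrying an ML log-likelihood.
#' @param n_obs number of observations used in the fit.
#' @return the BIC value.
#' @examples
#' d <- generateDesign(3, 3, seed = 1)
#' sim <- simulateExpression(d, 1, c(1, 0, 0, 0, 0), seed = 1)
#' f <- fitProbeMixedModel(exprMatrix(sim)[1, ], d, criterion = "ML")
#' bicOfFit(f, ncol(sim))
#' @export
bicOfFit <- function(fit, n_obs) {
  if (is.null(fit$loglik_ml) || !is.finite(fit$loglik_ml))
    stop("fit does not carry a finite ML log-likelihood")
  k <- fit$p + 2
  if (n_obs < k)
    stop("n_obs (", n_obs, ") smaller than the parameter count (", k, ")")
  -2 * fit$loglik_ml + k * log(n_obs)
}

.submodelContexts <- function(design) {
  # the rotation depends only on the sow blocks, so share Q and d
  base <- .mmContext(design, SUBMODEL_FORMULAS$complete)
  ctxs <- list(complete = base)
  for (nm in c("additive", "age", "genotype")) {
    X <- stats::model.matrix(SUBMODEL_FORMULAS[[nm]], base$factors)
    ctxs[[nm]] <- modifyList(base, list(X = X, Xt = crossprod(base$Q, X),
                                        p = ncol(X), coef_names = colnames(X),
                                        fixed = SUBMODEL_FORMULAS[[nm]]))
  }
  ctxs
}

.classifyRotated <- function(yt, ctxs, tol = 1e-10) {
  n <- length(yt)
  bic <- vapply(ctxs, function(ctx) {
    raw <- .fit_vc_cpp(ctx$Xt, yt, ctx$d, FALSE, tol)
    -2 * raw$loglik_ml + (ctx$p + 2) * log(n)
  }, numeric(1))
  b <- bic[SUBMODEL_TIE_ORDER]
  chosen <- SUBMODEL_TIE_ORDER[which.min(b)]  # first minimum = fewest params
  margin <- diff(sort(b))[1]
  list(bic = bic, chosen = chosen, margin = unname(margin))
}

#' Assign a probe to its best sub-model by BIC
#'
#' Fits the four candidate fixed-effect structures (each retaining the random
#' sow intercept) by ML and returns the minimum-BIC label; exact ties break
#' toward the structure with fewer fixed-effect parameters
#' (age < genotype < additive < complete).
#'
#' @param y expression values, one per design row.
#' @param design design data.frame.
#' @return list with the four BIC values (\code{bic_complete},
#'   \code{bic_additive}, \code{bic_age}, \code{bic_genotype}),
#'   \code{chosen}, and \code{margin} (BIC gap to the runner-up).
#' @examples
#' d <- generateDesign(4, 4, seed = 1)
#' sim <- simulateExpression(d, 1, c(0, 0, 0, 1, 0), effect_size = 1.5,
#'                           seed = 2)
#' classifyProbe(exprMatrix(sim)[1, ], d)$chosen
#' @export
classifyProbe <- function(y, design) {
  ctxs <- if (is.list(design) && !is.null(design$complete)) design
          else .submodelContexts(design)
  yt <- drop(crossprod(ctxs$complete$Q, y))
  r <- .classifyRotated(yt, ctxs)
  list(bic_complete = unname(r$bic["complete"]),
       bic_additive = unname(r$bic["additive"]),
       bic_age = unname(r$bic["age"]),
       bic_genotype = unname(r$bic["genotype"]),
       chosen = r$chosen, margin = r$margin)
}

#' Classify every DEP into the four sub-models
#'
#' @param deps data.frame with a \code{probe_id} column (typically
#'   \code{runDEScan(...)$deps}).
#' @param x a \linkS4class{MaturityExperiment} or probes x samples matrix.
#' @param design design data.frame (ignored for a MaturityExperiment).
#' @return list with \code{labels} (per-probe BICs, chosen label, margin)
#'   and \code{summary} (counts and percentages per sub-model).
#' @examples
#' d <- generateDesign(4, 4, seed = 1)
#' sim <- simulateExpression(d, 40, c(0.4, 0.2, 0.2, 0.1, 0.1),
#'                           effect_size = 2, seed = 1)
#' scan <- runDEScan(sim)
#' classifyAll(scan$deps, sim)$summary
#' @export
classifyAll <- function(deps, x, design = NULL) {
  xd <- .exprAndDesign(x, design)
  empty <- data.frame(probe_id = character(), bic_complete = numeric(),
                      bic_additive = numeric(), bic_age = numeric(),
                      bic_genotype = numeric(), chosen = character(),
                      margin = numeric(), stringsAsFactors = FALSE)
  summary0 <- data.frame(submodel = names(SUBMODEL_FORMULAS),
                         count = 0L, percent = 0, stringsAsFactors = FALSE)
  if (is.null(deps) || nrow(deps) == 0)
    return(list(labels = empty, summary = summary0))
  ids <- deps$probe_id
  miss <- setdiff(ids, rownames(xd$expr))
  if (length(miss))
    stop("DEP probe(s) absent from expression: ", paste(miss, collapse = ", "))
  ctxs <- .submodelContexts(xd$design)
  Yt <- xd$expr[ids, , drop = FALSE] %*% ctxs$complete$Q
  rows <- lapply(seq_along(ids), function(j) {
    r <- .classifyRotated(Yt[j, ], ctxs)
    data.frame(probe_id = ids[j],
               bic_complete = unname(r$bic["complete"]),
               bic_additive = unname(r$bic["additive"]),
               bic_age = unname(r$bic["age"]),
               bic_genotype = unname(r$bic["genotype"]),
               chosen = r$chosen, margin = r$margin,
               stringsAsFactors = FALSE)
  })
  labels <- do.call(rbind, rows)
  counts <- table(factor(labels$chosen, names(SUBMODEL_FORMULAS)))
  summ <- data.frame(submodel = names(counts),
                     count = as.integer(counts),
                     percent = 100 * as.integer(counts) / nrow(labels),
                     stringsAsFactors = FALSE)
  list(labels = labels, summary = summ)
}
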