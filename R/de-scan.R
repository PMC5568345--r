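## Genome-wide scans: full-vs-reduced F-type test per probe with BH-FDR, and
## the parental-genome reparameterization separating maternal from paternal
## effects.  The rotation Q is shared across probes, so the per-probe work is
## a 1-d variance optimization plus the Satterthwaite step.

.selectionMatrix <- function(coef_full, tested) {
  L <- matrix(0, length(tested), length(coef_full),
              dimnames = list(tested, coef_full))
  L[cbind(seq_along(tested), match(tested, coef_full))] <- 1
  L
}

# scan all probe rows with one fixed-effect formula; returns per-probe stats
# for the contrasts listed in `tested` (list of coefficient-name vectors)
.scanProbes <- function(expr, ctx, tested, tol = 1e-10) {
  Yt <- expr %*% ctx$Q
  m <- nrow(expr)
  Ls <- lapply(tested, .selectionMatrix, coef_full = ctx$coef_names)
  out <- lapply(Ls, function(L)
    data.frame(F_stat = rep(NA_real_, m), df_num = NA_real_,
               df_den = NA_real_, p_value = NA_real_))
  fits <- vector("list", m)
  rejects <- character(0)
  for (j in seq_len(m)) {
    yt <- Yt[j, ]
    if (stats::var(expr[j, ]) < 1e-12) {
      # constant probe: F undefined, recorded as non-significant
      for (k in seq_along(Ls)) {
        out[[k]]$F_stat[j] <- 0
        out[[k]]$df_num[j] <- nrow(Ls[[k]])
        out[[k]]$df_den[j] <- ctx$n - ctx$p
        out[[k]]$p_value[j] <- 1
      }
      rejects <- c(rejects, rownames(expr)[j])
      fits[[j]] <- NULL
      next
    }
    raw <- .fit_vc_cpp(ctx$Xt, yt, ctx$d, TRUE, tol)
    fit <- .asProbeFit(raw, ctx, yt, rownames(expr)[j])
    fits[[j]] <- fit
    for (k in seq_along(Ls)) {
      w <- .waldFTest(fit, Ls[[k]])
      out[[k]]$F_stat[j] <- w$F_stat
      out[[k]]$df_num[j] <- w$df_num
      out[[k]]$df_den[j] <- w$df_den
      out[[k]]$p_value[j] <- w$p_value
    }
  }
  list(tests = out, fits = fits, rejects = rejects)
}

.exprAndDesign <- function(x, design) {
  if (is(x, "MaturityExperiment")) list(expr = exprMatrix(x),
                                        design = designTable(x))
  else list(expr = as.matrix(x), design = .checkDesign(design))
}

#' Genome-wide differential expression scan
#'
#' Fits, for every probe, the full mixed model (gestational age + fetal
#' genotype + interaction, sow random) and tests all fixed-effect contrasts
#' jointly against the intercept-plus-sow reduced model with the F-type test;
#' p-values are BH-adjusted across probes and probes below \code{alpha_fdr}
#' are reported as differentially expressed (DEPs), together with the modeled
#' day110 - day90 log2 fold change within each fetal genotype.
#'
#' @param x a \linkS4class{MaturityExperiment}, or a probes x samples matrix.
#' @param design design data.frame (ignored when \code{x} is a
#'   MaturityExperiment).
#' @param alpha_fdr FDR threshold for calling DEPs (study threshold: 0.01).
#' @return list with \code{deps} (data.frame of significant probes: F, df,
#'   p, fdr_p, per-genotype log2FC), \code{table} (the same columns for all
#'   probes), and \code{rejects} (probe ids excluded as constant).
#' @examples
#' d <- generateDesign(4, 4, seed = 1)
#' sim <- simulateExpression(d, 40, c(0.5, 0.125, 0.125, 0.125, 0.125),
#'                           effect_size = 2, seed = 1)
#' scan <- runDEScan(sim)
#' head(scan$deps)
#' @export
runDEScan <- function(x, design = NULL, alpha_fdr = 0.01) {
  if (alpha_fdr < 0 || alpha_fdr > 1) stop("alpha_fdr must be in [0, 1]")
  xd <- .exprAndDesign(x, design)
  ctx <- .mmContext(xd$design, ~ gestational_age * fetal_genotype)
  tested <- list(all_fixed = setdiff(ctx$coef_names, "(Intercept)"))
  scan <- .scanProbes(xd$expr, ctx, tested)
  tab <- scan$tests[[1]]
  tab <- data.frame(probe_id = rownames(xd$expr), tab,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab$fdr_p <- bhAdjust(tab$p_value)

  # modeled day110 - day90 contrast per genotype: beta_age (+ interaction)
  lfc <- matrix(NA_real_, nrow(tab), 4,
                dimnames = list(NULL, paste0("log2fc_", GENOTYPE_LEVELS)))
  a_name <- "gestational_age110"
  for (j in seq_len(nrow(tab))) {
    f <- scan$fits[[j]]
    if (is.null(f)) { lfc[j, ] <- 0; next }
    b <- f$beta
    lfc[j, 1] <- b[a_name]
    for (k in 2:4) {
      int_name <- paste0(a_name, ":fetal_genotype", GENOTYPE_LEVELS[k])
      lfc[j, k] <- b[a_name] + b[int_name]
    }
  }
  tab <- cbind(tab, lfc)
  deps <- tab[tab$fdr_p < alpha_fdr, , drop = FALSE]
  rownames(deps) <- NULL
  list(deps = deps, table = tab, rejects = scan$rejects,
       alpha_fdr = alpha_fdr)
}

#' Parental-genome scan (maternal vs paternal effects)
#'
#' Reparameterizes the factorial as maternal genotype + paternal genotype +
#' gestational age with all pairwise interactions (sow random; the
#' maternal-by-paternal term spans the fourth fetal-genotype contrast) and
#' runs separate F-type tests for the paternal term set (paternal and its
#' interactions) and the maternal term set, each BH-adjusted across probes.
#'
#' @inheritParams runDEScan
#' @param alpha_fdr FDR threshold (study threshold for this model: 0.05).
#' @return list with \code{maternal} and \code{paternal} data.frames (per
#'   probe F, df, p, fdr_p and the significant subset flag \code{signif}),
#'   plus \code{rejects}.
#' @export
fitParentalModel <- function(x, design = NULL, alpha_fdr = 0.05) {
  xd <- .exprAndDesign(x, design)
  d <- xd$design
  tab <- table(d$maternal_genotype, d$paternal_genotype)
  if (any(tab == 0) || nrow(tab) < 2 || ncol(tab) < 2)
    stop("parental model needs both paternal genotypes within each maternal genotype")
  fixed <- ~ maternal_genotype * paternal_genotype +
    maternal_genotype * gestational_age + paternal_genotype * gestational_age
  ctx <- .mmContext(d, fixed)
  cn <- ctx$coef_names
  pat <- grep("paternal_genotype", cn, value = TRUE)
  mat <- grep("maternal_genotype", cn, value = TRUE)
  scan <- .scanProbes(xd$expr, ctx, list(maternal = mat, paternal = pat))
  mk <- function(df) {
    df <- data.frame(probe_id = rownames(xd$expr), df,
                     stringsAsFactors = FALSE, row.names = NULL)
    df$fdr_p <- bhAdjust(df$p_value)
    df$signif <- df$fdr_p < alpha_fdr
    df
  }
  list(maternal = mk(scan$tests$maternal), paternal = mk(scan$tests$paternal),
       rejects = scan$rejects, alpha_fdr = alpha_fdr)
}
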