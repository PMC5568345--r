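## Hypergeometric over-representation of gene lists against user-supplied
## annotation sets (GMT), with the fold-change gate applied upstream.

#' Gate DEPs by absolute log2 fold change
#'
#' Keeps probes whose |log2FC| within the queried genotype meets the
#' threshold (study gate: 0.5, i.e. absolute fold change 1.4) and records
#' the direction of change at day 110 versus day 90.
#'
#' @param deps data.frame with per-genotype \code{log2fc_*} columns
#'   (from \code{\link{runDEScan}}).
#' @param min_abs_log2fc threshold on |log2FC|.
#' @param genotype which genotype's fold change to gate on.
#' @return the gated data.frame with an added \code{direction} column
#'   ("up"/"down" at day 110).
#' @export
gateByFoldChange <- function(deps, min_abs_log2fc = 0.5, genotype = "LW") {
  col <- paste0("log2fc_", genotype)
  if (!col %in% colnames(deps)) stop("missing fold-change column ", col)
  lfc <- deps[[col]]
  keep <- !is.na(lfc) & abs(lfc) >= min_abs_log2fc
  out <- deps[keep, , drop = FALSE]
  out$direction <- ifelse(out[[col]] >= 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation of a gene set
#'
#' Upper-tail hypergeometric probability \eqn{P[X \ge k]} per annotation
#' term, where k genes of the n-gene query fall in a term of size K within
#' the N-gene universe; BH-adjusted across terms.
#'
#' @param query character vector of query genes (must be contained in the
#'   universe).
#' @param sets named list of term gene vectors (e.g. \code{\link{readGMT}}).
#' @param universe character vector of all considered genes.
#' @param alpha_fdr FDR threshold flagging enriched terms (study: 0.01).
#' @return data.frame(term, k, K, n, N, p_value, fdr_p, enriched), ordered
#'   by p-value.
#' @examples
#' sets <- list(t1 = c("a", "b", "c"), t2 = c("d", "e"))
#' hypergeomEnrich(c("a", "b"), sets, letters[1:10])
#' @export
hypergeomEnrich <- function(query, sets, universe, alpha_fdr = 0.01) {
  query <- unique(query)
  universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad))
    stop("query gene(s) absent from universe: ", paste(bad, collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(term) {
    set_u <- intersect(sets[[term]], universe)
    K <- length(set_u)
    k <- length(intersect(set_u, query))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_p <- bhAdjust(out$p_value)
  out$enriched <- out$fdr_p < alpha_fdr
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
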