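## qPCR validation statistics: calibrator-relative quantities, geNorm
## reference-gene stability, normalization to the stable references, and
## Pearson correlation of qPCR against microarray expression.

.checkQPCR <- function(cq, efficiency) {
  cq <- as.matrix(cq)
  if (is.null(rownames(cq))) stop("Cq matrix needs gene rownames")
  if (any(!is.na(cq) & cq <= 0)) stop("Cq values must be positive")
  if (is.null(names(efficiency))) names(efficiency) <- rownames(cq)
  miss <- setdiff(rownames(cq), names(efficiency))
  if (length(miss))
    stop("no efficiency for gene(s): ", paste(miss, collapse = ", "))
  eff <- efficiency[rownames(cq)]
  if (any(eff <= 0.5 | eff >= 1.5))
    stop("amplification efficiencies must lie in (0.5, 1.5)")
  list(cq = cq, efficiency = eff)
}

#' Calibrator-relative qPCR quantities
#'
#' Converts quantification cycles to relative quantities with the highest
#' expressed sample (lowest Cq) of each gene as calibrator:
#' \eqn{Q = (1 + E)^{Cq_{min} - Cq}}, so the calibrator has Q = 1 and all
#' quantities lie in (0, 1].  Missing Cq propagates to a missing quantity.
#'
#' @param cq genes x samples matrix of quantification cycles.
#' @param efficiency named per-gene amplification efficiencies (1 = perfect
#'   doubling chemistry).
#' @return genes x samples matrix of relative quantities.
#' @examples
#' cq <- rbind(g1 = c(20, 21, 23))
#' relativeQuantities(cq, c(g1 = 1))   # 1, 0.5, 0.125
#' @export
relativeQuantities <- function(cq, efficiency) {
  v <- .checkQPCR(cq, efficiency)
  out <- v$cq
  for (g in rownames(out)) {
    cqmin <- min(out[g, ], na.rm = TRUE)
    out[g, ] <- (1 + v$efficiency[g])^(cqmin - out[g, ])
  }
  out
}

#' geNorm stability ranking of candidate reference genes
#'
#' The stability measure of gene j is the mean, over all other candidates k,
#' of the standard deviation across samples of log2(Q_j / Q_k); lower M =
#' more stable.  The least stable gene is excluded iteratively until two
#' remain.
#'
#' @param quantities candidates x samples matrix of relative quantities
#'   (strictly positive).
#' @return list with \code{m_values} (data.frame gene, M of the full
#'   candidate set, ranked ascending), \code{exclusion_order} and
#'   \code{selected} (the final stable pair).
#' @export
geNormM <- function(quantities) {
  q <- as.matrix(quantities)
  if (nrow(q) < 3) stop("geNorm needs >= 3 candidate genes")
  if (ncol(q) < 2) stop("geNorm needs >= 2 samples")
  if (any(is.na(q)) || any(q <= 0))
    stop("quantities must be positive and complete")
  mOf <- function(mat) {
    vapply(seq_len(nrow(mat)), function(j) {
      others <- setdiff(seq_len(nrow(mat)), j)
      mean(vapply(others, function(k)
        stats::sd(log2(mat[j, ] / mat[k, ])), numeric(1)))
    }, numeric(1))
  }
  m_full <- mOf(q)
  mv <- data.frame(gene = rownames(q), M = m_full, stringsAsFactors = FALSE)
  mv <- mv[order(mv$M), , drop = FALSE]
  mv$rank <- seq_len(nrow(mv))
  rownames(mv) <- NULL
  cur <- q
  excluded <- character(0)
  while (nrow(cur) > 2) {
    m <- mOf(cur)
    worst <- which.max(m)
    excluded <- c(excluded, rownames(cur)[worst])
    cur <- cur[-worst, , drop = FALSE]
  }
  list(m_values = mv, exclusion_order = excluded,
       selected = rownames(cur))
}

#' Normalize target quantities to reference genes
#'
#' Divides each target's quantity by the per-sample geometric mean of the
#' selected reference genes' quantities.
#'
#' @param target_q targets x samples quantity matrix.
#' @param reference_q references x samples quantity matrix (>= 1 row).
#' @return normalized targets x samples matrix.
#' @export
normalizeTargets <- function(target_q, reference_q) {
  target_q <- as.matrix(target_q)
  reference_q <- as.matrix(reference_q)
  if (nrow(reference_q) < 1) stop("need at least one reference gene")
  if (any(is.na(reference_q)) || any(reference_q <= 0))
    stop("reference quantities must be positive and complete")
  gm <- exp(colMeans(log(reference_q)))
  sweep(target_q, 2, gm, "/")
}

#' Correlate qPCR expression with microarray rows
#'
#' Pearson correlation, per gene, between log2 normalized qPCR expression
#' and the log2 microarray row, matched by sample id; p-values from the t
#' distribution.  Genes with fewer than 3 complete pairs are skipped with a
#' warning.
#'
#' @param qpcr_norm genes x samples normalized qPCR quantities (positive).
#' @param array_rows probes x samples log2 expression.
#' @param gene_map named character vector mapping qPCR gene -> array probe
#'   id; defaults to identical names.
#' @return data.frame(gene, probe, n, r, p).
#' @export
validateAgainstArray <- function(qpcr_norm, array_rows, gene_map = NULL) {
  qpcr_norm <- as.matrix(qpcr_norm)
  array_rows <- as.matrix(array_rows)
  if (is.null(gene_map))
    gene_map <- stats::setNames(rownames(qpcr_norm), rownames(qpcr_norm))
  common <- intersect(colnames(qpcr_norm), colnames(array_rows))
  rows <- list()
  for (g in names(gene_map)) {
    probe <- gene_map[[g]]
    if (!g %in% rownames(qpcr_norm) || !probe %in% rownames(array_rows))
      next
    xq <- log2(qpcr_norm[g, common])
    xa <- array_rows[probe, common]
    ok <- is.finite(xq) & is.finite(xa)
    if (sum(ok) < 3) {
      warning("gene ", g, " skipped: fewer than 3 paired samples")
      next
    }
    ct <- stats::cor.test(xq[ok], xa[ok], method = "pearson")
    rows[[g]] <- data.frame(gene = g, probe = probe, n = sum(ok),
                            r = unname(ct$estimate), p = ct$p.value,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene = character(), probe = character(),
                      n = integer(), r = numeric(), p = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
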