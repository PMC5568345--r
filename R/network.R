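## PCA summaries of probe subsets and the probe-phenotype relevance network
## built from sPLS latent variates.

#' PCA summary of a probe subset
#'
#' Samples are observations, probes variables; columns are centered
#' (optionally unit-scaled) and decomposed by SVD.  Variance fractions come
#' from the squared singular values.
#'
#' @param expr_subset probes x samples matrix (e.g. the DEPs of one
#'   sub-model).
#' @param scale unit-scale probes before the decomposition.
#' @return list with \code{var_fraction} (percent, sums to 100),
#'   \code{scores} (samples x components) and \code{loadings}
#'   (probes x components).
#' @examples
#' d <- generateDesign(4, 4, seed = 1)
#' sim <- simulateExpression(d, 20, seed = 1)
#' p <- pcaSummary(exprMatrix(sim))
#' head(p$var_fraction)
#' @export
pcaSummary <- function(expr_subset, scale = FALSE) {
  X <- t(as.matrix(expr_subset))
  if (nrow(X) < 2 || ncol(X) < 2) stop("need >= 2 samples and >= 2 probes")
  sds <- apply(X, 2, stats::sd)
  if (all(sds < 1e-12)) stop("constant matrix: no variance to decompose")
  if (scale) {
    if (any(sds < 1e-12)) stop("cannot unit-scale constant probe(s)")
    X <- sweep(X, 2, sds, "/")
  }
  X <- sweep(X, 2, colMeans(X), "-")
  sv <- svd(X)
  frac <- 100 * sv$d^2 / sum(sv$d^2)
  k <- length(sv$d)
  scores <- sv$u %*% diag(sv$d, k, k)
  rownames(scores) <- rownames(X)
  loadings <- sv$v
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  list(var_fraction = stats::setNames(frac, paste0("PC", seq_len(k))),
       scores = scores, loadings = loadings)
}

#' Probe-phenotype relevance network from an sPLS fit
#'
#' Edge score between probe j and phenotype k over the chosen components:
#' \eqn{\sum_h cor(X_j, t_h) \cdot cor(Y_k, t_h)} — for one component this is
#' the product of the two variate correlations, so scores lie in [-1, 1].
#' Edges with |score| above the cutoff are emitted.  \code{method = "pearson"}
#' substitutes the raw probe-phenotype Pearson correlation for sensitivity
#' checks.
#'
#' @param fit an \linkS4class{SPLSFit}.
#' @param X,Y the matrices the fit was trained on.
#' @param components components to sum over (default: component 1).
#' @param cutoff absolute score threshold in (0, 1) (study value 0.75).
#' @param probes "selected" restricts to probes with nonzero weight on the
#'   chosen components; "all" scores every probe.
#' @param method "variate" (sPLS similarity, default) or "pearson".
#' @return data.frame(probe_id, phenotype, score, component_of_origin).
#' @export
relevanceNetwork <- function(fit, X, Y, components = 1L, cutoff = 0.75,
                             probes = c("selected", "all"),
                             method = c("variate", "pearson")) {
  probes <- match.arg(probes)
  method <- match.arg(method)
  if (!length(components)) stop("component set must be non-empty")
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  keep <- if (probes == "selected") selectedProbes(fit, components)
          else colnames(X)
  if (!length(keep)) return(data.frame(probe_id = character(),
                                       phenotype = character(),
                                       score = numeric(),
                                       component_of_origin = integer()))
  if (method == "pearson") {
    S <- stats::cor(X[, keep, drop = FALSE], Y,
                    use = "pairwise.complete.obs")
    origin <- matrix(NA_integer_, nrow(S), ncol(S))
  } else {
    Tm <- fit@variates[, components, drop = FALSE]
    cx <- stats::cor(X[, keep, drop = FALSE], Tm,
                     use = "pairwise.complete.obs")
    cy <- stats::cor(Y, Tm, use = "pairwise.complete.obs")
    per_comp <- lapply(seq_along(components), function(i)
      tcrossprod(cx[, i], cy[, i]))
    S <- Reduce(`+`, per_comp)
    amax <- array(unlist(per_comp), c(nrow(S), ncol(S), length(components)))
    origin <- components[apply(abs(amax), c(1, 2), which.max)]
    dim(origin) <- dim(S)
  }
  idx <- which(abs(S) > cutoff, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(probe_id = character(),
                                    phenotype = character(),
                                    score = numeric(),
                                    component_of_origin = integer()))
  out <- data.frame(probe_id = keep[idx[, 1]],
                    phenotype = colnames(Y)[idx[, 2]],
                    score = S[idx],
                    component_of_origin = origin[idx],
                    stringsAsFactors = FALSE)
  out[order(-abs(out$score)), , drop = FALSE]
}

#' Write a relevance network as SIF
#'
#' One line per edge: probe, interaction type carrying the score sign
#' ("pos"/"neg"), phenotype.
#'
#' @param edges data.frame from \code{\link{relevanceNetwork}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeNetworkSIF <- function(edges, path) {
  lines <- sprintf("%s\t%s\t%s", edges$probe_id,
                   ifelse(edges$score >= 0, "pos", "neg"), edges$phenotype)
  writeLines(lines, path)
  invisible(path)
}

#' Write a relevance network as GraphML
#'
#' Bipartite probe-phenotype graph with the signed score as an edge attribute
#' and an optional node attribute carrying each probe's sub-model label.
#'
#' @param edges data.frame from \code{\link{relevanceNetwork}}.
#' @param path output file.
#' @param submodel optional named character vector mapping probe ids to
#'   sub-model labels.
#' @return the path, invisibly.
#' @export
writeNetworkGraphML <- function(edges, path, submodel = NULL) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  nodes <- unique(c(edges$probe_id, edges$phenotype))
  type <- ifelse(nodes %in% edges$probe_id, "probe", "phenotype")
  sm <- rep("", length(nodes))
  if (!is.null(submodel)) {
    hit <- match(nodes, names(submodel))
    sm[!is.na(hit)] <- submodel[hit[!is.na(hit)]]
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="type" for="node" attr.name="type" attr.type="string"/>')
  w('  <key id="submodel" for="node" attr.name="submodel" attr.type="string"/>')
  w('  <key id="score" for="edge" attr.name="score" attr.type="double"/>')
  w('  <graph id="relevance" edgedefault="undirected">')
  for (i in seq_along(nodes)) {
    w('    <node id="', esc(nodes[i]), '">')
    w('      <data key="type">', type[i], "</data>")
    if (nzchar(sm[i])) w('      <data key="submodel">', esc(sm[i]), "</data>")
    w("    </node>")
  }
  for (i in seq_len(nrow(edges))) {
    w('    <edge source="', esc(edges$probe_id[i]), '" target="',
      esc(edges$phenotype[i]), '">')
    w('      <data key="score">', format(edges$score[i], digits = 10),
      "</data>")
    w("    </edge>")
  }
  w("  </graph>")
  w("</graphml>")
  invisible(path)
}
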