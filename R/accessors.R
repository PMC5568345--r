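#' Accessors for MaturityExperiment
#'
#' \code{designTable} returns the factorial design as a data.frame;
#' \code{exprMatrix} the log2 expression matrix; \code{phenotypes} the
#' samples x variables phenotype matrix (NULL if none); \code{truthTable}
#' the planted simulation truth (NULL for real data).
#'
#' @param x a \linkS4class{MaturityExperiment}.
#' @return see the individual descriptions.
#' @name MaturityExperiment-accessors
NULL

#' @rdname MaturityExperiment-accessors
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' @rdname MaturityExperiment-accessors
#' @export
setMethod("designTable", "MaturityExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(
    sample_id = rownames(cd),
    sow_id = cd$sow_id,
    maternal_genotype = as.character(cd$maternal_genotype),
    paternal_genotype = as.character(cd$paternal_genotype),
    fetal_genotype = as.character(cd$fetal_genotype),
    gestational_age = as.character(cd$gestational_age),
    stringsAsFactors = FALSE, row.names = NULL)
})

#' @rdname MaturityExperiment-accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname MaturityExperiment-accessors
#' @export
setMethod("exprMatrix", "MaturityExperiment", function(x)
  SummarizedExperiment::assay(x, "log2expr"))

#' @rdname MaturityExperiment-accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname MaturityExperiment-accessors
#' @export
setMethod("phenotypes", "MaturityExperiment", function(x) {
  if (!length(x@phenotypeNames)) return(NULL)
  cd <- SummarizedExperiment::colData(x)
  m <- as.matrix(as.data.frame(cd[, x@phenotypeNames, drop = FALSE]))
  rownames(m) <- rownames(cd)
  m
})

#' @rdname MaturityExperiment-accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname MaturityExperiment-accessors
#' @export
setMethod("truthTable", "MaturityExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (is.null(rd$true_class)) return(NULL)
  as.data.frame(rd)
})
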