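#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @import SummarizedExperiment
NULL

#' maturix: mixed-model differential expression and multivariate integration
#' for factorial fetal transcriptome studies
#'
#' The package implements the statistical workflow for a two-age (day 90 /
#' day 110 of gestation) by four-genotype (LW, MSLW, LWMS, MS) reciprocal-cross
#' fetal design with sows as random blocks: per-probe linear mixed models and
#' an F-type test against a reduced model, FDR control, BIC assignment of
#' differential probes to four fixed-effect sub-models, a parental-genome
#' reparameterization, sparse PLS integration of expression with phenotypic
#' variables, phenotype ANOVA with Box-Cox transformation, qPCR validation
#' statistics (geNorm), and hypergeometric enrichment.  A synthetic-data
#' generator with planted truth supports end-to-end testing.
#'
#' @useDynLib maturix, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @name maturix-package
#' @aliases maturix
#' @keywords internal
"_PACKAGE"

GENOTYPE_LEVELS <- c("LW", "MSLW", "LWMS", "MS")
AGE_LEVELS <- c("90", "110")
BREED_LEVELS <- c("LW", "MS")

#' Fetal genotype implied by a maternal x paternal cross
#'
#' Purebreds keep the shared breed name; crossbreds are named by the sow's
#' breed: a LW sow carries MSLW crossbreds, a MS sow carries LWMS crossbreds.
#'
#' @param maternal,paternal character vectors of breeds ("LW" or "MS").
#' @return character vector of fetal genotypes (LW, MSLW, LWMS or MS).
#' @examples
#' crossGenotype(c("LW", "LW", "MS", "MS"), c("LW", "MS", "LW", "MS"))
#' @export
crossGenotype <- function(maternal, paternal) {
  stopifnot(all(maternal %in% BREED_LEVELS), all(paternal %in% BREED_LEVELS))
  len <- max(length(maternal), length(paternal))
  maternal <- rep_len(as.character(maternal), len)
  paternal <- rep_len(as.character(paternal), len)
  ifelse(maternal == "LW",
         ifelse(paternal == "LW", "LW", "MSLW"),
         ifelse(paternal == "LW", "LWMS", "MS"))
}

#' MaturityExperiment: expression + design + phenotypes container
#'
#' A \linkS4class{SummarizedExperiment} whose assay \code{"log2expr"} holds
#' probes x samples log2 intensities and whose \code{colData} carries the
#' factorial design (sow, maternal/paternal/fetal genotype, gestational age)
#' plus any phenotypic variables.  Validity enforces the reciprocal-cross
#' rules: fetal genotype is the deterministic function of the parental breeds
#' and each sow has exactly one maternal genotype and one gestational age.
#'
#' @slot phenotypeNames character vector naming which colData columns are
#'   phenotypic variables (possibly empty).
#' @export
setClass("MaturityExperiment",
  contains = "SummarizedExperiment",
  slots = c(phenotypeNames = "character"))

.validMaturityExperiment <- function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("sow_id", "maternal_genotype", "paternal_genotype",
            "fetal_genotype", "gestational_age")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("colData lacks columns:", paste(miss, collapse = ", ")))
  mg <- as.character(cd$maternal_genotype)
  pg <- as.character(cd$paternal_genotype)
  fg <- as.character(cd$fetal_genotype)
  if (!all(fg == crossGenotype(mg, pg)))
    msg <- c(msg, "fetal_genotype inconsistent with parental genotypes")
  per_sow <- split(data.frame(mg = mg, age = as.character(cd$gestational_age)),
                   as.character(cd$sow_id))
  bad <- vapply(per_sow, function(s)
    length(unique(s$mg)) > 1L || length(unique(s$age)) > 1L, logical(1))
  if (any(bad))
    msg <- c(msg, paste("sow(s) with multiple maternal genotypes or ages:",
                        paste(names(per_sow)[bad], collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate probe ids")
  bad_ph <- setdiff(object@phenotypeNames, colnames(cd))
  if (length(bad_ph))
    msg <- c(msg, paste("phenotypeNames absent from colData:",
                        paste(bad_ph, collapse = ", ")))
  if (length(msg)) msg else TRUE
}
setValidity("MaturityExperiment", .validMaturityExperiment)

#' Construct a MaturityExperiment
#'
#' @param expr numeric matrix of log2 expression, probes x samples, with
#'   probe rownames and sample colnames.
#' @param design data.frame (or DataFrame) with one row per sample and columns
#'   \code{sample_id}, \code{sow_id}, \code{maternal_genotype},
#'   \code{paternal_genotype}, \code{fetal_genotype}, \code{gestational_age}.
#' @param phenotypes optional numeric matrix or data.frame, samples x
#'   variables; \code{NA} allowed.
#' @param truth optional per-probe truth table (data.frame) from the
#'   simulator; stored in \code{rowData}.
#' @return a \linkS4class{MaturityExperiment}.
#' @examples
#' d <- generateDesign(2, 2, seed = 1)
#' sim <- simulateExpression(d, n_probes = 10, seed = 1)
#' sim
#' @export
MaturityExperiment <- function(expr, design, phenotypes = NULL, truth = NULL) {
  expr <- as.matrix(expr)
  design <- as.data.frame(design)
  if (is.null(design$sample_id)) design$sample_id <- rownames(design)
  if (is.null(colnames(expr)))
    stop("expression matrix must have sample column names")
  ord <- match(colnames(expr), design$sample_id)
  if (anyNA(ord))
    stop("samples missing from design: ",
         paste(setdiff(colnames(expr), design$sample_id), collapse = ", "))
  design <- design[ord, , drop = FALSE]
  cd <- DataFrame(
    sow_id = as.character(design$sow_id),
    maternal_genotype = factor(design$maternal_genotype, BREED_LEVELS),
    paternal_genotype = factor(design$paternal_genotype, BREED_LEVELS),
    fetal_genotype = factor(design$fetal_genotype, GENOTYPE_LEVELS),
    gestational_age = factor(as.character(design$gestational_age), AGE_LEVELS),
    row.names = design$sample_id)
  pn <- character()
  if (!is.null(phenotypes)) {
    ph <- as.matrix(as.data.frame(phenotypes))
    if (is.null(rownames(ph))) rownames(ph) <- colnames(expr)
    ph <- ph[match(rownames(cd), rownames(ph)), , drop = FALSE]
    pn <- colnames(ph)
    for (v in pn) cd[[v]] <- as.numeric(ph[, v])
  }
  rd <- if (is.null(truth)) NULL else DataFrame(truth, row.names = truth$probe_id)
  se <- SummarizedExperiment(
    assays = S4Vectors::SimpleList(log2expr = expr),
    colData = cd,
    rowData = rd)
  new("MaturityExperiment", se, phenotypeNames = pn)
}

#' @describeIn MaturityExperiment show method
#' @param object a MaturityExperiment
#' @export
setMethod("show", "MaturityExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("MaturityExperiment:", nrow(object), "probes x", ncol(object), "samples\n")
  tab <- table(age = cd$gestational_age, genotype = cd$fetal_genotype)
  cat("  sows:", length(unique(cd$sow_id)),
      "| age x genotype cells:", sum(tab > 0), "of", length(tab), "\n")
  if (length(object@phenotypeNames))
    cat("  phenotypes:", length(object@phenotypeNames), "variables\n")
  if (!is.null(SummarizedExperiment::rowData(object)$true_class))
    cat("  planted truth classes:",
        paste(names(table(SummarizedExperiment::rowData(object)$true_class)),
              collapse = "/"), "\n")
  invisible(NULL)
})
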