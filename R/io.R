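## Plain-TSV readers/writers for the pipeline tables and GMT annotation sets.
## Dialect: tab-separated, UTF-8, '.' decimal, no quoting; 'NA' marks missing
## values in phenotype tables only.

.readTSV <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

.writeTSV <- function(df, path) {
  # full 17-digit precision so numeric tables round-trip bit-exactly
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- df[[j]]
      s <- sprintf("%.17g", x)
      s[is.na(x)] <- NA
      df[[j]] <- s
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of probe ids.
#' Raw (linear-scale) intensities are log2-transformed unless
#' \code{already_log2 = TRUE}; zero or negative raw intensities are rejected
#' before the transform.
#'
#' @param path TSV file path.
#' @param already_log2 set TRUE when the file already holds log2 values.
#' @return numeric matrix, probes x samples.
#' @export
readExpression <- function(path, already_log2 = TRUE) {
  df <- .readTSV(path, colClasses = NA)
  if (ncol(df) < 2) stop("expression TSV needs a probe id column plus samples")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate probe id(s): ", paste(dup, collapse = ", "))
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicate sample id(s) in header")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    stop("non-numeric expression column(s): ",
         paste(colnames(df)[-1][bad], collapse = ", "))
  }
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop("missing value in expression row '", ids[bad],
         "': expression matrices must be complete")
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!already_log2) {
    if (any(m <= 0)) {
      bad <- which(rowSums(m <= 0) > 0)[1]
      stop("non-positive raw intensity in row '", ids[bad],
           "' cannot be log2-transformed")
    }
    m <- log2(m)
  }
  m
}

#' Write an expression matrix as TSV (probe rows, sample columns)
#' @param expr numeric matrix with dimnames.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeExpression <- function(expr, path) {
  df <- data.frame(probe_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTSV(df, path)
}

#' Read / write a design table TSV
#' @param path file path.
#' @return data.frame with the design columns.
#' @export
readDesign <- function(path) {
  d <- .readTSV(path, colClasses = "character")
  .checkDesign(d)
}

#' @rdname readDesign
#' @param design design data.frame.
#' @export
writeDesign <- function(design, path) .writeTSV(.checkDesign(design), path)

#' Read / write a phenotype table TSV (first column sample_id; NA allowed)
#' @param path file path.
#' @return numeric matrix, samples x variables, with sample rownames.
#' @export
readPhenotypes <- function(path) {
  df <- .readTSV(path)
  if (colnames(df)[1] != "sample_id")
    stop("phenotype TSV must start with a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if (anyDuplicated(colnames(df)[-1])) stop("duplicate phenotype names")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  empty <- colnames(m)[colSums(!is.na(m)) == 0]
  if (length(empty))
    stop("phenotype variable(s) with no non-missing values: ",
         paste(empty, collapse = ", "))
  m
}

#' @rdname readPhenotypes
#' @param pheno numeric matrix, samples x variables, sample rownames.
#' @export
writePhenotypes <- function(pheno, path) {
  df <- data.frame(sample_id = rownames(pheno), pheno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTSV(df, path)
}

#' Read / write a simulation truth table TSV
#' @param path file path.
#' @return data.frame as produced by \code{\link{simulateExpression}}.
#' @export
readTruth <- function(path) {
  tt <- .readTSV(path)
  for (j in seq_along(tt))
    if (is.numeric(tt[[j]])) tt[[j]] <- as.numeric(tt[[j]])
  if (!is.null(tt$probe_id)) rownames(tt) <- tt$probe_id
  tt
}

#' @rdname readTruth
#' @param truth truth data.frame.
#' @export
writeTruth <- function(truth, path) .writeTSV(truth, path)

#' Read a GMT annotation file
#'
#' One term per line: term id, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors; term descriptions kept in the
#'   \code{"description"} attribute.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(short), collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate GMT term ids")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2), ids)
  sets
}

#' Harmonize expression, design and phenotype tables by sample id
#'
#' Reorders every table to the design's sample order; samples absent from any
#' table are dropped with a warning and reported in the \code{dropped}
#' element.
#'
#' @param expr probes x samples matrix.
#' @param design design data.frame.
#' @param pheno optional samples x variables matrix.
#' @return list(expr, design, pheno, dropped).
#' @export
alignSamples <- function(expr, design, pheno = NULL) {
  design <- .checkDesign(design)
  common <- intersect(design$sample_id, colnames(expr))
  if (!is.null(pheno)) common <- intersect(common, rownames(pheno))
  if (!length(common))
    stop("no samples shared by the supplied tables")
  keep <- design$sample_id[design$sample_id %in% common]
  dropped <- unique(c(setdiff(design$sample_id, keep),
                      setdiff(colnames(expr), keep),
                      if (!is.null(pheno)) setdiff(rownames(pheno), keep)))
  if (length(dropped))
    warning("dropped sample(s) absent from some table: ",
            paste(dropped, collapse = ", "))
  list(expr = expr[, keep, drop = FALSE],
       design = design[match(keep, design$sample_id), , drop = FALSE],
       pheno = if (is.null(pheno)) NULL else pheno[keep, , drop = FALSE],
       dropped = dropped)
}
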