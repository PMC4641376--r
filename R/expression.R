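#' Expression dataset with control/case condition labels
#'
#' Container for a gene-by-sample matrix of (log-scale) expression values
#' together with a two-level condition assignment.  Both conditions must
#' contain at least two samples; rows containing missing values are not
#' allowed (readers drop and count them before construction).
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names.
#' @param condition character vector of `"control"`/`"case"` labels, either
#'   named by sample id or in column order of `values`.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values` (the matrix) and `condition` (named character vector).
#' @export
ExpressionDataset <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (anyNA(values))
    stop("expression matrix contains missing values")
  cond_names <- names(condition)
  condition <- as.character(condition)
  names(condition) <- cond_names
  if (is.null(names(condition))) {
    if (length(condition) != ncol(values))
      stop("unnamed 'condition' must have one label per sample")
    names(condition) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(condition))
  if (length(missing) > 0)
    stop("no condition assignment for sample(s): ",
         paste(missing, collapse = ", "))
  condition <- condition[colnames(values)]
  bad <- !condition %in% c("control", "case")
  if (any(bad))
    stop("condition labels must be 'control' or 'case'; offending: ",
         paste(unique(condition[bad]), collapse = ", "))
  counts <- table(factor(condition, levels = c("control", "case")))
  if (any(counts < 2))
    stop("each condition needs at least 2 samples (control=",
         counts[["control"]], ", case=", counts[["case"]], ")")
  structure(list(values = values, condition = condition),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$values), "genes x",
      ncol(x$values), "samples (",
      sum(x$condition == "control"), "control /",
      sum(x$condition == "case"), "case )\n")
  invisible(x)
}

#' Gene ids of an expression dataset
#' @param dataset an [ExpressionDataset].
#' @return Character vector of gene symbols.
#' @export
gene_ids <- function(dataset) rownames(dataset$values)

#' Sample ids of an expression dataset
#' @inheritParams gene_ids
#' @return Character vector of sample names.
#' @export
sample_ids <- function(dataset) colnames(dataset$values)

#' Split an expression matrix by condition
#' @inheritParams gene_ids
#' @param which `"control"` or `"case"`.
#' @return Sub-matrix of the requested condition's samples.
#' @export
condition_values <- function(dataset, which = c("control", "case")) {
  which <- match.arg(which)
  dataset$values[, dataset$condition == which, drop = FALSE]
}

#' Read a gene-by-sample expression table
#'
#' Expects a TSV/CSV file with gene ids in the first column and sample ids
#' in the header.  Duplicate gene rows are collapsed by their mean (with a
#' message); rows containing missing values are dropped and counted in the
#' `n_dropped_na` attribute of the result.
#'
#' @param path file path.
#' @param condition_spec condition assignment: a named character vector
#'   (sample id -> `"control"`/`"case"`), a two-column data frame
#'   (sample id, condition), or a path to a two-column TSV of the same.
#' @param sep field separator; `"\t"` by default, use `","` for CSV.
#' @param uppercase uppercase gene symbols at load (default `TRUE`) so
#'   that membership checks against gene sets and networks are
#'   case-insensitive.
#' @return An [ExpressionDataset]; attributes `n_dropped_na` and
#'   `n_collapsed` report dropped/merged rows.
#' @export
read_expression <- function(path, condition_spec, sep = "\t",
                            uppercase = TRUE) {
  tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3)
    stop("expression table needs a gene id column plus >= 2 samples")
  genes <- as.character(tab[[1]])
  if (uppercase) genes <- toupper(genes)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  n_na <- sum(!stats::complete.cases(m))
  if (n_na > 0) {
    keep <- stats::complete.cases(m)
    m <- m[keep, , drop = FALSE]
    genes <- genes[keep]
    message(n_na, " gene row(s) with missing values dropped")
  }
  n_collapsed <- 0L
  if (anyDuplicated(genes)) {
    n_collapsed <- sum(duplicated(genes))
    message(n_collapsed, " duplicate gene row(s) collapsed by mean")
    m <- rowsum(m, group = genes, reorder = FALSE) /
      as.vector(table(genes)[unique(genes)])
    genes <- unique(genes)
  }
  rownames(m) <- genes
  cond <- normalize_condition_spec(condition_spec)
  ds <- ExpressionDataset(m, cond)
  attr(ds, "n_dropped_na") <- n_na
  attr(ds, "n_collapsed") <- n_collapsed
  ds
}

normalize_condition_spec <- function(condition_spec) {
  if (is.character(condition_spec) && length(condition_spec) == 1 &&
      is.null(names(condition_spec)) && file.exists(condition_spec)) {
    condition_spec <- read.delim(condition_spec, header = TRUE,
                                 stringsAsFactors = FALSE)
  }
  if (is.data.frame(condition_spec)) {
    if (ncol(condition_spec) < 2)
      stop("condition table needs sample id and condition columns")
    out <- as.character(condition_spec[[2]])
    names(out) <- as.character(condition_spec[[1]])
    return(out)
  }
  if (is.character(condition_spec) && !is.null(names(condition_spec)))
    return(condition_spec)
  stop("'condition_spec' must be a named vector, a data frame, ",
       "or a path to a two-column table")
}
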