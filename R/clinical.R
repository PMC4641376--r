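#' Read a sample-by-clinical-index table
#'
#' The file must contain a `sample_id` column (or have sample ids in its
#' first column).  `type_spec` declares every other column as
#' `"continuous"` or `"categorical"`; non-numeric entries in continuous
#' columns become missing and are counted.
#'
#' @param path file path (TSV).
#' @param type_spec named character vector, index name ->
#'   `"continuous"`/`"categorical"`.
#' @return A data frame of class `ClinicalTable` with row names set to
#'   sample ids, an `index_types` attribute, and `n_coerced_na` counting
#'   values coerced to missing.
#' @export
read_clinical <- function(path, type_spec) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  id_col <- if ("sample_id" %in% names(tab)) "sample_id" else names(tab)[1]
  ids <- as.character(tab[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in clinical table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tab <- tab[, setdiff(names(tab), id_col), drop = FALSE]
  clinical_table(tab, ids, type_spec)
}

#' Construct a clinical table from a data frame
#' @param data data frame of clinical indices (no id column).
#' @param sample_ids character vector of unique sample ids.
#' @param type_spec named character vector, index name ->
#'   `"continuous"`/`"categorical"`.
#' @return A `ClinicalTable` data frame (see [read_clinical]).
#' @export
clinical_table <- function(data, sample_ids, type_spec) {
  if (is.null(names(type_spec)) ||
      !all(type_spec %in% c("continuous", "categorical")))
    stop("'type_spec' must be a named vector of ",
         "'continuous'/'categorical'")
  unknown <- setdiff(names(type_spec), names(data))
  if (length(unknown) > 0)
    stop("type_spec names absent from table: ",
         paste(unknown, collapse = ", "))
  data <- data[, names(type_spec), drop = FALSE]
  n_coerced <- 0L
  for (idx in names(type_spec)) {
    if (type_spec[[idx]] == "continuous") {
      v <- suppressWarnings(as.numeric(as.character(data[[idx]])))
      n_coerced <- n_coerced + sum(is.na(v) & !is.na(data[[idx]]))
      data[[idx]] <- v
    } else {
      data[[idx]] <- as.character(data[[idx]])
    }
  }
  rownames(data) <- as.character(sample_ids)
  attr(data, "index_types") <- type_spec
  attr(data, "n_coerced_na") <- n_coerced
  class(data) <- c("ClinicalTable", "data.frame")
  data
}

#' Clinical index types of a table
#' @param clinical a `ClinicalTable`.
#' @return Named character vector of index types.
#' @export
index_types <- function(clinical) attr(clinical, "index_types")
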