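#' Write a result table as TSV
#'
#' Serializes any result record data frame with a fixed column order
#' (the order of `records`), no quoting, and floating point values
#' rendered with 6 significant digits so that read-after-write
#' round-trips are stable.
#'
#' @param records a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  for (j in seq_along(records)) {
    if (is.double(records[[j]]))
      records[[j]] <- formatC(records[[j]], digits = 6, format = "g")
  }
  ok <- tryCatch({
    write.table(records, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read back a TSV result table
#' @param path file path written by [write_table].
#' @return A data frame.
#' @export
read_table_tsv <- function(path) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
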